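# helpers building aligned toy REML problems
toy_reml <- function(n = 80, m = 60, h2 = 0.5, seed = 1) {
  set.seed(seed)
  g <- random_geno(n, m, seed = seed)
  grm <- compute_grm(g)
  L <- chol(h2 * grm$values + diag(1 - h2, n) + diag(1e-8, n))
  y <- as.vector(t(L) %*% rnorm(n)) + 10
  pheno <- tibble::tibble(sample = g$samples, y = y,
                          age_days = runif(n, 700, 3600))
  list(pheno = pheno, grm = grm)
}

test_that("REML estimates are shift-invariant and scale as c^2", {
  tr <- toy_reml(n = 120, seed = 2)
  model <- qg_model("y", covariates = NULL)
  f1 <- fit_greml(tr$pheno, tr$grm, model)
  ph2 <- tr$pheno; ph2$y <- ph2$y + 100
  f2 <- fit_greml(ph2, tr$grm, model)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-4)
  ph3 <- tr$pheno; ph3$y <- 3 * ph3$y
  f3 <- fit_greml(ph3, tr$grm, model)
  expect_equal(9 * f1$sigma2, f3$sigma2, tolerance = 1e-2)
})

test_that("a heritability-free trait yields a near-zero genetic fraction", {
  set.seed(3)
  g <- random_geno(800, 120, seed = 3)
  pheno <- tibble::tibble(sample = g$samples, y = rnorm(800, 50, 2))
  fit <- fit_greml(pheno, compute_grm(g), qg_model("y", covariates = NULL))
  expect_lte(sum(fit$fractions), 0.05)
})

test_that("variance fractions sum to one with the residual", {
  tr <- toy_reml(seed = 4)
  fit <- fit_greml(tr$pheno, tr$grm, qg_model("y", covariates = NULL))
  expect_equal(sum(fit$sigma2) / fit$V_P, 1, tolerance = 1e-8)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(td$variance >= 0))
  expect_true(glance(fit)$converged)
})

test_that("the boundary-mixture LRT behaves as specified", {
  mk <- function(logL, labels) {
    structure(list(logL = logL, grm_labels = labels), class = "qg_greml")
  }
  # LRT = 0 -> p = 0.5
  expect_equal(lrt_genetic_variance(mk(-10, "g"), mk(-10, NULL))$p_value, 0.5)
  # LRT = 3.84, one component -> about 0.025
  r <- lrt_genetic_variance(mk(-10 + 3.84 / 2, "g"), mk(-10, NULL))
  expect_equal(r$p_value, 0.5 * pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(round(r$p_value, 3), 0.025)
  expect_false(r$excluded)
  # weak-evidence fits are flagged excluded
  r2 <- lrt_genetic_variance(mk(-10 + 0.2, "g"), mk(-10, NULL))
  expect_gt(r2$p_value, 0.05)
  expect_true(r2$excluded)
  # a slightly negative LRT is clipped with a warning
  expect_warning(r3 <- lrt_genetic_variance(mk(-10.1, "g"), mk(-10, NULL)),
                 "clipping")
  expect_equal(r3$lrt, 0)
  # two dropped components use a plain chi-square
  r4 <- lrt_genetic_variance(mk(-10 + 2, c("a", "b")), mk(-10, NULL))
  expect_equal(r4$p_value, pchisq(4, 2, lower.tail = FALSE))
})

test_that("fit_null matches the REML residual-only likelihood", {
  tr <- toy_reml(n = 60, seed = 5)
  model <- qg_model("y", covariates = "age_days")
  nul <- fit_null(tr$pheno, model)
  d <- qtlfine:::build_design(tr$pheno, model)
  r <- lm(d$y ~ d$X - 1)
  expect_equal(unname(nul$sigma2["residual"]),
               sum(resid(r)^2) / (length(d$y) - ncol(d$X)))
})

test_that("self-correlation of a trait with itself is (near) unity", {
  tr <- toy_reml(n = 150, seed = 6)
  ph <- tr$pheno
  ph$y2 <- ph$y
  bf <- fit_bivariate(ph, tr$grm, qg_model("y", covariates = NULL),
                      qg_model("y2", covariates = NULL))
  rg <- bf$components$r_g[bf$components$component == "genetic"]
  expect_gt(rg, 0.97)
})

test_that("independently simulated traits show no genetic correlation", {
  rgs <- vapply(1:2, function(s) {
    set.seed(s + 20)
    g <- random_geno(500, 150, seed = s + 20)
    grm <- compute_grm(g)
    L <- t(chol(0.5 * grm$values + diag(0.5, 500) + diag(1e-8, 500)))
    ph <- tibble::tibble(sample = g$samples,
                         y1 = as.vector(L %*% rnorm(500)),
                         y2 = as.vector(L %*% rnorm(500)))
    bf <- fit_bivariate(ph, grm, qg_model("y1", covariates = NULL),
                        qg_model("y2", covariates = NULL))
    bf$components$r_g[bf$components$component == "genetic"]
  }, numeric(1))
  expect_lt(abs(mean(rgs)), 0.3)
})

test_that("gEBVs vanish when a component's variance is at the floor", {
  set.seed(7)
  g <- random_geno(200, 80, seed = 7)
  grm <- compute_grm(g)
  # pure-noise trait: the genetic component is floored, but another live
  # component keeps the prediction non-degenerate
  pheno <- tibble::tibble(sample = g$samples, y = rnorm(200))
  fit <- fit_greml(pheno, grm, qg_model("y", covariates = NULL))
  if (fit$sigma2["genetic"] <= fit$floor + 1e-12) {
    expect_error(predict_gebv(fit, grm), "floor")
  } else {
    blup <- predict_gebv(fit, grm)
    expect_lt(max(abs(blup$gebv$genetic)), 0.5)
  }
})

test_that("component gEBVs are centred and track the genetic signal", {
  tr <- toy_reml(n = 200, m = 80, h2 = 0.6, seed = 8)
  fit <- fit_greml(tr$pheno, tr$grm, qg_model("y", covariates = NULL))
  blup <- predict_gebv(fit, tr$grm)
  expect_lt(abs(mean(blup$gebv$genetic)), 1e-6 * sd(tr$pheno$y))
  expect_equal(blup$gebv$total, blup$gebv$genetic)
  long <- tidy(blup)
  expect_setequal(unique(long$component), c("genetic", "total"))
})

test_that("fit summaries export in the Source/Variance/SE layout", {
  tr <- toy_reml(n = 60, seed = 9)
  fit <- fit_greml(tr$pheno, tr$grm, qg_model("y", covariates = NULL))
  path <- tempfile(fileext = ".hsq")
  write_hsq(fit, path, lrt = tibble::tibble(lrt = 2.1, df = 1, p_value = 0.07))
  lines <- readLines(path)
  expect_equal(lines[1], "Source\tVariance\tSE")
  expect_true(any(startsWith(lines, "V(genetic)")))
  expect_true(any(startsWith(lines, "V(e)")))
  expect_true(any(startsWith(lines, "logL")))
  expect_true(any(startsWith(lines, "Pval")))
  expect_equal(as.integer(sub("n\t", "", lines[length(lines)])), fit$n_used)
})
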