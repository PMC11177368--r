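# Bivariate AI-REML: two traits, shared variance-component structure.
# Each component c (every GRM plus the residual) carries a 2x2 covariance
# matrix (v1_c, c12_c, v2_c); the stacked covariance is
#   V = sum_c B_c (x) A_c  +  R (x) I
# in Kronecker notation with y = (y1', y2')'. The same AI machinery as the
# univariate fit applies, with three derivative matrices per component.
# Parameterised by covariances; r_G is clamped to [-1, 1] afterwards.

biv_build_blocks <- function(theta, A_list, n) {
  q <- length(A_list)  # GRM components; residual handled with A = I
  V11 <- matrix(0, n, n); V12 <- matrix(0, n, n); V22 <- matrix(0, n, n)
  for (c in seq_len(q)) {
    k <- 3 * (c - 1)
    V11 <- V11 + theta[k + 1] * A_list[[c]]
    V12 <- V12 + theta[k + 2] * A_list[[c]]
    V22 <- V22 + theta[k + 3] * A_list[[c]]
  }
  k <- 3 * q
  diag(V11) <- diag(V11) + theta[k + 1]
  V12 <- V12 + diag(theta[k + 2], n)
  diag(V22) <- diag(V22) + theta[k + 3]
  list(V11 = V11, V12 = V12, V22 = V22)
}

# stacked-covariance pieces via blockwise (Schur-complement) inversion:
# factorising two n x n blocks is markedly cheaper than one 2n x 2n matrix
biv_parts <- function(theta, y, X, A_list, n) {
  B <- biv_build_blocks(theta, A_list, n)
  ch11 <- tryCatch(chol(B$V11), error = function(e) NULL)
  if (is.null(ch11)) return(NULL)
  V11i <- chol2inv(ch11)
  W <- V11i %*% B$V12
  S <- B$V22 - B$V12 %*% W
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) return(NULL)
  Si <- chol2inv(chS)
  logdetV <- 2 * (sum(log(diag(ch11))) + sum(log(diag(chS))))
  WSi <- W %*% Si
  Vi <- rbind(cbind(V11i + WSi %*% t(W), -WSi),
              cbind(-t(WSi), Si))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  logdetX <- 2 * sum(log(diag(chX)))
  P <- Vi - ViX %*% chol2inv(chX) %*% t(ViX)
  Py <- P %*% y
  logL <- -0.5 * (logdetV + logdetX + sum(y * Py))
  list(P = P, Py = Py, logL = logL)
}

# apply the derivative matrix of parameter (component c, type) to a stacked
# vector; type 1 = trait-1 variance, 2 = covariance, 3 = trait-2 variance
biv_apply_d <- function(type, A, v, n) {
  v1 <- v[seq_len(n)]; v2 <- v[n + seq_len(n)]
  mul <- function(x) if (is.null(A)) x else as.vector(A %*% x)
  switch(type,
         c(mul(v1), rep(0, n)),
         c(mul(v2), mul(v1)),
         c(rep(0, n), mul(v2)))
}

biv_trace_PdV <- function(type, A, P, n) {
  i1 <- seq_len(n); i2 <- n + i1
  if (is.null(A)) {
    switch(type,
           sum(diag(P)[i1]),
           2 * sum(diag(P[i1, i2, drop = FALSE])),
           sum(diag(P)[i2]))
  } else {
    switch(type,
           sum(P[i1, i1] * A),
           2 * sum(P[i1, i2] * A),
           sum(P[i2, i2] * A))
  }
}

biv_clamp <- function(theta, q, floor_val) {
  for (c in seq_len(q + 1)) {
    k <- 3 * (c - 1)
    theta[k + 1] <- max(theta[k + 1], floor_val)
    theta[k + 3] <- max(theta[k + 3], floor_val)
    lim <- 0.99 * sqrt(theta[k + 1] * theta[k + 3])
    theta[k + 2] <- max(min(theta[k + 2], lim), -lim)
  }
  theta
}

#' Fit a bivariate GREML model
#'
#' Estimates per-component genetic variances, covariances and correlations
#' for two traits observed on the same individuals (complete-case), with
#' any number of GRM components plus a correlated residual. Supports the
#' region-local design: a QTL-window GRM together with a rest-of-genome GRM
#' that excludes the window's buffer.
#'
#' @param pheno Phenotype tibble containing both traits.
#' @param grms A `qg_grm` or named list of them.
#' @param model1,model2 [qg_model()] for each trait (fixed effects may
#'   differ).
#' @param max_iter,tol AI-REML controls.
#' @param start Optional start vector for the `3 * (n_grm + 1)` parameters
#'   (per component: trait-1 variance, covariance, trait-2 variance;
#'   residual last). Defaults to equal splits of the phenotypic
#'   (co)variances.
#' @return An object of class `qg_bivar` with a per-component tibble
#'   `components` (`component`, `v1`, `cov12`, `v2`, `r_g`, `r_g_se`,
#'   `defined`), `logL`, `converged`, `n_used`. `r_g` is flagged undefined
#'   when either trait's component variance is below `1e-8` of its
#'   phenotypic variance.
#' @export
fit_bivariate <- function(pheno, grms, model1, model2, max_iter = 100,
                          tol = 1e-4, start = NULL) {
  if (inherits(grms, "qg_grm")) grms <- list(genetic = grms)
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- vapply(grms, `[[`, character(1), "label")
  }
  common <- Reduce(intersect, lapply(grms, `[[`, "samples"))
  common <- intersect(pheno$sample, common)
  d1 <- build_design(pheno, model1, samples = common)
  d2 <- build_design(pheno, model2, samples = common)
  both <- intersect(d1$samples, d2$samples)
  d1 <- build_design(pheno, model1, samples = both)
  d2 <- build_design(pheno, model2, samples = both)
  n <- length(both)
  grms_al <- align_grms(grms, both)
  A_list <- lapply(grms_al, `[[`, "values")
  q <- length(A_list)
  y <- c(d1$y, d2$y)
  X <- rbind(cbind(d1$X, matrix(0, n, ncol(d2$X))),
             cbind(matrix(0, n, ncol(d1$X)), d2$X))
  r1 <- stats::lm.fit(d1$X, d1$y)$residuals
  r2 <- stats::lm.fit(d2$X, d2$y)$residuals
  s1 <- stats::var(r1); s2 <- stats::var(r2); s12 <- stats::cov(r1, r2)
  floor_val <- 1e-6 * min(s1, s2)
  theta <- start %||% c(rep(c(s1 / (2 * q), s12 / (2 * q), s2 / (2 * q)), q),
                        s1 / 2, s12 / 2, s2 / 2)
  theta <- biv_clamp(theta, q, floor_val)
  np <- 3 * (q + 1)
  converged <- FALSE
  AI <- NULL
  parts <- biv_parts(theta, y, X, A_list, n)
  if (is.null(parts)) stop("stacked covariance not positive definite")
  for (iter in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    u <- vector("list", np)
    score <- numeric(np)
    for (j in seq_len(np)) {
      c <- (j - 1) %/% 3 + 1
      type <- (j - 1) %% 3 + 1
      A <- if (c <= q) A_list[[c]] else NULL
      u[[j]] <- biv_apply_d(type, A, Py, n)
      score[j] <- -0.5 * (biv_trace_PdV(type, A, P, n) - sum(Py * u[[j]]))
    }
    U <- do.call(cbind, u)
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    delta <- tryCatch(solve(AI, score), error = function(e)
      solve(AI + diag(1e-8 * mean(diag(AI)), np), score))
    step <- if (iter == 1) 0.316 else 1   # damped first step
    cand_parts <- NULL
    for (h in seq_len(6)) {
      cand <- biv_clamp(theta + step * as.vector(delta), q, floor_val)
      cand_parts <- biv_parts(cand, y, X, A_list, n)
      if (!is.null(cand_parts) && cand_parts$logL >= parts$logL - 1e-8) break
      step <- step / 2
      cand_parts <- NULL
    }
    if (is.null(cand_parts)) {
      # no improving step found: treat the current point as the optimum
      converged <- TRUE
      break
    }
    moved <- cand_parts$logL - parts$logL
    theta <- cand
    parts <- cand_parts
    if (iter > 1 && abs(moved) < tol) {
      converged <- TRUE
      break
    }
  }
  final <- parts
  C <- tryCatch(solve(AI), error = function(e) NULL)
  vp1 <- sum(theta[seq(1, np, by = 3)])
  vp2 <- sum(theta[seq(3, np, by = 3)])
  labels <- c(names(grms), "residual")
  rows <- lapply(seq_len(q + 1), function(c) {
    k <- 3 * (c - 1)
    v1 <- theta[k + 1]; c12 <- theta[k + 2]; v2 <- theta[k + 3]
    defined <- v1 > 1e-8 * vp1 && v2 > 1e-8 * vp2
    r <- if (defined) max(min(c12 / sqrt(v1 * v2), 1), -1) else NA_real_
    r_se <- NA_real_
    if (defined && !is.null(C)) {
      g <- c(-r / (2 * v1), 1 / sqrt(v1 * v2), -r / (2 * v2))
      Cc <- C[k + 1:3, k + 1:3]
      r_se <- sqrt(max(0, g %*% Cc %*% g))
    }
    tibble(component = labels[c], v1 = v1, cov12 = c12, v2 = v2,
           r_g = r, r_g_se = r_se, defined = defined)
  })
  structure(list(components = bind_rows(rows), logL = final$logL,
                 converged = converged, n_used = n, iter = iter,
                 traits = c(model1$trait, model2$trait),
                 v_p = c(vp1, vp2)), class = "qg_bivar")
}

#' @export
print.qg_bivar <- function(x, ...) {
  cat("<qg_bivar> ", paste(x$traits, collapse = " x "), ": n = ", x$n_used,
      ", logL = ", round(x$logL, 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$components)
  invisible(x)
}
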