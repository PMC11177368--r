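# Average-information REML for linear mixed models with one or many
# GRM-structured genetic variance components:
#   y ~ N(X beta, sum_c sigma2_c A_c + sigma2_e I).
# One expectation-maximisation step first, then AI (quasi-Newton) updates
# with step halving; variances are constrained to a small positive floor.
# All traces use the identity tr(P A) = sum(P * A) for symmetric A, so one
# Cholesky of V per iteration is the only O(n^3) operation.

reml_parts <- function(theta, y, X, A_list) {
  n <- length(y)
  q <- length(A_list)
  V <- diag(theta[q + 1], n)
  for (c in seq_len(q)) V <- V + theta[c] * A_list[[c]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  logdetX <- 2 * sum(log(diag(chX)))
  XtViX_inv <- chol2inv(chX)
  P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  Py <- P %*% y
  logL <- -0.5 * (logdetV + logdetX + sum(y * Py))
  list(P = P, Py = Py, logL = logL, Vi = Vi, XtViX_inv = XtViX_inv, ViX = ViX)
}

reml_loglik_only <- function(theta, y, X, A_list) {
  parts <- reml_parts(theta, y, X, A_list)
  if (is.null(parts)) -Inf else parts$logL
}

reml_core <- function(y, X, A_list, max_iter = 100, tol = 1e-4,
                      floor_frac = 1e-6, start = NULL) {
  n <- length(y)
  q <- length(A_list)
  Vp0 <- stats::var(stats::lm.fit(X, y)$residuals)
  floor_val <- floor_frac * Vp0
  theta <- start %||% c(rep(Vp0 / (2 * q), q), Vp0 / 2)
  theta <- pmax(theta, floor_val)
  converged <- FALSE
  AI <- NULL
  parts <- reml_parts(theta, y, X, A_list)
  if (is.null(parts)) stop("covariance matrix not positive definite during REML")
  for (iter in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    u <- vector("list", q + 1)
    trPA <- numeric(q + 1)
    yPAPy <- numeric(q + 1)
    for (c in seq_len(q)) {
      u[[c]] <- A_list[[c]] %*% Py
      trPA[c] <- sum(P * A_list[[c]])
      yPAPy[c] <- sum(Py * u[[c]])
    }
    u[[q + 1]] <- Py
    trPA[q + 1] <- sum(diag(P))
    yPAPy[q + 1] <- sum(Py * Py)
    score <- -0.5 * (trPA - yPAPy)
    U <- do.call(cbind, u)
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    delta <- if (iter == 1) {
      # EM first step (robust far from the optimum)
      theta^2 * (yPAPy - trPA) / n
    } else {
      as.vector(tryCatch(solve(AI, score), error = function(e)
        solve(AI + diag(1e-8 * mean(diag(AI)), q + 1), score)))
    }
    # step halving if the restricted likelihood would decrease
    step <- 1
    cand_parts <- NULL
    cand <- theta
    for (h in seq_len(5)) {
      cand <- pmax(theta + step * delta, floor_val)
      if (max(abs(cand - theta)) < 1e-10 * Vp0) break  # pinned at the floor
      cand_parts <- reml_parts(cand, y, X, A_list)
      if (!is.null(cand_parts) && cand_parts$logL >= parts$logL - 1e-8) break
      step <- step / 2
      cand_parts <- NULL
    }
    if (is.null(cand_parts)) {
      # no admissible improving step: current point is the constrained optimum
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
  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, q + 1))
  beta <- as.vector(parts$XtViX_inv %*% crossprod(X, parts$Vi %*% y))
  names(beta) <- colnames(X)
  list(theta = theta, se = se, logL = parts$logL, converged = converged,
       AI = AI, beta = beta, Py = parts$Py, n = n, Vp0 = Vp0,
       floor = floor_val, iter = iter)
}

#' Fit a (multi-component) GREML model
#'
#' Estimates genetic variance(s) tied to one or more genomic relationship
#' matrices plus a residual variance by restricted maximum likelihood,
#' using average-information iterations with an EM first step. Convergence
#' is declared when the restricted log-likelihood changes by less than
#' `tol`; variances are constrained to a floor of `1e-6` of the phenotypic
#' variance.
#'
#' @param pheno Phenotype tibble (must contain the model's columns and
#'   `sample`).
#' @param grms A `qg_grm` or named list of them (the variance components).
#' @param model A [qg_model()].
#' @param max_iter Maximum AI iterations (default 100).
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @return An object of class `qg_greml`; see [tidy.qg_greml()] and
#'   [glance.qg_greml()] for tabular summaries. Key fields: `sigma2`
#'   (named vector of component variances incl. `residual`), `se`,
#'   `fractions` (ratio of each genetic variance to phenotypic variance,
#'   i.e. h2 for a single all-SNP GRM), `fraction_se`, `V_P`, `logL`,
#'   `converged`, `n_used`.
#' @export
fit_greml <- function(pheno, grms, model, max_iter = 100, tol = 1e-4) {
  if (inherits(grms, "qg_grm")) grms <- list(genetic = grms)
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- vapply(grms, `[[`, character(1), "label")
  }
  common <- Reduce(intersect, lapply(grms, `[[`, "samples"))
  common <- intersect(pheno$sample, common)
  d <- build_design(pheno, model, samples = common)
  if (length(d$y) <= ncol(d$X) + length(grms)) {
    stop("too few observations (", length(d$y), ") for ", ncol(d$X),
         " fixed effects and ", length(grms), " variance components")
  }
  grms_al <- align_grms(grms, d$samples)
  A_list <- lapply(grms_al, `[[`, "values")
  fit <- reml_core(d$y, d$X, A_list, max_iter = max_iter, tol = tol)
  q <- length(A_list)
  sigma2 <- setNames(fit$theta, c(names(grms), "residual"))
  V_P <- sum(sigma2)
  fractions <- sigma2[seq_len(q)] / V_P
  # delta-method SEs for the variance fractions
  C <- tryCatch(solve(fit$AI), error = function(e) NULL)
  fraction_se <- rep(NA_real_, q)
  if (!is.null(C)) {
    for (c in seq_len(q)) {
      g <- rep(-sigma2[c] / V_P^2, q + 1)
      g[c] <- g[c] + 1 / V_P
      fraction_se[c] <- sqrt(max(0, g %*% C %*% g))
    }
  }
  structure(list(
    sigma2 = sigma2, se = setNames(fit$se, names(sigma2)),
    fractions = setNames(as.vector(fractions), names(grms)),
    fraction_se = setNames(fraction_se, names(grms)),
    V_P = V_P, logL = fit$logL, converged = fit$converged,
    n_used = fit$n, beta = fit$beta, iter = fit$iter,
    model = model, samples = d$samples, y = d$y, X = d$X,
    grm_labels = names(grms), Py = fit$Py, AI = fit$AI,
    floor = fit$floor), class = "qg_greml")
}

#' @export
print.qg_greml <- function(x, ...) {
  cat("<qg_greml> ", x$model$trait, ": n = ", x$n_used, ", logL = ",
      round(x$logL, 3), if (!x$converged) " (NOT converged)", "\n", sep = "")
  for (nm in x$grm_labels) {
    cat("  V(", nm, ") = ", signif(x$sigma2[nm], 4), " (",
        signif(x$fractions[nm], 3), " of V_P)\n", sep = "")
  }
  cat("  V(residual) = ", signif(x$sigma2["residual"], 4),
      ", V_P = ", signif(x$V_P, 4), "\n", sep = "")
  invisible(x)
}

#' Write a GREML fit summary in the .hsq layout
#'
#' Source/Variance/SE rows per component, the variance ratios, the
#' restricted log-likelihood and the sample size — the tabular convention
#' of the common GREML tools.
#'
#' @param fit A [fit_greml()] result.
#' @param path Output TSV path.
#' @param lrt Optional [lrt_genetic_variance()] row to append (LRT, df,
#'   Pval).
#' @return `path`, invisibly.
#' @export
write_hsq <- function(fit, path, lrt = NULL) {
  rows <- list()
  for (nm in fit$grm_labels) {
    rows[[length(rows) + 1]] <- c(paste0("V(", nm, ")"),
                                  fit$sigma2[nm], fit$se[nm])
  }
  rows[[length(rows) + 1]] <- c("V(e)", fit$sigma2["residual"],
                                fit$se["residual"])
  rows[[length(rows) + 1]] <- c("Vp", fit$V_P, NA)
  for (nm in fit$grm_labels) {
    rows[[length(rows) + 1]] <- c(paste0("V(", nm, ")/Vp"),
                                  fit$fractions[nm], fit$fraction_se[nm])
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Source\tVariance\tSE", con)
  apply(df, 1, function(r) writeLines(paste(r, collapse = "\t"), con))
  writeLines(paste0("logL\t", fit$logL), con)
  if (!is.null(lrt)) {
    writeLines(paste0("LRT\t", lrt$lrt), con)
    writeLines(paste0("df\t", lrt$df), con)
    writeLines(paste0("Pval\t", lrt$p_value), con)
  }
  writeLines(paste0("n\t", fit$n_used), con)
  invisible(path)
}

#' Likelihood-ratio test for genetic variance
#'
#' Tests the `k` genetic components present in the full fit but absent from
#' the nested null fit. For `k = 1` the null distribution is the boundary
#' mixture `0.5 chi2_0 + 0.5 chi2_1`, so `p = 0.5 Pr(chi2_1 >= LRT)`
#' (`p = 0.5` at LRT = 0); for `k > 1` a plain `chi2_k` is used. Traits
#' with `p > 0.05` are flagged `excluded` (no usable genetic variance).
#'
#' @param fit_full,fit_null Nested [fit_greml()] fits (same data and fixed
#'   effects; the null drops `k` genetic components).
#' @return A tibble with `lrt`, `df`, `p_value`, `excluded`.
#' @export
lrt_genetic_variance <- function(fit_full, fit_null) {
  k <- length(fit_full$grm_labels) - length(fit_null$grm_labels %||% character())
  if (k < 1) stop("the null model must drop at least one genetic component")
  lrt <- 2 * (fit_full$logL - fit_null$logL)
  if (lrt < -1e-6) {
    warning("full-model log-likelihood below the null's (LRT = ",
            signif(lrt, 4), "); clipping to 0")
  }
  lrt <- max(lrt, 0)
  p <- if (k == 1) 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
       else pchisq(lrt, df = k, lower.tail = FALSE)
  tibble(lrt = lrt, df = k, p_value = p, excluded = p > 0.05)
}

#' Fit a fixed-effects-only null model (no genetic variance)
#'
#' Convenience wrapper producing the nested null for
#' [lrt_genetic_variance()]: ordinary least squares with the restricted
#' likelihood evaluated at the residual-only covariance.
#'
#' @inheritParams fit_greml
#' @return A list with `logL`, `sigma2`, `n_used`, `grm_labels = NULL`.
#' @export
fit_null <- function(pheno, model, samples = NULL) {
  d <- build_design(pheno, model, samples = samples)
  n <- length(d$y)
  r <- stats::lm.fit(d$X, d$y)$residuals
  p <- qr(d$X)$rank
  s2 <- sum(r^2) / (n - p)   # REML estimate of the residual variance
  # restricted log-likelihood at (0, s2)
  XtX <- crossprod(d$X)
  logL <- -0.5 * (n * log(s2) + determinant(XtX / s2)$modulus[1] +
                    sum(r^2) / s2)
  list(logL = as.numeric(logL), sigma2 = c(residual = s2), n_used = n,
       grm_labels = NULL, samples = d$samples)
}

#' BLUP prediction of component-specific breeding values
#'
#' Predicts, for every individual and every genetic component of a
#' converged GREML fit, the genomic estimated breeding value
#' \deqn{\hat u_c = \sigma^2_c A_c V^{-1} (y - X \hat\beta)}
#' with V the fitted total covariance (equivalently
#' \eqn{\hat u_c = \sigma^2_c A_c P y}).
#'
#' @param fit A converged [fit_greml()] result.
#' @param grms The same GRMs the fit used (for their relationship values).
#' @return An object of class `qg_blup`: `gebv` tibble (sample plus one
#'   column per component and `total`), and `fixed` (fixed-effect
#'   estimates). Component gEBVs are centred by construction (each column
#'   mean is ~0).
#' @export
predict_gebv <- function(fit, grms) {
  stopifnot(inherits(fit, "qg_greml"))
  if (!fit$converged) stop("refusing to predict from a non-converged fit")
  if (inherits(grms, "qg_grm")) grms <- list(genetic = grms)
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- vapply(grms, `[[`, character(1), "label")
  }
  if (!setequal(names(grms), fit$grm_labels)) {
    stop("GRM components do not match the fit: ",
         paste(fit$grm_labels, collapse = ", "))
  }
  grms <- align_grms(grms[fit$grm_labels], fit$samples)
  if (all(fit$sigma2[fit$grm_labels] <= fit$floor + 1e-12)) {
    stop("all genetic variances are at the floor; gEBVs are degenerate")
  }
  out <- tibble(sample = fit$samples)
  for (nm in fit$grm_labels) {
    out[[nm]] <- as.vector(fit$sigma2[nm] * (grms[[nm]]$values %*% fit$Py))
  }
  out$total <- rowSums(as.matrix(out[, fit$grm_labels, drop = FALSE]))
  structure(list(gebv = out, fixed = fit$beta, trait = fit$model$trait,
                 components = fit$grm_labels), class = "qg_blup")
}

#' @export
print.qg_blup <- function(x, ...) {
  cat("<qg_blup> ", x$trait, ": ", nrow(x$gebv), " individuals, components: ",
      paste(x$components, collapse = ", "), "\n", sep = "")
  invisible(x)
}
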