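# Independent oracles, written directly from the rule definitions with
# plain loops; they share no code with the implementation paths they check.

# ROH: enumerate all maximal qualifying runs by direct looping.
oracle_roh_one <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(data.frame())
  hom_win <- logical(m - w + 1)
  for (s in seq_len(m - w + 1)) {
    win <- g[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  eligible <- logical(m)
  for (j in seq_len(m)) {
    covering <- max(1, j - w + 1):min(j, m - w + 1)
    eligible[j] <- mean(hom_win[covering]) > params$window_hit_threshold
  }
  segs <- list()
  j <- 1
  while (j <= m) {
    if (!eligible[j]) { j <- j + 1; next }
    k <- j
    while (k < m && eligible[k + 1] && pos[k + 1] - pos[k] <= params$max_gap_bp) {
      k <- k + 1
    }
    len <- pos[k] - pos[j] + 1
    nsnp <- k - j + 1
    if (nsnp >= params$min_snps && len >= params$min_length_bp &&
        len / nsnp <= params$min_density_bp_per_snp) {
      segs[[length(segs) + 1]] <- data.frame(start = pos[j], end = pos[k],
                                             n_snps = nsnp)
    }
    j <- k + 1
  }
  do.call(rbind, segs) %||% data.frame()
}

# restricted log-likelihood evaluated directly from its definition
oracle_reml_loglik <- function(sg, se, y, X, A) {
  n <- length(y)
  V <- sg * A + diag(se, n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

# BLUP by explicitly solving Henderson's mixed-model equations
oracle_mme_blup <- function(y, X, A_list, sigma2_g, sigma2_e) {
  n <- length(y)
  q <- length(A_list)
  # random effect u_c ~ N(0, sigma2_g[c] A_c), Z_c = I
  Z <- do.call(cbind, rep(list(diag(n)), q))
  Ginv <- matrix(0, n * q, n * q)
  for (c in seq_len(q)) {
    idx <- (c - 1) * n + seq_len(n)
    Ginv[idx, idx] <- solve(sigma2_g[c] * A_list[[c]])
  }
  lhs <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + sigma2_e * Ginv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  p <- ncol(X)
  u <- sol[-(seq_len(p))]
  lapply(seq_len(q), function(c) u[(c - 1) * n + seq_len(n)])
}
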