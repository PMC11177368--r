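# broom-style tidiers for fitted objects.

#' Tidy a GREML fit
#'
#' @param x A `qg_greml`.
#' @param ... Unused.
#' @return One row per variance component (including the residual):
#'   `component`, `variance`, `se`, `fraction` (of phenotypic variance;
#'   `NA` for the residual row by convention — use `1 - sum(fraction)`),
#'   `fraction_se`.
#' @method tidy qg_greml
#' @export
tidy.qg_greml <- function(x, ...) {
  comps <- c(x$grm_labels, "residual")
  tibble(component = comps,
         variance = unname(x$sigma2[comps]),
         se = unname(x$se[comps]),
         fraction = c(unname(x$fractions), NA_real_),
         fraction_se = c(unname(x$fraction_se), NA_real_))
}

#' One-row summary of a GREML fit
#'
#' @param x A `qg_greml`.
#' @param ... Unused.
#' @return Tibble with `trait`, `n`, `V_P`, `h2` (sum of genetic
#'   fractions), `logL`, `converged`, `n_components`, `iterations`.
#' @method glance qg_greml
#' @export
glance.qg_greml <- function(x, ...) {
  tibble(trait = x$model$trait, n = x$n_used, V_P = x$V_P,
         h2 = sum(x$fractions), logL = x$logL, converged = x$converged,
         n_components = length(x$grm_labels), iterations = x$iter)
}

#' Tidy a bivariate GREML fit
#'
#' @param x A `qg_bivar`.
#' @param ... Unused.
#' @return The per-component tibble (`component`, `v1`, `cov12`, `v2`,
#'   `r_g`, `r_g_se`, `defined`).
#' @method tidy qg_bivar
#' @export
tidy.qg_bivar <- function(x, ...) x$components

#' One-row summary of a bivariate GREML fit
#'
#' @param x A `qg_bivar`.
#' @param ... Unused.
#' @return Tibble with `trait1`, `trait2`, `n`, `logL`, `converged`.
#' @method glance qg_bivar
#' @export
glance.qg_bivar <- function(x, ...) {
  tibble(trait1 = x$traits[1], trait2 = x$traits[2], n = x$n_used,
         logL = x$logL, converged = x$converged)
}

#' Tidy a BLUP result
#'
#' @param x A `qg_blup`.
#' @param ... Unused.
#' @return Long tibble: `sample`, `component`, `gebv`.
#' @method tidy qg_blup
#' @export
tidy.qg_blup <- function(x, ...) {
  x$gebv %>%
    tidyr::pivot_longer(cols = -"sample", names_to = "component",
                        values_to = "gebv")
}

#' Tidy an association scan
#'
#' @param x A `qg_gwas`.
#' @param ... Unused.
#' @return The per-variant tibble without the extra class/attributes.
#' @method tidy qg_gwas
#' @export
tidy.qg_gwas <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "qg_gwas")
  out
}

#' One-row summary of an association scan
#'
#' @param x A `qg_gwas`.
#' @param ... Unused.
#' @return Tibble with `trait`, `n_tests`, `lambda_gc`, `threshold`,
#'   `n_significant`, `top_snp`, `top_p`.
#' @method glance qg_gwas
#' @export
glance.qg_gwas <- function(x, ...) {
  thr <- attr(x, "threshold")
  sig <- !is.na(x$p_value) & x$p_value <= thr
  top <- which.min(replace(x$p_value, is.na(x$p_value), Inf))
  tibble(trait = attr(x, "trait"), n_tests = attr(x, "n_tests"),
         lambda_gc = attr(x, "lambda_gc"), threshold = thr,
         n_significant = sum(sig),
         top_snp = if (length(top)) x$id[top] else NA_character_,
         top_p = if (length(top)) x$p_value[top] else NA_real_)
}
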