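# Fixed-effect model specification and design-matrix construction shared by
# the REML, BLUP and association stages.

#' Specify a trait model
#'
#' Describes the response and fixed-effect structure of an analysis: a trait
#' column, quantitative covariates (e.g. age in days, a conditioning SNP
#' dosage, or a conditioning trait) and categorical factors (age class, sex,
#' judge, event). The design matrix built from it uses treatment contrasts
#' with the first observed level as reference and drops rank-deficient
#' columns.
#'
#' @param trait Name of the trait column in the phenotype table.
#' @param covariates Character vector of quantitative covariate columns.
#' @param factors Character vector of categorical fixed-effect columns.
#' @return An object of class `qg_model`.
#' @examples
#' qg_model("height", covariates = "age_days")
#' qg_model("frame", covariates = NULL,
#'          factors = c("age_class", "sex", "judge", "event"))
#' @export
qg_model <- function(trait, covariates = "age_days", factors = character()) {
  structure(list(trait = trait,
                 covariates = as.character(covariates %||% character()),
                 factors = as.character(factors %||% character())),
            class = "qg_model")
}

#' @export
print.qg_model <- function(x, ...) {
  cat("<qg_model> ", x$trait, " ~ 1",
      if (length(x$covariates)) paste("", paste(x$covariates, collapse = " + "), sep = " + "),
      if (length(x$factors)) paste("", paste(x$factors, collapse = " + "), sep = " + "),
      "\n", sep = "")
  invisible(x)
}

# Build y and X for the samples (in order) of `samples`; complete cases only.
# Returns list(y, X, samples). Extra numeric covariates can be injected via
# `extra` (named list of vectors aligned with pheno rows), used by the
# conditional scans.
build_design <- function(pheno, model, samples = NULL, extra = NULL) {
  stopifnot(inherits(model, "qg_model"))
  df <- as.data.frame(pheno)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  cols <- c(model$trait, model$covariates, model$factors, names(extra))
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(samples)) {
    idx <- match(samples, df$sample)
    if (anyNA(idx)) stop("sample ", samples[which(is.na(idx))[1]],
                         " absent from phenotype table")
    df <- df[idx, , drop = FALSE]
  }
  ok <- complete.cases(df[, cols, drop = FALSE])
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete observations for trait ", model$trait)
  y <- as.numeric(df[[model$trait]])
  terms <- c("1", model$covariates, names(extra), model$factors)
  for (f in model$factors) df[[f]] <- factor(df[[f]])
  # factors collapsed to a single level carry no information; drop them
  keep_f <- vapply(model$factors, function(f) nlevels(df[[f]]) > 1, logical(1))
  terms <- setdiff(terms, model$factors[!keep_f])
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(fml, data = df)
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  list(y = y, X = X, samples = df$sample)
}
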