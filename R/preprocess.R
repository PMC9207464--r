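#' Adjust clinical scores for covariates by regression residuals
#'
#' Ordinary least-squares residuals of a score on an intercept plus the
#' given covariates (factor and numeric columns), fitted pooled across all
#' patients and visits.  Typical use: removing gender and treatment-dose
#' effects from follow-up scores before clustering.
#'
#' @param values numeric per-visit score vector (`NA` cells allowed; their
#'   residual is `NA`).
#' @param covariates data.frame of per-visit covariates, rows aligned with
#'   `values`.
#' @return residual vector (mean zero over observed cells).
#' @export
adjust_clinical <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values)) {
    stop("covariate rows must align with score values")
  }
  if (anyNA(covariates)) stop("covariates must be complete")
  varying <- vapply(covariates, function(x) length(unique(x)) > 1L, logical(1))
  covariates <- covariates[, varying, drop = FALSE]
  if (ncol(covariates) == 0L) {
    return(as.numeric(values - mean(values, na.rm = TRUE)))
  }
  d <- cbind(data.frame(.y = values), covariates)
  fit <- stats::lm(.y ~ ., data = d, na.action = stats::na.exclude)
  if (any(is.na(stats::coef(fit)))) {
    warning("rank-deficient covariate design; aliased columns dropped")
  }
  as.numeric(stats::residuals(fit))
}

#' Additive genotype encoding
#'
#' Maps allele-copy counts of the alternative allele to the centered
#' additive code: 0 copies -> -1 (homozygous reference), 1 copy -> 0
#' (heterozygous), 2 copies -> 1 (homozygous alternative).
#'
#' @param calls numeric vector/matrix with entries in `{0, 1, 2}`.
#' @return same shape with entries in `{-1, 0, 1}`.
#' @export
encode_genotypes <- function(calls) {
  bad <- !(calls %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype entries must be in {0, 1, 2}; offending position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  calls - 1
}

#' Decode additive genotypes back to allele-copy counts
#' @param values entries in `{-1, 0, 1}`.
#' @return entries in `{0, 1, 2}`.
#' @export
decode_genotypes <- function(values) {
  bad <- !(values %in% c(-1, 0, 1))
  if (any(bad)) {
    stop("encoded genotypes must be in {-1, 0, 1}; offending position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  values + 1
}

#' Screen markers on deleteriousness and frequency
#'
#' Retains the union of a known-association list and the markers whose
#' scaled CADD deleteriousness score exceeds `cadd_min` and whose allele
#' frequency exceeds `maf_min` (both strict inequalities).
#'
#' @param annotation data.frame with `marker_id`, `scaled_cadd`,
#'   `allele_frequency`.
#' @param known_assoc character vector of marker ids retained regardless of
#'   thresholds.
#' @param cadd_min scaled CADD threshold (default 25).
#' @param maf_min allele-frequency threshold (default 0.01).
#' @return character vector of retained marker ids (annotation order).
#' @export
screen_markers <- function(annotation, known_assoc = character(0),
                           cadd_min = 25, maf_min = 0.01) {
  stopifnot(is.finite(cadd_min), is.finite(maf_min))
  keep <- (annotation$scaled_cadd > cadd_min &
             annotation$allele_frequency > maf_min) |
    annotation$marker_id %in% known_assoc
  annotation$marker_id[keep]
}
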