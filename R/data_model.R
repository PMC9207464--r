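#' Longitudinal clinical data container
#'
#' Holds per-patient follow-up visits of `V` numeric clinical scores at
#' arbitrary (ragged) visit times.  Internally the visits are stacked into a
#' single cell matrix with one row per visit, sorted by patient (file order)
#' and, within patient, by time.  Missing score cells are `NA` and are
#' dropped cell-wise from all likelihood computations.
#'
#' @param data data.frame in long format: one row per visit.
#' @param id_col,time_col names of the patient-id and visit-time columns.
#' @param value_cols names of the clinical score columns; default all
#'   remaining columns.
#' @return An object of class `longitudinal_data` with fields
#'   `patient_ids` (length `N`, file order), `visit_patient` (integer patient
#'   index per visit row), `visit_time` (numeric), `values` (visits x V
#'   matrix, `NA` allowed), `variable_names`.
#' @export
longitudinal_data <- function(data, id_col = "patient_id", time_col = "time",
                              value_cols = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c(id_col, time_col) %in% names(data))) {
    stop("columns '", id_col, "' and '", time_col, "' are required")
  }
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(data), c(id_col, time_col))
  }
  if (length(value_cols) < 1L) stop("at least one clinical score column is required")
  if (nrow(data) < 1L) stop("empty cohort: no visit rows")
  ids <- as.character(data[[id_col]])
  times <- as.numeric(data[[time_col]])
  if (any(!is.finite(times))) stop("visit times must be finite")
  patient_ids <- unique(ids)
  pidx <- match(ids, patient_ids)
  ord <- order(pidx, times)
  values <- as.matrix(data[ord, value_cols, drop = FALSE])
  storage.mode(values) <- "double"
  obj <- structure(list(
    patient_ids = patient_ids,
    visit_patient = pidx[ord],
    visit_time = times[ord],
    values = values,
    variable_names = value_cols
  ), class = "longitudinal_data")
  validate_longitudinal(obj)
  obj
}

validate_longitudinal <- function(x) {
  n <- length(x$patient_ids)
  if (n < 1L) stop("empty cohort")
  if (!all(seq_len(n) %in% x$visit_patient)) {
    stop("every patient must have at least one visit")
  }
  if (any(!is.finite(x$visit_time))) stop("visit times must be finite")
  split_times <- split(x$visit_time, x$visit_patient)
  if (any(vapply(split_times, is.unsorted, logical(1)))) {
    stop("visit times must be non-decreasing within patient after sorting")
  }
  invisible(x)
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat(sprintf("longitudinal_data: %d patients, %d visits, %d variables (%s)\n",
              length(x$patient_ids), length(x$visit_time),
              length(x$variable_names),
              paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

n_patients <- function(clinical) length(clinical$patient_ids)

#' Genotype matrix container
#'
#' `N x L` matrix of additively coded genetic markers taking values in
#' `{-1, 0, 1}` (homozygous reference, heterozygous, homozygous alternative).
#' Rows align with the patients of the clinical container.
#'
#' @param values numeric matrix, patients in rows, markers in columns.
#' @param patient_ids character patient identifiers (row order).
#' @param marker_ids marker labels; default taken from column names.
#' @param dosage if `TRUE`, `values` are allele-copy counts in `{0,1,2}` and
#'   are recoded to `{-1,0,1}` (see [encode_genotypes()]).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, patient_ids = rownames(values),
                            marker_ids = colnames(values), dosage = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(patient_ids)) stop("patient_ids are required")
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(values)))
  if (length(patient_ids) != nrow(values)) stop("patient_ids length must match rows")
  if (anyNA(values)) stop("genotype matrix must have no missing entries at fit time")
  if (dosage) values <- encode_genotypes(values)
  structure(list(
    values = values,
    patient_ids = as.character(patient_ids),
    marker_ids = as.character(marker_ids)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d patients x %d markers\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Model parameter container
#'
#' Parameters of the gated trajectory mixture: per-cluster polynomial
#' coefficients and residual scales for each clinical variable, and
#' multinomial logistic gating weights over the markers with the reference
#' class pinned to zero for identifiability.
#'
#' @param alpha `K x V x (P+1)` array of trajectory coefficients on the
#'   rescaled time axis (`t / time_scale`).
#' @param sigma `K x V` matrix of positive residual standard deviations.
#' @param omega0 length-`K` gating intercepts (`omega0[reference_class] == 0`).
#' @param omega `K x L` gating coefficient matrix
#'   (`omega[reference_class, ] == 0`).
#' @param reference_class index of the pinned class (default 1).
#' @param time_scale positive scalar; visit times are divided by it before
#'   powers are taken.
#' @return Object of class `model_parameters`.
#' @export
model_parameters <- function(alpha, sigma, omega0, omega,
                             reference_class = 1L, time_scale = 1) {
  alpha <- as.array(alpha)
  if (length(dim(alpha)) != 3L) stop("alpha must be a K x V x (P+1) array")
  K <- dim(alpha)[1]; V <- dim(alpha)[2]; P <- dim(alpha)[3] - 1L
  sigma <- as.matrix(sigma)
  omega <- as.matrix(omega)
  if (!all(dim(sigma) == c(K, V))) stop("sigma must be K x V")
  if (length(omega0) != K) stop("omega0 must have length K")
  if (nrow(omega) != K) stop("omega must have K rows")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (time_scale <= 0) stop("time_scale must be positive")
  rc <- as.integer(reference_class)
  if (rc < 1L || rc > K) stop("reference_class out of range")
  if (omega0[rc] != 0 || any(omega[rc, ] != 0)) {
    stop("reference class gating parameters must be identically zero")
  }
  if (any(!is.finite(alpha)) || any(!is.finite(omega)) || any(!is.finite(omega0))) {
    stop("parameters must be finite")
  }
  structure(list(
    K = K, V = V, P = P, L = ncol(omega),
    alpha = alpha, sigma = sigma,
    omega0 = as.numeric(omega0), omega = omega,
    reference_class = rc, time_scale = time_scale
  ), class = "model_parameters")
}

#' Posterior responsibility container
#'
#' @param tau `N x K` matrix of posterior cluster-membership probabilities;
#'   rows must sum to 1 within `1e-10`.
#' @return Object of class `responsibilities`.
#' @export
responsibilities <- function(tau) {
  tau <- as.matrix(tau)
  if (any(tau < -1e-12) || any(tau > 1 + 1e-12)) {
    stop("responsibilities must lie in [0, 1]")
  }
  rs <- rowSums(tau)
  if (any(abs(rs - 1) > 1e-10)) stop("responsibility rows must sum to 1")
  structure(list(tau = tau), class = "responsibilities")
}

as_tau <- function(x) {
  if (inherits(x, "responsibilities")) x$tau else as.matrix(x)
}

#' One-hot responsibility matrix from hard labels
#' @param labels integer class labels in `1..K`.
#' @param K number of classes.
#' @return `N x K` 0/1 matrix.
#' @export
labels_to_tau <- function(labels, K) {
  n <- length(labels)
  tau <- matrix(0, n, K)
  tau[cbind(seq_len(n), as.integer(labels))] <- 1
  tau
}

#' Align clinical and genotype containers by patient id
#'
#' Verifies that both containers describe the same cohort and permutes the
#' genotype rows into the clinical (file) patient order.
#'
#' @param clinical a [longitudinal_data()] object.
#' @param geno a [genotype_matrix()] object.
#' @return `list(clinical = , geno = )` with aligned row order.
#' @export
validate_aligned <- function(clinical, geno) {
  stopifnot(inherits(clinical, "longitudinal_data"),
            inherits(geno, "genotype_matrix"))
  cid <- clinical$patient_ids
  gid <- geno$patient_ids
  if (length(cid) == 0L) stop("empty cohort")
  missing_in_geno <- setdiff(cid, gid)
  missing_in_clin <- setdiff(gid, cid)
  if (length(missing_in_geno) || length(missing_in_clin)) {
    stop("patient id mismatch between clinical and genotype data; ",
         "missing in genotype: [",
         paste(missing_in_geno, collapse = ", "),
         "]; missing in clinical: [",
         paste(missing_in_clin, collapse = ", "), "]")
  }
  perm <- match(cid, gid)
  if (!identical(perm, seq_along(gid))) {
    geno$values <- geno$values[perm, , drop = FALSE]
    geno$patient_ids <- gid[perm]
  }
  list(clinical = clinical, geno = geno)
}

# ---- CSV readers / writers ------------------------------------------------

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read / write the clinical CSV dialect
#'
#' Long format: columns `patient_id`, `time`, then one named column per
#' clinical score, one row per visit.
#' @param file path to a CSV file.
#' @return [longitudinal_data()] object.
#' @export
read_clinical_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  longitudinal_data(df)
}

#' @rdname read_clinical_csv
#' @param clinical a [longitudinal_data()] object.
#' @export
write_clinical_csv <- function(clinical, file) {
  df <- data.frame(
    patient_id = clinical$patient_ids[clinical$visit_patient],
    time = fmt_num(clinical$visit_time),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (v in seq_along(clinical$variable_names)) {
    df[[clinical$variable_names[v]]] <- fmt_num(clinical$values[, v])
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read / write the genotype CSV dialect
#'
#' First column `patient_id`, remaining columns one per marker with entries
#' in `{-1, 0, 1}` (or `{0, 1, 2}` allele dosages with `dosage = TRUE`).
#' @param file path to a CSV file.
#' @param dosage if `TRUE` entries are allele-copy counts and are recoded.
#' @return [genotype_matrix()] object.
#' @export
read_genotype_csv <- function(file, dosage = FALSE) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  genotype_matrix(vals, patient_ids = ids, marker_ids = colnames(df)[-1L],
                  dosage = dosage)
}

#' @rdname read_genotype_csv
#' @param geno a [genotype_matrix()] object.
#' @export
write_genotype_csv <- function(geno, file) {
  df <- data.frame(patient_id = geno$patient_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  vals <- geno$values
  for (l in seq_along(geno$marker_ids)) df[[geno$marker_ids[l]]] <- fmt_num(vals[, l])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read a marker annotation CSV (`marker_id, scaled_cadd, allele_frequency`)
#' @param file path to a CSV file.
#' @return data.frame with the three columns, `allele_frequency` in `[0, 1]`.
#' @export
read_annotation_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("marker_id", "scaled_cadd", "allele_frequency")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$allele_frequency < 0 | df$allele_frequency > 1, na.rm = TRUE)) {
    stop("allele_frequency must lie in [0, 1]")
  }
  df[, need]
}

#' Convert trajectory coefficients between time scalings
#'
#' Fitted `alpha` are reported on the rescaled axis `u = t / time_scale`.
#' This converts a coefficient vector (or the `K x V x (P+1)` array) from one
#' scale to another: `alpha_p' = alpha_p * (to / from)^p`.
#'
#' @param alpha coefficient array with last dimension `P+1`.
#' @param from,to positive time scales.
#' @return Rescaled coefficients of the same shape.
#' @export
rescale_alpha <- function(alpha, from, to) {
  stopifnot(from > 0, to > 0)
  d <- dim(alpha)
  P1 <- if (is.null(d)) length(alpha) else d[length(d)]
  fac <- (to / from)^(seq_len(P1) - 1L)
  if (is.null(d)) return(alpha * fac)
  sweep(alpha, length(d), fac, "*")
}
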