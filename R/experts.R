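#' Polynomial design matrix in (rescaled) visit time
#'
#' Row `j` is `(1, t_j, ..., t_j^P)`.
#'
#' @param times numeric visit times (already rescaled if applicable).
#' @param P polynomial degree, `P >= 0`.
#' @return `length(times) x (P+1)` matrix.
#' @export
polynomial_design <- function(times, P) {
  if (length(P) != 1L || is.na(P) || P < 0) stop("P must be a non-negative integer")
  P <- as.integer(P)
  if (any(!is.finite(times))) stop("times must be finite")
  outer(as.numeric(times), 0:P, `^`)
}

# Per-cell cluster means for all classes: list over k of (n_cells x V)
# matrices, from the stacked design of the clinical container.
expert_cell_means <- function(design, alpha) {
  K <- dim(alpha)[1]
  lapply(seq_len(K), function(k) {
    # alpha[k, , ]: V x (P+1); means = design %*% t(alpha_k)
    ak <- matrix(alpha[k, , ], nrow = dim(alpha)[2])
    design %*% t(ak)
  })
}

clinical_design <- function(clinical, P, time_scale) {
  polynomial_design(clinical$visit_time / time_scale, P)
}

#' Expert log-likelihood matrix
#'
#' `N x K` matrix whose `(i, k)` entry is the Gaussian trajectory
#' log-likelihood of patient `i` under cluster `k`:
#' `sum_v sum_j log dnorm(y_iv(j); sum_p alpha_vkp u_ij^p, sigma_vk)` over
#' non-missing cells, with `u = t / time_scale`.  Patients with no observed
#' cells get 0 (they inform the fit only through the gate).
#'
#' @param clinical [longitudinal_data()] object.
#' @param params [model_parameters()] object.
#' @return `N x K` numeric matrix.
#' @export
expert_loglik_matrix <- function(clinical, params) {
  X <- clinical_design(clinical, params$P, params$time_scale)
  Y <- clinical$values
  pidx <- clinical$visit_patient
  N <- n_patients(clinical)
  K <- params$K
  means <- expert_cell_means(X, params$alpha)
  out <- matrix(0, N, K)
  obs <- !is.na(Y)
  for (k in seq_len(K)) {
    sd_mat <- matrix(params$sigma[k, ], nrow(Y), ncol(Y), byrow = TRUE)
    ll <- matrix(0, nrow(Y), ncol(Y))
    ll[obs] <- stats::dnorm(Y[obs], mean = means[[k]][obs], sd = sd_mat[obs],
                            log = TRUE)
    out[, k] <- rowsum(rowSums(ll), pidx, reorder = TRUE)[, 1L]
  }
  out
}

#' Expert log-likelihood of one patient under one cluster
#'
#' @inheritParams expert_loglik_matrix
#' @param i patient index.
#' @param k cluster index.
#' @return Scalar log-likelihood; 0 (with a warning) if the patient has no
#'   observed cells.
#' @export
expert_loglik <- function(clinical, params, i, k) {
  rows <- clinical$visit_patient == i
  if (!any(!is.na(clinical$values[rows, , drop = FALSE]))) {
    warning("patient ", clinical$patient_ids[i],
            " has no observed clinical cells; expert log-likelihood is 0")
    return(0)
  }
  expert_loglik_matrix(clinical, params)[i, k]
}

#' Weighted maximum-likelihood update of the trajectory experts
#'
#' For each cluster `k` and clinical variable `v`, solves the
#' responsibility-weighted least-squares regression of the observed cells on
#' the polynomial time design (a patient's weight `tau_ik` repeats across
#' its cells), and sets `sigma_vk` to the square root of the weighted mean
#' squared residual (maximum likelihood, no degrees-of-freedom correction),
#' floored at `sigma_min`.
#'
#' @param clinical [longitudinal_data()] object.
#' @param tau `N x K` responsibilities (matrix or [responsibilities()]).
#' @param P polynomial degree.
#' @param time_scale positive scalar used to rescale times before powers.
#' @param sigma_min lower floor for the residual scales.
#' @param weight_floor minimum total weight of a cluster; below it a
#'   degenerate-cluster error is raised.
#' @return `list(alpha = K x V x (P+1) array, sigma = K x V matrix)`.
#' @export
update_expert_params <- function(clinical, tau, P, time_scale = 1,
                                 sigma_min = 1e-4, weight_floor = 1e-8) {
  tau <- as_tau(tau)
  K <- ncol(tau)
  V <- length(clinical$variable_names)
  X <- clinical_design(clinical, P, time_scale)
  Y <- clinical$values
  pidx <- clinical$visit_patient
  wtot <- colSums(tau)
  if (any(wtot <= weight_floor)) {
    stop("degenerate cluster: total responsibility weight below floor ",
         "(cluster ", which.min(wtot), ")", call. = FALSE)
  }
  alpha <- array(NA_real_, dim = c(K, V, P + 1L))
  sigma <- matrix(NA_real_, K, V)
  for (v in seq_len(V)) {
    obs <- which(!is.na(Y[, v]))
    if (length(obs) <= P) stop("variable ", v, ": fewer observed cells than coefficients")
    Xv <- X[obs, , drop = FALSE]
    yv <- Y[obs, v]
    pv <- pidx[obs]
    for (k in seq_len(K)) {
      w <- tau[pv, k]
      sw <- sum(w)
      if (sw <= weight_floor) {
        stop("degenerate cluster: no observed weight for cluster ", k,
             ", variable ", v, call. = FALSE)
      }
      fit <- stats::lm.wfit(Xv, yv, w)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      alpha[k, v, ] <- cf
      sigma[k, v] <- max(sqrt(sum(w * fit$residuals^2) / sw), sigma_min)
    }
  }
  list(alpha = alpha, sigma = sigma)
}
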