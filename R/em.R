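#' EM / CEM configuration
#'
#' @param K number of clusters (>= 1).
#' @param P polynomial degree of the trajectory experts.
#' @param mode `"cem"` (classification EM, the default: responsibilities are
#'   replaced by hard argmax assignments between the E and M steps) or
#'   `"em"` (soft responsibilities throughout).
#' @param n_init number of random hard-partition initializations.
#' @param init_iter iterations run from each initialization before the best
#'   (by penalized objective) is continued to convergence; `NULL` runs every
#'   initialization to convergence and retains the lowest BIC.
#' @param init_gate `"constant"` (default) advances the short
#'   initialization runs with genetics-free constant mixing weights (the
#'   gate is uninformative from a random partition, and skipping its
#'   cross-validated refit there makes the multi-start cheap); `"full"`
#'   runs the complete M step from the first iteration.
#' @param max_iter iteration cap per run.
#' @param tol relative penalized-objective change declaring convergence.
#' @param lambda_policy `"cv"` (penalty re-selected by cross-validation at
#'   every M step) or `"fixed"` (use `lambda`).
#' @param lambda fixed penalty when `lambda_policy = "fixed"`.
#' @param n_folds cross-validation folds for the in-loop penalty selection.
#' @param nlambda,lambda_min_ratio geometry of the penalty grid (geometric,
#'   from `lambda_max` down to `lambda_min_ratio * lambda_max`).
#' @param dfmax cap on the number of nonzero gating coefficients explored
#'   along the penalty path; `NULL` chooses `max(100, 0.4 N)`.
#' @param seed master seed; every stochastic element (initial partitions,
#'   fold assignments) derives its own seed from it.
#' @param sigma_min floor on expert residual scales.
#' @param weight_floor minimal total responsibility of a cluster before it is
#'   declared degenerate.
#' @param time_scale positive scalar dividing visit times before powers;
#'   `NULL` uses the cohort maximum `|t|`.
#' @param standardize standardize markers internally in the gating fit.
#' @param reference_class gating class pinned to zero.
#' @return list of class `em_config`.
#' @export
em_config <- function(K, P = 1L, mode = c("cem", "em"), n_init = 10L,
                      init_iter = 20L, init_gate = c("constant", "full"),
                      max_iter = 200L, tol = 1e-6,
                      lambda_policy = c("cv", "fixed"), lambda = NULL,
                      n_folds = 5L, nlambda = 100L, lambda_min_ratio = 1e-3,
                      dfmax = NULL, seed = 1L, sigma_min = 1e-4,
                      weight_floor = 1e-3, time_scale = NULL,
                      standardize = TRUE, reference_class = 1L) {
  mode <- match.arg(mode)
  init_gate <- match.arg(init_gate)
  lambda_policy <- match.arg(lambda_policy)
  if (K < 1L) stop("K must be >= 1")
  if (n_init < 1L) stop("n_init must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  if (lambda_policy == "fixed" && (is.null(lambda) || lambda < 0)) {
    stop("lambda_policy = 'fixed' requires lambda >= 0")
  }
  structure(list(K = as.integer(K), P = as.integer(P), mode = mode,
                 n_init = as.integer(n_init),
                 init_iter = if (is.null(init_iter)) NULL else as.integer(init_iter),
                 init_gate = init_gate,
                 max_iter = as.integer(max_iter), tol = tol,
                 lambda_policy = lambda_policy, lambda = lambda,
                 n_folds = as.integer(n_folds), nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, dfmax = dfmax,
                 seed = as.integer(seed), sigma_min = sigma_min,
                 weight_floor = weight_floor, time_scale = time_scale,
                 standardize = standardize,
                 reference_class = as.integer(reference_class)),
            class = "em_config")
}

# deterministic integer seed stream derived from a master seed
seed_for <- function(master, ...) {
  v <- c(master, ...)
  x <- 0
  for (t in v) x <- (x * 31 + as.numeric(t)) %% 2147483629
  as.integer(x + 1)
}

#' E step: posterior responsibilities
#'
#' `tau_ik` proportional to `eta_k(g_i) * prod_v prod_j f_k(y_iv(j))`,
#' computed in log space with max-subtraction.
#'
#' @param clinical [longitudinal_data()] object.
#' @param geno [genotype_matrix()] (row-aligned) or plain matrix.
#' @param params [model_parameters()] object.
#' @return [responsibilities()] object.
#' @export
e_step <- function(clinical, geno, params) {
  lp <- e_step_logpost(clinical, geno, params)
  bad <- !is.finite(apply(lp, 1L, max))
  if (any(bad)) {
    stop("non-finite log-posterior for patient(s): ",
         paste(clinical$patient_ids[bad], collapse = ", "))
  }
  responsibilities(softmax_rows(lp))
}

e_step_logpost <- function(clinical, geno, params) {
  leta <- log_softmax_rows(
    sweep(geno_values(geno) %*% t(params$omega), 2L, params$omega0, `+`))
  leta + expert_loglik_matrix(clinical, params)
}

#' Hard classification of responsibilities
#'
#' Argmax per row; ties broken by the lowest class index.
#' @param tau responsibilities (matrix or [responsibilities()]).
#' @return integer labels.
#' @export
classify <- function(tau) {
  max.col(as_tau(tau), ties.method = "first")
}

# penalty term on the standardized-marker scale, matching the solver
penalty_norm <- function(omega, marker_sd) {
  sum(abs(sweep(omega, 2L, marker_sd, `*`)))
}

#' Penalized complete-data objective
#'
#' The expected (or classified) complete-data log-likelihood minus the
#' gating penalty:
#' `sum_i sum_k tau_ik (log eta_ik + loglik_ik) - N * lambda * pen(omega)`,
#' where `pen` is the L1 norm of the gating coefficients on the
#' standardized-marker scale (the scale on which the M-step solver applies
#' `lambda`; the factor `N` aligns the solver's `1/N` likelihood scaling
#' with the unscaled complete-data term).
#'
#' @inheritParams e_step
#' @param tau responsibilities or hard labels (integer vector).
#' @param lambda penalty value.
#' @param marker_sd per-marker standard deviations used by the penalty;
#'   `NULL` recomputes them from `geno` (population sd, constant markers
#'   get 1).
#' @return scalar objective value.
#' @export
penalized_objective <- function(clinical, geno, tau, params, lambda,
                                marker_sd = NULL) {
  G <- geno_values(geno)
  if (is.null(dim(tau)) && !inherits(tau, "responsibilities")) {
    tau <- labels_to_tau(as.integer(tau), params$K)
  } else {
    tau <- as_tau(tau)
  }
  if (is.null(marker_sd)) {
    if (params$standardize_penalty %||% TRUE) {
      marker_sd <- marker_scale_stats(G)$scale
      marker_sd[marker_sd == 0] <- 1
    } else {
      marker_sd <- rep(1, ncol(G))
    }
  }
  leta <- log_softmax_rows(sweep(G %*% t(params$omega), 2L, params$omega0, `+`))
  ll <- expert_loglik_matrix(clinical, params)
  sum(tau * (leta + ll)) -
    nrow(G) * lambda * penalty_norm(params$omega, marker_sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observed-data log-likelihood of the mixture
#'
#' `sum_i log sum_k eta_k(g_i) prod_vj f_k(y_iv(j))`, log-sum-exp
#' stabilized.
#' @inheritParams e_step
#' @return scalar.
#' @export
observed_loglik <- function(clinical, geno, params) {
  lp <- e_step_logpost(clinical, geno, params)
  m <- apply(lp, 1L, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Parameter count and BIC of a gated mixture fit
#'
#' `nu = K V (P+1) + K V + (K-1) + #nonzero(omega)`: trajectory
#' coefficients, residual scales, free gating intercepts, and selected
#' gating coefficients.  `BIC = -2 loglik + nu log N` with `N` the number
#' of patients.
#'
#' @param K,V,P model dimensions.
#' @param n_nonzero number of nonzero gating coefficients.
#' @return integer parameter count.
#' @export
count_parameters <- function(K, V, P, n_nonzero = 0L) {
  as.integer(K * V * (P + 1L) + K * V + (K - 1L) + n_nonzero)
}

#' @rdname count_parameters
#' @param fit a `gatemix_fit` object.
#' @param clinical the clinical container the fit was computed on.
#' @export
mixture_bic <- function(fit, clinical) {
  N <- n_patients(clinical)
  nu <- count_parameters(fit$params$K, fit$params$V, fit$params$P,
                         sum(fit$params$omega != 0))
  -2 * fit$loglik + nu * log(N)
}

# ---- engine internals -----------------------------------------------------

# one EM/CEM run from a responsibility state; returns on convergence,
# iteration cap, or degeneracy (status field)
run_engine <- function(clinical, geno, cfg, tau, run_seed, n_iter_cap,
                       iter_offset = 0L, trace = NULL, gate_constant = FALSE,
                       gate_fixed = NULL, experts_fixed = NULL) {
  G <- geno_values(geno)
  N <- nrow(G); L <- ncol(G); K <- cfg$K
  marker_sd <- marker_scale_stats(G)$scale
  marker_sd[marker_sd == 0] <- 1
  if (!cfg$standardize) marker_sd <- rep(1, L)
  dfmax <- cfg$dfmax %||% max(100L, round(0.4 * N))
  time_scale <- cfg$time_scale
  labels_prev <- classify(tau)
  obj_prev <- -Inf
  converged <- FALSE
  params <- NULL; gate_fit <- NULL; lambda_q <- 0
  if (is.null(trace)) {
    trace <- data.frame(iter = integer(0), lambda = numeric(0),
                        support_size = integer(0), objective = numeric(0))
  }
  q <- iter_offset
  status <- "ok"
  repeat {
    q <- q + 1L
    # ---- M step: experts ----
    experts <- if (!is.null(experts_fixed)) experts_fixed else tryCatch(
      update_expert_params(clinical, tau, cfg$P, time_scale,
                           cfg$sigma_min, cfg$weight_floor),
      error = function(e) e)
    if (inherits(experts, "error")) { status <- "degenerate"; break }
    # ---- M step: gate ----
    if (!is.null(gate_fixed)) {
      gate_fit <- list(omega0 = gate_fixed$omega0, omega = gate_fixed$omega,
                       support = support_from_omega(gate_fixed$omega,
                                                    cfg$reference_class),
                       lambda = 0, df = sum(gate_fixed$omega != 0))
      lambda_q <- 0
    } else if (gate_constant || K == 1L) {
      pk <- pmax(colMeans(as_tau(tau)), 1e-10)
      omega0 <- log(pk / pk[cfg$reference_class])
      omega0 <- omega0 - omega0[cfg$reference_class]
      omega <- matrix(0, K, L)
      gate_fit <- list(omega0 = omega0, omega = omega,
                       support = data.frame(class = integer(0),
                                            marker = integer(0)),
                       lambda = 0, df = 0L)
      lambda_q <- 0
    } else if (cfg$lambda_policy == "cv") {
      sel <- select_lambda_cv(G, tau, n_folds = cfg$n_folds,
                              seed = seed_for(run_seed, 1000L + q),
                              reference_class = cfg$reference_class,
                              nlambda = cfg$nlambda,
                              lambda_min_ratio = cfg$lambda_min_ratio,
                              standardize = cfg$standardize, dfmax = dfmax)
      gate_fit <- sel$fit
      lambda_q <- sel$lambda
    } else {
      gate_fit <- fit_sparse_multinomial(G, tau, cfg$lambda,
                                         reference_class = cfg$reference_class,
                                         standardize = cfg$standardize)
      lambda_q <- gate_fit$lambda
    }
    params <- model_parameters(experts$alpha, experts$sigma,
                               gate_fit$omega0, gate_fit$omega,
                               reference_class = cfg$reference_class,
                               time_scale = time_scale)
    # ---- E step (+ classification) ----
    lp <- e_step_logpost(clinical, G, params)
    if (any(!is.finite(apply(lp, 1L, max)))) { status <- "numeric"; break }
    tau_soft <- softmax_rows(lp)
    if (cfg$mode == "cem") {
      labels <- classify(tau_soft)
      if (any(tabulate(labels, K) == 0L)) { status <- "degenerate"; break }
      tau_new <- labels_to_tau(labels, K)
    } else {
      labels <- classify(tau_soft)
      if (any(colSums(tau_soft) < cfg$weight_floor)) {
        status <- "degenerate"; break
      }
      tau_new <- tau_soft
    }
    # ---- penalized objective (monotone for fixed lambda) ----
    pen <- N * lambda_q * penalty_norm(params$omega, marker_sd)
    obj <- if (cfg$mode == "cem") {
      sum(lp[cbind(seq_len(N), labels)]) - pen
    } else {
      m <- apply(lp, 1L, max)
      sum(m + log(rowSums(exp(lp - m)))) - pen
    }
    trace <- rbind(trace, data.frame(iter = q, lambda = lambda_q,
                                     support_size = nrow(gate_fit$support),
                                     objective = obj))
    same_partition <- cfg$mode == "cem" && identical(labels, labels_prev)
    rel <- abs(obj - obj_prev) / (abs(obj_prev) + 1e-10)
    tau <- tau_new
    labels_prev <- labels
    if (same_partition || (is.finite(obj_prev) && rel < cfg$tol)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    if (q - iter_offset >= n_iter_cap) break
  }
  list(status = status, params = params, tau = tau,
       tau_soft = if (exists("tau_soft", inherits = FALSE)) tau_soft else NULL,
       labels = labels_prev, gate_fit = gate_fit, lambda = lambda_q,
       trace = trace, converged = converged, n_iter = q)
}

random_partition <- function(N, K, seed) {
  with_local_seed(seed, sample(rep_len(seq_len(K), N)))
}

finalize_fit <- function(clinical, geno, cfg, run, init_id, attempt_seed) {
  G <- geno_values(geno)
  N <- nrow(G)
  labels <- run$labels
  support <- run$gate_fit$support
  params_pen <- run$params
  if (cfg$K == 1L || nrow(support) >= 0L) {
    db <- if (cfg$K == 1L) {
      list(omega0 = 0, omega = matrix(0, 1L, ncol(G)),
           wald_ci = data.frame(), non_wald = FALSE)
    } else {
      debias_refit(G, labels, support, cfg$K, cfg$reference_class)
    }
  }
  # reported parameters carry the debiased gate (unpenalized refit on the
  # selected support, which the refit preserves); log-likelihood and BIC
  # are evaluated at these debiased parameters, consistently across
  # initializations and across (K, P) grid cells
  params <- model_parameters(params_pen$alpha, params_pen$sigma,
                             db$omega0, db$omega,
                             reference_class = cfg$reference_class,
                             time_scale = params_pen$time_scale)
  ll <- observed_loglik(clinical, G, params)
  nu <- count_parameters(cfg$K, params$V, cfg$P, nrow(support))
  structure(list(
    params = params,
    params_penalized = params_pen,
    tau = run$tau_soft %||% as_tau(run$tau),
    labels = labels,
    objective_trace = run$trace,
    loglik = ll,
    bic = -2 * ll + nu * log(N),
    nu = nu,
    lambda = run$lambda,
    support = support,
    debias = db,
    n_iter = run$n_iter,
    converged = run$converged,
    seed = cfg$seed,
    init_id = init_id,
    init_seed = attempt_seed,
    config = cfg
  ), class = "gatemix_fit")
}

#' @export
print.gatemix_fit <- function(x, ...) {
  cat(sprintf(paste0("gatemix_fit: K=%d, P=%d (%s), %d iterations%s\n",
                     "  loglik %.2f, BIC %.2f (nu=%d), lambda %.4g, ",
                     "support %d coefficient(s) on %d marker(s)\n"),
              x$params$K, x$params$P, x$config$mode, x$n_iter,
              if (x$converged) "" else " (not converged)",
              x$loglik, x$bic, x$nu, x$lambda, nrow(x$support),
              length(unique(x$support$marker))))
  invisible(x)
}

#' Fit the gated trajectory mixture
#'
#' Runs the modified EM (or classification EM) algorithm: repeated E steps,
#' optional hard classification, and M steps that refit the trajectory
#' experts in closed form and the sparse multinomial gate with the penalty
#' re-selected by cross-validation.  `n_init` random hard partitions are
#' each advanced `init_iter` iterations; the most promising (highest
#' penalized objective) is continued to convergence (with `init_iter =
#' NULL`, every start runs to convergence and the lowest-BIC run wins).
#' After convergence the selected gating coefficients are re-estimated
#' without penalty ([debias_refit()]) and returned in `$debias` with Wald
#' intervals; the reported log-likelihood and BIC are evaluated at the
#' debiased parameters.
#'
#' @param clinical [longitudinal_data()] object.
#' @param geno [genotype_matrix()] object (same cohort).
#' @param config an [em_config()] object.
#' @return A `gatemix_fit` object; see [em_config()] for the knobs and
#'   [finalize_fit] internals for the fields.
#' @export
fit_mixture <- function(clinical, geno, config) {
  aligned <- validate_aligned(clinical, geno)
  clinical <- aligned$clinical; geno <- aligned$geno
  cfg <- config
  N <- n_patients(clinical)
  if (N <= cfg$K) stop("need more patients than clusters")
  if (is.null(cfg$time_scale)) {
    cfg$time_scale <- max(abs(clinical$visit_time), 1e-12)
  }

  if (cfg$K == 1L) {
    tau <- matrix(1, N, 1L)
    run <- run_engine(clinical, geno, cfg, tau, run_seed = cfg$seed,
                      n_iter_cap = 1L)
    run$converged <- TRUE
    return(finalize_fit(clinical, geno, cfg, run, 1L, cfg$seed))
  }

  shorts <- list()
  for (init in seq_len(cfg$n_init)) {
    run <- NULL
    for (attempt in 1:3) {
      s <- seed_for(cfg$seed, init, attempt)
      labels0 <- random_partition(N, cfg$K, s)
      cap <- cfg$init_iter %||% cfg$max_iter
      const_gate <- !is.null(cfg$init_iter) && cfg$init_gate == "constant"
      cand <- run_engine(clinical, geno, cfg, labels_to_tau(labels0, cfg$K),
                         run_seed = s, n_iter_cap = cap,
                         gate_constant = const_gate)
      if (cand$status == "ok") { run <- cand; run$attempt_seed <- s; break }
    }
    if (!is.null(run)) {
      run$init_id <- init
      shorts[[length(shorts) + 1L]] <- run
    }
  }
  if (length(shorts) == 0L) {
    stop("all initializations failed (degenerate clusters); ",
         "consider smaller K")
  }

  if (is.null(cfg$init_iter)) {
    # full runs: retain the lowest BIC after debiasing
    fits <- lapply(shorts, function(r)
      finalize_fit(clinical, geno, cfg, r, r$init_id, r$attempt_seed))
    return(fits[[which.min(vapply(fits, function(f) f$bic, numeric(1)))]])
  }

  ord <- order(vapply(shorts, function(r) -utils::tail(r$trace$objective, 1L),
                      numeric(1)))
  for (j in ord[seq_len(min(3L, length(ord)))]) {
    r <- shorts[[j]]
    cont <- run_engine(clinical, geno, cfg, as_tau(r$tau),
                       run_seed = r$attempt_seed,
                       n_iter_cap = max(1L, cfg$max_iter - r$n_iter),
                       iter_offset = r$n_iter, trace = r$trace)
    if (cont$status == "ok") {
      return(finalize_fit(clinical, geno, cfg, cont, r$init_id,
                          r$attempt_seed))
    }
  }
  stop("engine failed to converge from every retained initialization")
}

#' Two-step baseline: trajectory-only clustering, then sparse gate
#'
#' Stage 1 fits the mixture with constant (genetics-free) mixing weights
#' `pi_k`, updated as responsibility means each M step.  Stage 2 runs the
#' cross-validated sparse multinomial gate and the debiasing refit on the
#' final hard labels.  This is the classical cluster-then-associate
#' baseline the integrative method is compared against.
#'
#' @inheritParams fit_mixture
#' @return A `gatemix_fit` object; `$stage1` holds the stage-1 trace.
#' @export
fit_two_step <- function(clinical, geno, config) {
  aligned <- validate_aligned(clinical, geno)
  clinical <- aligned$clinical; geno <- aligned$geno
  cfg <- config
  N <- n_patients(clinical)
  if (N <= cfg$K) stop("need more patients than clusters")
  if (is.null(cfg$time_scale)) {
    cfg$time_scale <- max(abs(clinical$visit_time), 1e-12)
  }
  G <- geno_values(geno)

  if (cfg$K == 1L) return(fit_mixture(clinical, geno, cfg))

  shorts <- list()
  for (init in seq_len(cfg$n_init)) {
    run <- NULL
    for (attempt in 1:3) {
      s <- seed_for(cfg$seed, 7000L, init, attempt)
      labels0 <- random_partition(N, cfg$K, s)
      cap <- cfg$init_iter %||% cfg$max_iter
      cand <- run_engine(clinical, geno, cfg, labels_to_tau(labels0, cfg$K),
                         run_seed = s, n_iter_cap = cap, gate_constant = TRUE)
      if (cand$status == "ok") { run <- cand; run$attempt_seed <- s; break }
    }
    if (!is.null(run)) { run$init_id <- init; shorts[[length(shorts) + 1L]] <- run }
  }
  if (length(shorts) == 0L) stop("all stage-1 initializations failed")

  pick_best <- function(runs) {
    runs[[which.max(vapply(runs, function(r)
      utils::tail(r$trace$objective, 1L), numeric(1)))]]
  }
  stage1 <- NULL
  if (is.null(cfg$init_iter)) {
    stage1 <- pick_best(shorts)
  } else {
    ord <- order(vapply(shorts, function(r)
      -utils::tail(r$trace$objective, 1L), numeric(1)))
    for (j in ord[seq_len(min(3L, length(ord)))]) {
      r <- shorts[[j]]
      cont <- run_engine(clinical, geno, cfg, as_tau(r$tau),
                         run_seed = r$attempt_seed,
                         n_iter_cap = max(1L, cfg$max_iter - r$n_iter),
                         iter_offset = r$n_iter, trace = r$trace,
                         gate_constant = TRUE)
      if (cont$status == "ok") {
        cont$init_id <- r$init_id; cont$attempt_seed <- r$attempt_seed
        stage1 <- cont; break
      }
    }
  }
  if (is.null(stage1)) stop("stage 1 failed to converge")

  labels <- stage1$labels
  tau_hard <- labels_to_tau(labels, cfg$K)
  dfmax <- cfg$dfmax %||% max(100L, round(0.4 * N))
  sel <- select_lambda_cv(G, tau_hard, n_folds = cfg$n_folds,
                          seed = seed_for(cfg$seed, 7999L),
                          reference_class = cfg$reference_class,
                          nlambda = cfg$nlambda,
                          lambda_min_ratio = cfg$lambda_min_ratio,
                          standardize = cfg$standardize, dfmax = dfmax)
  run <- stage1
  run$gate_fit <- sel$fit
  run$lambda <- sel$lambda
  run$params <- model_parameters(stage1$params$alpha, stage1$params$sigma,
                                 sel$fit$omega0, sel$fit$omega,
                                 reference_class = cfg$reference_class,
                                 time_scale = cfg$time_scale)
  out <- finalize_fit(clinical, geno, cfg, run, stage1$init_id,
                      stage1$attempt_seed)
  out$stage1 <- list(trace = stage1$trace, pi = colMeans(labels_to_tau(labels, cfg$K)))
  out
}
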