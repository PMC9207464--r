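#' Replicated simulation benchmark of the subtyping methods
#'
#' Repeats: simulate a dataset from `scenario`, run each requested method,
#' score clustering quality (ARI against the simulated labels) and marker
#' selection (pooled sensitivity/specificity against the active support).
#'
#' Methods:
#' * `integrative` — the full gated mixture ([fit_mixture()]).
#' * `two_step` — trajectory-only clustering then sparse gate
#'   ([fit_two_step()]).
#' * `oracle_integrative` — classification with every parameter at truth.
#' * `semi_oracle_integrative` — gate fixed at the true coefficients,
#'   trajectory experts estimated.
#' * `oracle_two_step` — trajectory experts fixed at truth, constant
#'   weights; the sparse gate is fitted on the resulting labels.
#'
#' @param scenario a [simulation_config()]; per-replicate seeds derive from
#'   `seed`.
#' @param n_replicates number of simulated replicates.
#' @param methods subset of the method names above.
#' @param config an [em_config()] template (its `K`, `P` should match the
#'   scenario; its `seed` is re-derived per replicate).
#' @param seed master seed.
#' @return list of class `gatemix_benchmark`: `per_replicate` (data.frame:
#'   method, replicate, ari, n_selected), `pooled` (data.frame: method,
#'   mean_ari, sensitivity, specificity), `selection_counts` (per-method
#'   named list), `n_replicates`, `seed`.
#' @export
run_benchmark <- function(scenario, n_replicates = 25L,
                          methods = c("integrative", "two_step"),
                          config = em_config(K = scenario$K, P = scenario$P),
                          seed = 1L) {
  known <- c("integrative", "two_step", "oracle_integrative",
             "semi_oracle_integrative", "oracle_two_step")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "))
  }
  per <- list()
  sel_lists <- stats::setNames(
    replicate(length(methods), list(), simplify = FALSE), methods)
  aris <- stats::setNames(
    replicate(length(methods), numeric(0), simplify = FALSE), methods)
  for (r in seq_len(n_replicates)) {
    sc <- scenario
    sc$seed <- seed_for(seed, 31L, r)
    ds <- simulate_dataset(sc)
    for (m in methods) {
      cfg <- config
      cfg$seed <- seed_for(seed, 37L, r, match(m, known))
      res <- run_benchmark_method(ds, m, cfg)
      ari <- adjusted_rand_index(ds$true_labels, res$labels)
      aris[[m]] <- c(aris[[m]], ari)
      if (!is.null(res$selected)) {
        sel_lists[[m]][[length(sel_lists[[m]]) + 1L]] <- res$selected
      }
      per[[length(per) + 1L]] <- data.frame(
        method = m, replicate = r, ari = ari,
        n_selected = if (is.null(res$selected)) NA_integer_
                     else length(res$selected))
    }
  }
  L <- scenario$L
  truth <- sim_active_support(scenario)
  pooled <- do.call(rbind, lapply(methods, function(m) {
    if (length(sel_lists[[m]])) {
      sm <- selection_metrics(truth, sel_lists[[m]], L)
      data.frame(method = m, mean_ari = mean(aris[[m]]),
                 sensitivity = sm$sensitivity, specificity = sm$specificity)
    } else {
      data.frame(method = m, mean_ari = mean(aris[[m]]),
                 sensitivity = NA_real_, specificity = NA_real_)
    }
  }))
  counts <- lapply(methods, function(m) {
    if (length(sel_lists[[m]]))
      selection_metrics(truth, sel_lists[[m]], L)$selection_counts
    else NULL
  })
  names(counts) <- methods
  structure(list(per_replicate = do.call(rbind, per), pooled = pooled,
                 selection_counts = counts, n_replicates = n_replicates,
                 seed = seed),
            class = "gatemix_benchmark")
}

run_benchmark_method <- function(ds, method, cfg) {
  clinical <- ds$clinical; geno <- ds$geno
  tp <- ds$true_params
  if (method == "integrative") {
    fit <- fit_mixture(clinical, geno, cfg)
    return(list(labels = fit$labels, selected = selected_markers(fit)))
  }
  if (method == "two_step") {
    fit <- fit_two_step(clinical, geno, cfg)
    return(list(labels = fit$labels, selected = selected_markers(fit)))
  }
  if (method == "oracle_integrative") {
    labels <- classify(e_step(clinical, geno, tp))
    return(list(labels = labels, selected = NULL))
  }
  if (method == "semi_oracle_integrative") {
    fit <- oracle_engine_fit(clinical, geno, cfg,
                             gate_fixed = list(omega0 = tp$omega0,
                                               omega = tp$omega),
                             time_scale = tp$time_scale)
    return(list(labels = fit$labels, selected = NULL))
  }
  if (method == "oracle_two_step") {
    fit <- oracle_engine_fit(clinical, geno, cfg, gate_constant = TRUE,
                             experts_fixed = list(alpha = tp$alpha,
                                                  sigma = tp$sigma),
                             time_scale = tp$time_scale)
    tau_hard <- labels_to_tau(fit$labels, cfg$K)
    sel <- select_lambda_cv(geno, tau_hard, n_folds = cfg$n_folds,
                            seed = seed_for(cfg$seed, 811L),
                            reference_class = cfg$reference_class,
                            nlambda = cfg$nlambda,
                            lambda_min_ratio = cfg$lambda_min_ratio,
                            dfmax = cfg$dfmax %||% max(100L, round(0.4 * n_patients(clinical))))
    return(list(labels = fit$labels,
                selected = sort(unique(sel$fit$support$marker))))
  }
  stop("unhandled method ", method)
}

# multi-start engine run with some parameter blocks frozen at the truth
oracle_engine_fit <- function(clinical, geno, cfg, gate_fixed = NULL,
                              experts_fixed = NULL, gate_constant = FALSE,
                              time_scale = NULL) {
  cfg$time_scale <- time_scale %||% max(abs(clinical$visit_time), 1e-12)
  N <- n_patients(clinical)
  best <- NULL
  for (init in seq_len(cfg$n_init)) {
    for (attempt in 1:3) {
      s <- seed_for(cfg$seed, 900L, init, attempt)
      labels0 <- random_partition(N, cfg$K, s)
      run <- run_engine(clinical, geno, cfg, labels_to_tau(labels0, cfg$K),
                        run_seed = s, n_iter_cap = cfg$max_iter,
                        gate_constant = gate_constant,
                        gate_fixed = gate_fixed,
                        experts_fixed = experts_fixed)
      if (run$status == "ok") break
      run <- NULL
    }
    if (!is.null(run)) {
      obj <- utils::tail(run$trace$objective, 1L)
      if (is.null(best) || obj > best$obj) best <- list(run = run, obj = obj)
    }
  }
  if (is.null(best)) stop("all oracle-variant initializations failed")
  best$run
}

#' Write a benchmark report as CSV files
#' @param bench a `gatemix_benchmark`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_benchmark_report <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "per_replicate.csv")
  p2 <- file.path(dir, "pooled.csv")
  utils::write.csv(bench$per_replicate, p1, row.names = FALSE)
  utils::write.csv(bench$pooled, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
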