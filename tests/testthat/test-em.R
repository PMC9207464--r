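test_that("the E step reproduces hand-computed posteriors", {
  ds <- small_instance(1)
  # K = 1: trivially all ones
  p1 <- model_parameters(array(0, c(1, 2, 2)), matrix(1, 1, 2), 0,
                         matrix(0, 1, 5), time_scale = 500)
  expect_equal(e_step(ds$clinical, ds$geno, p1)$tau,
               matrix(1, 40, 1), ignore_attr = TRUE)
  # gate-only posterior when expert likelihoods are identical across classes
  p2 <- make_small_params(2, 2, 5, time_scale = 500)
  p2$alpha[2, , ] <- p2$alpha[1, , ]
  p2$sigma[2, ] <- p2$sigma[1, ]
  tau <- e_step(ds$clinical, ds$geno, p2)$tau
  expect_equal(tau, gating_probs(ds$geno, p2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # equal gate, expert log-likelihoods (-1, -3): softmax gives
  # (e^2, 1) / (1 + e^2)
  expect_equal(gatemix:::softmax_rows(matrix(log(0.5) + c(-1, -3), 1)),
               matrix(c(exp(2), 1) / (1 + exp(2)), 1), tolerance = 1e-12)
})

test_that("E step posteriors match a naive per-cell oracle", {
  ds <- small_instance(2)
  p <- make_small_params(2, 2, 5, seed = 3, time_scale = 500)
  lp_naive <- naive_logpost(ds$clinical, ds$geno, p)
  tau <- e_step(ds$clinical, ds$geno, p)$tau
  expect_equal(tau, gatemix:::softmax_rows(lp_naive), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(tau) - 1)), 1e-10)
})

test_that("classification takes the argmax with lowest-index ties", {
  expect_equal(classify(matrix(c(0.2, 0.8), 1)), 2L)
  expect_equal(classify(matrix(c(0.5, 0.5), 1)), 1L)
  expect_equal(classify(rbind(c(0.1, 0.6, 0.3), c(1 / 3, 1 / 3, 1 / 3))),
               c(2L, 1L))
})

test_that("penalized objective and observed log-likelihood match naive sums", {
  ds <- small_instance(3)
  p <- make_small_params(2, 2, 5, seed = 5, time_scale = 500)
  tau <- e_step(ds$clinical, ds$geno, p)$tau
  lp <- naive_logpost(ds$clinical, ds$geno, p)
  sdv <- apply(ds$geno$values, 2, function(x) sqrt(mean((x - mean(x))^2)))
  lam <- 0.07
  naive_obj <- sum(tau * lp) -
    40 * lam * sum(abs(sweep(p$omega, 2, sdv, `*`)))
  expect_equal(penalized_objective(ds$clinical, ds$geno, tau, p, lam),
               naive_obj, tolerance = 1e-10)
  # linear in lambda at fixed parameters
  o1 <- penalized_objective(ds$clinical, ds$geno, tau, p, lam)
  o2 <- penalized_objective(ds$clinical, ds$geno, tau, p, 2 * lam)
  expect_equal(o1 - o2, 40 * lam * sum(abs(sweep(p$omega, 2, sdv, `*`))),
               tolerance = 1e-9)

  ll_naive <- sum(log(rowSums(exp(lp))))
  expect_equal(observed_loglik(ds$clinical, ds$geno, p), ll_naive,
               tolerance = 1e-8)
  # mixture bound: observed >= expected complete-data part (Jensen)
  expect_gte(observed_loglik(ds$clinical, ds$geno, p), sum(tau * lp) - 1e-9)
})

test_that("parameter counting follows the stated rule", {
  expect_equal(count_parameters(1, 1, 0, 0), 2L)
  expect_equal(count_parameters(2, 4, 1, 10), 35L)
  # zero-coefficient markers do not change the count
  expect_equal(count_parameters(3, 2, 1, 4), count_parameters(3, 2, 1, 4))
})

test_that("K = 1 fit equals a single polynomial regression", {
  ds <- small_instance(4)
  fit <- fit_mixture(ds$clinical, ds$geno, em_config(K = 1, P = 1, seed = 2))
  up <- update_expert_params(ds$clinical, matrix(1, 40, 1), P = 1,
                             time_scale = fit$params$time_scale)
  expect_equal(fit$params$alpha, up$alpha, tolerance = 1e-10)
  expect_equal(fit$params$sigma, up$sigma, tolerance = 1e-10)
  expect_equal(fit$labels, rep(1L, 40))
  expect_equal(fit$nu, count_parameters(1, 2, 1, 0))
  expect_equal(fit$bic, -2 * fit$loglik + fit$nu * log(40))
})

test_that("fixed-penalty objective traces are non-decreasing", {
  for (mode in c("cem", "em")) {
    for (r in 1:10) {
      ds <- small_instance(100 + r)
      cfg <- em_config(K = 2, P = 1, mode = mode, n_init = 2,
                       init_iter = 1, init_gate = "full",
                       lambda_policy = "fixed", lambda = 0.05,
                       seed = r, max_iter = 40)
      fit <- fit_mixture(ds$clinical, ds$geno, cfg)
      tr <- fit$objective_trace$objective
      expect_gte(min(diff(tr)), -1e-8 * max(1, abs(tr[1])))
    }
  }
})

test_that("CEM reaches a partition fixed point", {
  ds <- small_instance(7)
  fit <- fit_mixture(ds$clinical, ds$geno,
                     em_config(K = 2, P = 1, seed = 5, max_iter = 60))
  # one more E/classify cycle at the converged penalized parameters leaves
  # the partition unchanged
  relab <- classify(e_step(ds$clinical, ds$geno, fit$params_penalized))
  expect_equal(relab, fit$labels)
  expect_true(fit$converged)
})

test_that("well-separated data are recovered exactly from every seed", {
  for (r in 1:5) {
    ds <- simulate_dataset(strong_toy_config(seed = 40 + r))
    fit <- fit_mixture(ds$clinical, ds$geno,
                       em_config(K = 2, P = 1, seed = r, n_init = 4))
    expect_equal(adjusted_rand_index(ds$true_labels, fit$labels), 1)
  }
})

test_that("permuting the initial labels only permutes the solution", {
  ds <- simulate_dataset(strong_toy_config(seed = 60))
  cfg <- em_config(K = 2, P = 1, seed = 3, lambda_policy = "fixed",
                   lambda = 0.05, max_iter = 40)
  cfg$time_scale <- 4000
  labels0 <- gatemix:::random_partition(100, 2, seed = 17)
  r1 <- gatemix:::run_engine(ds$clinical, ds$geno, cfg,
                             labels_to_tau(labels0, 2),
                             run_seed = 5, n_iter_cap = 40)
  r2 <- gatemix:::run_engine(ds$clinical, ds$geno, cfg,
                             labels_to_tau(3L - labels0, 2),
                             run_seed = 5, n_iter_cap = 40)
  expect_equal(adjusted_rand_index(r1$labels, r2$labels), 1)
  expect_equal(tail(r1$trace$objective, 1), tail(r2$trace$objective, 1),
               tolerance = 1e-6)
})

test_that("fit results honour their structural invariants", {
  ds <- small_instance(9)
  fit <- fit_mixture(ds$clinical, ds$geno, em_config(K = 2, P = 1, seed = 4))
  expect_equal(fit$labels, classify(fit$tau))
  expect_equal(fit$support,
               gatemix:::support_from_omega(fit$params$omega, 1L),
               ignore_attr = TRUE)
  expect_equal(fit$bic, -2 * fit$loglik + fit$nu * log(40))
})

test_that("the two-step baseline keeps weights constant in stage one", {
  ds <- small_instance(10)
  fit <- fit_two_step(ds$clinical, ds$geno,
                      em_config(K = 2, P = 1, seed = 6))
  expect_equal(sum(fit$stage1$pi), 1)
  # a strongly separated toy: trajectory-only clustering already matches
  # the integrative labels up to relabeling
  ds2 <- simulate_dataset(strong_toy_config(seed = 70))
  f_int <- fit_mixture(ds2$clinical, ds2$geno,
                       em_config(K = 2, P = 1, seed = 2))
  f_two <- fit_two_step(ds2$clinical, ds2$geno,
                        em_config(K = 2, P = 1, seed = 2))
  expect_equal(adjusted_rand_index(f_int$labels, f_two$labels), 1)
})

test_that("degenerate requests fail loudly", {
  ds <- small_instance(11)
  expect_error(fit_mixture(ds$clinical, ds$geno,
                           em_config(K = 41, P = 1)), "more patients")
})
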