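test_that("polynomial design returns direct powers", {
  expect_equal(polynomial_design(2, 2), cbind(1, 2, 4), ignore_attr = TRUE)
  expect_equal(polynomial_design(c(3, -1), 0), cbind(c(1, 1)),
               ignore_attr = TRUE)
  expect_equal(polynomial_design(c(0.5, 1), 1), rbind(c(1, 0.5), c(1, 1)),
               ignore_attr = TRUE)
  expect_error(polynomial_design(1, -1), "non-negative")
  expect_error(polynomial_design(Inf, 1), "finite")
})

test_that("expert log-likelihood matches scalar normal densities", {
  # one patient, one cell at its fitted mean with unit sd
  cl <- make_flat_clinical(2)
  p <- model_parameters(array(2, c(1, 1, 1)), matrix(1, 1, 1), 0,
                        matrix(0, 1, 1), time_scale = 1)
  expect_equal(expert_loglik(cl, p, 1, 1), -0.5 * log(2 * pi))
  # one-sd offset
  p2 <- model_parameters(array(2, c(1, 1, 1)), matrix(0.7, 1, 1), 0,
                         matrix(0, 1, 1), time_scale = 1)
  cl2 <- make_flat_clinical(2 + 0.7)
  expect_equal(expert_loglik(cl2, p2, 1, 1),
               -0.5 * log(2 * pi * 0.7^2) - 0.5)
  # two cells, P = 1: hand-summed pair of scalar densities
  cl3 <- make_clinical(c("a", "a"), c(0, 1), cbind(c(1.2, 3.1)))
  p3 <- model_parameters(array(c(1, 2), c(1, 1, 2)), matrix(0.5, 1, 1), 0,
                         matrix(0, 1, 1), time_scale = 1)
  expect_equal(expert_loglik(cl3, p3, 1, 1),
               dnorm(1.2, 1, 0.5, log = TRUE) + dnorm(3.1, 3, 0.5, log = TRUE))
})

test_that("missing cells drop out of the likelihood and trigger the warning", {
  cl <- make_clinical(c("a", "a", "b"), c(0, 1, 0),
                      cbind(c(1, NA, NA), c(NA, 2, NA)))
  p <- model_parameters(array(0, c(1, 2, 1)), matrix(1, 1, 2), 0,
                        matrix(0, 1, 1), time_scale = 1)
  ll <- expert_loglik_matrix(cl, p)
  expect_equal(ll[1, 1], dnorm(1, log = TRUE) + dnorm(2, log = TRUE))
  expect_warning(v <- expert_loglik(cl, p, 2, 1), "no observed")
  expect_equal(v, 0)
})

test_that("weighted expert update reduces to known closed forms", {
  # hard labels, P = 0: mean and ML sd of the cluster's values
  cl <- make_flat_clinical(c(1, 3, 10, 14))
  tau <- labels_to_tau(c(1, 1, 2, 2), 2)
  up <- update_expert_params(cl, tau, P = 0)
  expect_equal(as.numeric(up$alpha[, 1, 1]), c(2, 12))
  expect_equal(as.numeric(up$sigma[, 1]), c(1, 2))

  # all mass on one class equals the unweighted polynomial MLE
  set.seed(4)
  n <- 40
  tms <- runif(n, 0, 2)
  y <- 1 + 0.5 * tms - 0.3 * tms^2 + rnorm(n, 0, 0.4)
  cl2 <- make_clinical(sprintf("q%02d", 1:n), tms, cbind(y))
  up2 <- update_expert_params(cl2, matrix(1, n, 1), P = 2)
  ref <- lm(y ~ tms + I(tms^2))
  expect_equal(as.numeric(up2$alpha[1, 1, ]), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(up2$sigma[1, 1], sqrt(mean(residuals(ref)^2)),
               tolerance = 1e-8)

  # duplicating every patient and halving tau leaves estimates unchanged
  cl3 <- make_clinical(c(sprintf("q%02d", 1:n), sprintf("r%02d", 1:n)),
                       c(tms, tms), cbind(c(y, y)))
  up3 <- update_expert_params(cl3, matrix(0.5, 2 * n, 1) * 2, P = 2)
  expect_equal(up3$alpha, up2$alpha, tolerance = 1e-10)
})

test_that("degenerate clusters are rejected", {
  cl <- make_flat_clinical(c(1, 2, 3))
  tau <- cbind(c(1, 1, 1), c(0, 0, 0))
  expect_error(update_expert_params(cl, tau, P = 0), "degenerate")
})

test_that("the expert update maximizes the weighted likelihood term", {
  # M-step optimality: random perturbations never improve the tau-weighted
  # expert log-likelihood
  set.seed(11)
  for (rep in 1:5) {
    n <- 30
    tms <- runif(n, 0, 1)
    y <- rnorm(n, 1 + tms, 0.8)
    cl <- make_clinical(sprintf("p%02d", 1:n), tms, cbind(y))
    tau <- matrix(runif(n * 2), n, 2)
    tau <- tau / rowSums(tau)
    up <- update_expert_params(cl, tau, P = 1)
    base <- make_params <- function(alpha, sigma) {
      model_parameters(alpha, sigma, c(0, 0), matrix(0, 2, 1),
                       time_scale = 1)
    }
    wll <- function(alpha, sigma) {
      ll <- expert_loglik_matrix(cl, make_params(alpha, sigma))
      sum(tau * ll)
    }
    best <- wll(up$alpha, up$sigma)
    for (j in 1:10) {
      da <- up$alpha + array(rnorm(4, 0, 0.05), dim(up$alpha))
      ds <- up$sigma * exp(matrix(rnorm(2, 0, 0.05), 2, 1))
      expect_lte(wll(da, ds), best + 1e-8)
    }
  }
})

test_that("experts are recovered from labeled data at realistic size", {
  # N = 400 patients, 9 visits: compare to the per-cluster lm oracle and
  # require agreement within 3 oracle standard errors
  set.seed(21)
  N <- 400; J <- 9
  z <- rep(1:2, each = N / 2)
  tms <- runif(N * J)
  pid <- rep(sprintf("p%03d", 1:N), each = J)
  alpha_true <- rbind(c(0, 1), c(2, -1))
  sigma_true <- c(0.8, 1.2)
  zi <- rep(z, each = J)
  y <- alpha_true[zi, 1] + alpha_true[zi, 2] * tms +
    rnorm(N * J, 0, sigma_true[zi])
  cl <- make_clinical(pid, tms, cbind(y))
  up <- update_expert_params(cl, labels_to_tau(z, 2), P = 1, time_scale = 1)
  for (k in 1:2) {
    sel <- zi == k
    orc <- lm(y[sel] ~ tms[sel])
    se <- summary(orc)$coefficients[, 2]
    expect_lt(max(abs(as.numeric(up$alpha[k, 1, ]) - alpha_true[k, ]) / se), 3)
    expect_equal(up$sigma[k, 1], sigma_true[k], tolerance = 0.1)
  }
})
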