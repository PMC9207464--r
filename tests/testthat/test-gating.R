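# penalized objective of the pinned multinomial gate, on the original
# marker scale (used with standardize = FALSE fits)
pinned_objective <- function(G, tau, omega0, omega, lambda, ref = 1L) {
  scores <- sweep(G %*% t(omega), 2L, omega0, `+`)
  m <- apply(scores, 1L, max)
  leta <- scores - m - log(rowSums(exp(scores - m)))
  sum(tau * leta) / nrow(G) - lambda * sum(abs(omega[-ref, , drop = FALSE]))
}

test_that("gating probabilities follow the stabilized softmax", {
  G <- random_geno_matrix(12, 4, seed = 2)
  p0 <- list(omega0 = rep(0, 3), omega = matrix(0, 3, 4))
  expect_equal(gating_probs(G, p0), matrix(1 / 3, 12, 3),
               ignore_attr = TRUE)
  # K = 2, omega_20 = ln 3: every row (1/4, 3/4)
  p1 <- list(omega0 = c(0, log(3)), omega = matrix(0, 2, 4))
  expect_equal(gating_probs(G, p1), cbind(rep(0.25, 12), 0.75),
               ignore_attr = TRUE)
  # shift invariance of the linear scores
  om <- matrix(rnorm(12), 3, 4)
  pa <- list(omega0 = c(1, -2, 0.5), omega = om)
  pb <- list(omega0 = pa$omega0 + 7, omega = om)
  expect_equal(gating_probs(G, pa), gating_probs(G, pb), tolerance = 1e-12)
  expect_error(gating_probs(G, list(omega0 = c(0, NA), omega = om[1:2, ])),
               "finite")
})

test_that("gating probability rows sum to one for extreme coefficients", {
  set.seed(14)
  G <- random_geno_matrix(30, 5, seed = 14)
  for (r in 1:10) {
    p <- list(omega0 = runif(3, -10, 10), omega = matrix(runif(15, -10, 10), 3))
    expect_lt(max(abs(rowSums(gating_probs(G, p)) - 1)), 1e-12)
  }
})

test_that("fully penalized fit returns zero coefficients and tau-mean intercepts", {
  set.seed(3)
  G <- random_geno_matrix(40, 6, seed = 3)
  tau <- matrix(runif(40 * 3), 40, 3); tau <- tau / rowSums(tau)
  lmax <- gating_lambda_max(G, tau)
  fit <- fit_sparse_multinomial(G, tau, lmax * 1.01)
  expect_true(all(fit$omega == 0))
  expect_equal(colMeans(gating_probs(G, fit)), colMeans(tau),
               tolerance = 1e-6)
})

test_that("unpenalized fit matches the maximum-likelihood oracle", {
  skip_if_not_installed("nnet")
  set.seed(31)
  G <- random_geno_matrix(30, 2, seed = 31)
  z <- 1 + (G[, 1] + rnorm(30) > 0)
  tau <- labels_to_tau(z, 2)
  mine <- fit_sparse_multinomial(G, tau, 0, tol = 1e-13)
  d <- data.frame(z = factor(z), x1 = G[, 1], x2 = G[, 2])
  orc <- nnet::multinom(z ~ x1 + x2, d, trace = FALSE, maxit = 1000,
                        reltol = 1e-14)
  expect_equal(as.numeric(coef(orc)),
               c(mine$omega0[2], mine$omega[2, ]), tolerance = 1e-4)
})

test_that("binomial lasso oracle agrees at positive penalties", {
  skip_if_not_installed("glmnet")
  # K = 2 with the reference pinned is exactly glmnet's binomial problem
  set.seed(42)
  G <- random_geno_matrix(80, 12, seed = 42)
  eta <- 0.5 + 1.2 * G[, 1] - 0.8 * G[, 3]
  y <- rbinom(80, 1, 1 / (1 + exp(-eta))) + 1
  tau <- labels_to_tau(y, 2)
  for (lam in c(0.02, 0.08)) {
    mine <- fit_sparse_multinomial(G, tau, lam, tol = 1e-12)
    orc <- glmnet::glmnet(G, factor(y), family = "binomial", lambda = lam,
                          standardize = TRUE, thresh = 1e-12)
    expect_equal(mine$omega[2, ], as.numeric(coef(orc))[-1],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("penalized solution beats brute-force searches of its objective", {
  set.seed(7)
  # dense grid oracle, step 0.05, over two coefficients and the intercept
  G <- random_geno_matrix(20, 2, seed = 7)
  z <- 1 + (G[, 1] > 0)
  tau <- labels_to_tau(z, 2)
  for (lam in c(0.05, 0.15, 0.4)) {
    fit <- fit_sparse_multinomial(G, tau, lam, standardize = FALSE,
                                  tol = 1e-12)
    mine <- pinned_objective(G, tau, fit$omega0, fit$omega, lam)
    grid <- seq(-3, 3, by = 0.05)
    best <- -Inf
    for (b1 in grid) {
      s1 <- G[, 1] * b1
      for (b2 in grid) {
        s <- s1 + G[, 2] * b2
        # profile the unpenalized intercept over its own fine grid
        S <- outer(s, grid, `+`)
        val <- max(colMeans(tau[, 2] * S - log1p(exp(S)))) -
          lam * (abs(b1) + abs(b2))
        if (val > best) best <- val
      }
    }
    expect_gte(mine, best - 1e-6)
  }

  # box-constrained split-positive L-BFGS-B oracle, K = 3, L = 3
  G3 <- random_geno_matrix(40, 3, seed = 8)
  z3 <- sample(1:3, 40, replace = TRUE)
  tau3 <- labels_to_tau(z3, 3)
  for (lam in c(0.03, 0.1)) {
    fit <- fit_sparse_multinomial(G3, tau3, lam, standardize = FALSE,
                                  tol = 1e-12)
    mine <- pinned_objective(G3, tau3, fit$omega0, fit$omega, lam)
    # theta = (b0_2, b0_3, vec(B+), vec(B-)) with B = B+ - B-
    negobj <- function(th) {
      b0 <- c(0, th[1:2])
      Bp <- matrix(th[3:8], 3, 2); Bm <- matrix(th[9:14], 3, 2)
      om <- rbind(0, t(Bp - Bm))
      -(pinned_objective(G3, tau3, b0, om, 0) - lam * sum(Bp) - lam * sum(Bm))
    }
    orc <- optim(rep(0.01, 14), negobj, method = "L-BFGS-B",
                 lower = c(-Inf, -Inf, rep(0, 12)),
                 control = list(maxit = 2000, factr = 1e4))
    expect_gte(mine, -orc$value - 1e-5)
  }
})

test_that("constant marker columns are dropped and restored as zeros", {
  G <- random_geno_matrix(30, 3, seed = 9)
  G[, 2] <- 1
  z <- 1 + (G[, 1] > 0)
  fit <- fit_sparse_multinomial(G, labels_to_tau(z, 2), 0.05)
  expect_equal(fit$omega[, 2], c(0, 0))
})

test_that("support shrinks as the penalty grows along the path", {
  set.seed(15)
  for (r in 1:8) {
    G <- random_geno_matrix(50, 10, seed = 100 + r)
    z <- 1 + (0.8 * G[, 1] - G[, 2] + rnorm(50, 0, 0.7) > 0)
    tau <- labels_to_tau(z, 2)
    lmax <- gating_lambda_max(G, tau)
    path <- gatemix:::multinom_lasso_path(G, tau,
                                          gatemix:::default_lambda_grid(lmax, 30, 1e-2))
    expect_true(all(diff(path$df) >= -1L))   # monotone up to solver jitter
  }
})

test_that("patient order permutation permutes nothing but row order", {
  set.seed(16)
  G <- random_geno_matrix(40, 6, seed = 16)
  z <- 1 + (G[, 1] > 0)
  tau <- labels_to_tau(z, 2)
  perm <- sample(40)
  f1 <- fit_sparse_multinomial(G, tau, 0.05)
  f2 <- fit_sparse_multinomial(G[perm, ], tau[perm, ], 0.05)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-8)
  expect_equal(f1$omega0, f2$omega0, tolerance = 1e-8)
})

test_that("cross-validation selects shrinkage under the null and power under signal", {
  # pure-noise markers: maximal shrinkage (an empty support) should win in
  # the clear majority of runs, and the spurious support stays tiny when it
  # does not (cross-validated lasso is known to admit occasional noise)
  hits <- 0; sizes <- integer(0)
  for (r in 1:25) {
    G <- random_geno_matrix(200, 8, seed = 300 + r)
    z <- gatemix:::with_local_seed(400 + r, sample(1:2, 200, replace = TRUE))
    sel <- select_lambda_cv(G, labels_to_tau(z, 2), seed = r,
                            nlambda = 25, lambda_min_ratio = 1e-2)
    hits <- hits + (nrow(sel$fit$support) == 0L)
    sizes <- c(sizes, nrow(sel$fit$support))
  }
  expect_gte(hits / 25, 0.7)
  expect_equal(median(sizes), 0)

  # one strong marker: it must enter the selected support nearly always
  got <- 0
  for (r in 1:25) {
    G <- random_geno_matrix(400, 8, seed = 500 + r)
    eta <- 3 * G[, 1]
    z <- gatemix:::with_local_seed(600 + r,
                                   rbinom(400, 1, 1 / (1 + exp(-eta)))) + 1
    sel <- select_lambda_cv(G, labels_to_tau(z, 2), seed = r,
                            nlambda = 25, lambda_min_ratio = 1e-2)
    got <- got + (1 %in% sel$fit$support$marker)
  }
  expect_gte(got / 25, 0.95)
})

test_that("singleton penalty grids are returned unchanged", {
  G <- random_geno_matrix(30, 4, seed = 18)
  z <- 1 + (G[, 1] > 0)
  sel <- select_lambda_cv(G, labels_to_tau(z, 2), lambda_grid = 0.07,
                          seed = 1)
  expect_equal(sel$lambda, 0.07)
  expect_equal(nrow(sel$cv_curve), 1L)
})

test_that("debiasing refit preserves the support and matches its oracles", {
  skip_if_not_installed("nnet")
  set.seed(19)
  G <- random_geno_matrix(150, 4, seed = 19)
  eta <- 1.2 * G[, 1] - G[, 2]
  z <- rbinom(150, 1, 1 / (1 + exp(-eta))) + 1

  # empty support: intercept-only, fitted probabilities = label frequencies
  db0 <- debias_refit(G, z, NULL, K = 2)
  pr <- gating_probs(G, db0)
  expect_equal(colMeans(pr), as.numeric(table(z) / 150), tolerance = 1e-6)

  # full support equals the lambda = 0 fit and the nnet oracle
  supp <- expand.grid(class = 2L, marker = 1:4)
  db <- debias_refit(G, z, supp, K = 2)
  free <- fit_sparse_multinomial(G, labels_to_tau(z, 2), 0, tol = 1e-13)
  expect_equal(db$omega, free$omega, tolerance = 1e-4)
  orc <- nnet::multinom(factor(z) ~ G, trace = FALSE, maxit = 1000,
                        reltol = 1e-14)
  expect_equal(as.numeric(coef(orc)), c(db$omega0[2], db$omega[2, ]),
               tolerance = 1e-3)

  # partial support: unlisted coefficients stay exactly zero
  supp2 <- data.frame(class = 2L, marker = c(1L, 3L))
  db2 <- debias_refit(G, z, supp2, K = 2)
  expect_equal(db2$omega[2, c(2, 4)], c(0, 0))
  expect_true(all(db2$omega[2, c(1, 3)] != 0))

  # CI excluding zero is equivalent to p < 0.05
  ci <- db$wald_ci
  excl <- ci$lower > 0 | ci$upper < 0
  expect_equal(excl, ci$p_value < 0.05)
})

test_that("separable refits fall back to a stabilized non-Wald fit", {
  G <- cbind(c(rep(-1, 10), rep(1, 10)), random_geno_matrix(20, 1, seed = 20))
  z <- c(rep(1, 10), rep(2, 10))
  expect_warning(db <- debias_refit(G, z, data.frame(class = 2L, marker = 1L),
                                    K = 2), "separable|ill-conditioned")
  expect_true(db$non_wald)
  expect_true(all(is.finite(db$wald_ci$se)))
})
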