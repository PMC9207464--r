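#' Gating probabilities of the multinomial logistic gate
#'
#' Row `i`, class `k` equals
#' `exp(omega0_k + omega_k' g_i) / sum_k' exp(omega0_k' + omega_k'' g_i)`,
#' computed with max-subtraction for numerical stability.
#'
#' @param geno a [genotype_matrix()] or plain `N x L` matrix.
#' @param params a [model_parameters()] object (or any list with `omega0`,
#'   `omega`).
#' @return `N x K` matrix of probabilities; rows sum to 1.
#' @export
gating_probs <- function(geno, params) {
  G <- geno_values(geno)
  omega <- as.matrix(params$omega)
  omega0 <- as.numeric(params$omega0)
  if (any(!is.finite(omega)) || any(!is.finite(omega0))) {
    stop("gating parameters must be finite")
  }
  scores <- sweep(G %*% t(omega), 2L, omega0, `+`)
  softmax_rows(scores)
}

geno_values <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$values else as.matrix(geno)
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

# log of row-wise softmax, stabilized
log_softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  scores - m - log(rowSums(exp(scores - m)))
}

# population (1/N) column standardization stats
marker_scale_stats <- function(G) {
  ctr <- colMeans(G)
  sc <- sqrt(colMeans(sweep(G, 2L, ctr)^2))
  list(center = ctr, scale = sc)
}

#' Largest useful penalty for the gating problem
#'
#' The smallest `lambda` for which all (standardized-scale) gating
#' coefficients are zero, given responsibilities `tau`.
#' @param geno genotype matrix or plain matrix.
#' @param tau `N x K` responsibilities.
#' @param reference_class pinned class index.
#' @param standardize standardize markers internally (as the fit does).
#' @return Positive scalar.
#' @export
gating_lambda_max <- function(geno, tau, reference_class = 1L,
                              standardize = TRUE) {
  G <- geno_values(geno)
  tau <- as_tau(tau)
  if (standardize) {
    st <- marker_scale_stats(G)
    keep <- st$scale > 0
    G <- sweep(sweep(G[, keep, drop = FALSE], 2L, st$center[keep]), 2L,
               st$scale[keep], `/`)
  }
  N <- nrow(G)
  pbar <- pmax(colMeans(tau), 1e-10)
  others <- setdiff(seq_len(ncol(tau)), reference_class)
  R <- sweep(-tau[, others, drop = FALSE], 2L, pbar[others], `+`)
  max(max(abs(crossprod(G, R))) / N, 1e-6)
}

default_lambda_grid <- function(lambda_max, nlambda = 100,
                                lambda_min_ratio = 1e-3) {
  # tiny inflation of the top keeps the boundary coefficient exactly zero
  exp(seq(log(lambda_max * (1 + 1e-6)), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

# Core path fit on a fixed, decreasing lambda grid.  Returns coefficients on
# the original marker scale, as K x L omega matrices with the reference row
# zero.  `tau` may be soft or one-hot.
multinom_lasso_path <- function(G, tau, lambda, reference_class = 1L,
                                standardize = TRUE, maxit_outer = 30L,
                                maxit_cd = 500L, tol = 1e-9, dfmax = NULL,
                                cand_mask = NULL, coef_cap = 30) {
  G <- geno_values(G)
  tau <- as_tau(tau)
  N <- nrow(G); L <- ncol(G); K <- ncol(tau)
  stopifnot(nrow(tau) == N, K >= 2L)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  others <- setdiff(seq_len(K), reference_class)

  ctr <- rep(0, L); sc <- rep(1, L)
  if (standardize) {
    st <- marker_scale_stats(G)
    ctr <- st$center; sc <- st$scale
  }
  # constant columns are dropped from the penalized problem and restored as
  # zero coefficients
  keep <- apply(G, 2L, function(x) any(x != x[1L]))
  sc[!keep] <- 1
  Xs <- G[, keep, drop = FALSE]
  if (standardize) {
    Xs <- sweep(sweep(Xs, 2L, ctr[keep]), 2L, sc[keep], `/`)
  }
  p <- ncol(Xs)
  pbar <- pmax(colMeans(tau), 1e-10)
  b0_init <- log(pbar[others] / pbar[reference_class])
  Tm <- tau[, others, drop = FALSE]
  if (is.null(dfmax)) dfmax <- as.integer(max(p, 1L)) * length(others)
  if (is.null(cand_mask)) {
    mask <- matrix(0L, 0L, 0L)
    restrict <- FALSE
  } else {
    mask <- cand_mask[keep, , drop = FALSE]
    storage.mode(mask) <- "integer"
    restrict <- TRUE
  }
  if (p == 0L) {
    # no informative markers: intercept-only solution at every lambda
    nl <- length(lambda)
    omega0 <- matrix(0, K, nl)
    omega0[others, ] <- b0_init
    return(list(lambda = lambda, omega0 = omega0,
                omega = array(0, c(K, L, nl)), df = rep(0L, nl),
                converged = rep(TRUE, nl), scale = sc, center = ctr))
  }
  fit <- cpp_multinom_lasso_path(Xs, Tm, lambda, b0_init,
                                 as.integer(maxit_outer),
                                 as.integer(maxit_cd), tol,
                                 as.integer(dfmax), mask, restrict, coef_cap)
  nl <- fit$nlambda_used
  omega <- array(0, c(K, L, nl))
  omega0 <- matrix(0, K, nl)
  kept_idx <- which(keep)
  for (m in seq_len(nl)) {
    Bstd <- fit$beta[, , m, drop = TRUE]
    Bstd <- matrix(Bstd, nrow = p)
    Borig <- Bstd / sc[kept_idx]
    omega[others, kept_idx, m] <- t(Borig)
    omega0[others, m] <- fit$b0[, m] - colSums(Bstd * (ctr[kept_idx] / sc[kept_idx]))
  }
  list(lambda = lambda[seq_len(nl)], omega0 = omega0, omega = omega,
       df = as.integer(fit$df[seq_len(nl)]),
       converged = as.logical(fit$converged[seq_len(nl)]),
       scale = sc, center = ctr)
}

support_from_omega <- function(omega, reference_class = 1L) {
  # coordinate descent produces exact zeros; the threshold only guards
  # against floating-point dust at the soft-threshold boundary
  nz <- which(abs(omega) > 1e-8, arr.ind = TRUE)
  nz <- nz[nz[, 1L] != reference_class, , drop = FALSE]
  data.frame(class = as.integer(nz[, 1L]), marker = as.integer(nz[, 2L]))
}

#' Fit the L1-penalized multinomial logistic gate at a given penalty
#'
#' Maximizes `(1/N) sum_i sum_k tau_ik log eta_k(g_i; omega) -
#' lambda * sum_k ||omega_k||_1` with unpenalized intercepts and the
#' reference class pinned to zero.  Markers are standardized internally for
#' the penalty; coefficients are returned on the original scale.  The fit is
#' warm-started along a geometric path from `lambda_max` down to the target
#' penalty.
#'
#' @param geno [genotype_matrix()] or plain matrix (no missing entries).
#' @param tau `N x K` responsibilities (soft weights or one-hot labels).
#' @param lambda penalty, `lambda >= 0` (0 is taken as a very small ridge-free
#'   path endpoint: `1e-5 * lambda_max`).
#' @param reference_class pinned class (default 1).
#' @param standardize standardize markers internally for the penalty.
#' @param ... passed to the internal path solver.
#' @return A `gating_fit` list: `omega0` (length `K`), `omega` (`K x L`),
#'   `lambda`, `support` (data.frame of nonzero class/marker pairs),
#'   `cv_curve` (`NULL` here), `df`, `converged`.
#' @export
fit_sparse_multinomial <- function(geno, tau, lambda, reference_class = 1L,
                                   standardize = TRUE, ...) {
  tau <- as_tau(tau)
  if (length(lambda) != 1L || lambda < 0) stop("lambda must be a scalar >= 0")
  if (nrow(tau) < ncol(tau)) stop("need at least K patients")
  lmax <- gating_lambda_max(geno, tau, reference_class, standardize)
  if (lambda == 0) {
    # exact maximum-likelihood request: optimize all coordinates directly
    G <- geno_values(geno)
    mask <- matrix(1L, ncol(G), ncol(tau) - 1L)
    path <- multinom_lasso_path(G, tau, 0, reference_class = reference_class,
                                standardize = standardize, cand_mask = mask,
                                maxit_outer = 200L, maxit_cd = 1000L, ...)
  } else {
  target <- lambda
  if (target >= lmax) {
    grid <- target
  } else {
    grid <- default_lambda_grid(lmax, nlambda = max(
      5L, ceiling(20 * log10(lmax / target))), lambda_min_ratio = target / lmax)
    grid[length(grid)] <- target
  }
  path <- multinom_lasso_path(geno, tau, grid,
                              reference_class = reference_class,
                              standardize = standardize, ...)
  }
  m <- length(path$lambda)
  omega <- path$omega[, , m, drop = TRUE]
  omega <- matrix(omega, nrow = nrow(path$omega0))
  if (lambda > 0 && path$lambda[m] > lambda * (1 + 1e-8)) {
    warning("path terminated early (dfmax or separability guard); ",
            "returning the fit at lambda = ", signif(path$lambda[m], 4))
  }
  structure(list(
    omega0 = path$omega0[, m],
    omega = omega,
    lambda = if (lambda == 0) 0 else path$lambda[m],
    lambda_requested = lambda,
    support = support_from_omega(omega, reference_class),
    cv_curve = NULL,
    df = path$df[m],
    converged = path$converged[m],
    reference_class = reference_class
  ), class = "gating_fit")
}

# mean per-patient weighted multinomial log-likelihood sum_k tau log eta
weighted_multinom_loglik <- function(G, tau, omega0, omega) {
  leta <- log_softmax_rows(sweep(geno_values(G) %*% t(omega), 2L, omega0, `+`))
  sum(tau * leta) / nrow(tau)
}

# deterministic stratified fold assignment (by tau-argmax), widening folds
# if a class is too small to appear in every fold
make_cv_folds <- function(tau, n_folds, seed) {
  labels <- max.col(as_tau(tau), ties.method = "first")
  N <- length(labels)
  counts <- tabulate(labels, nbins = ncol(as_tau(tau)))
  present <- counts[counts > 0]
  nf <- n_folds
  if (min(present) < n_folds) {
    nf <- max(2L, min(present))
    if (nf < n_folds) {
      warning("some class has fewer members than folds; using ", nf, " folds")
    }
  }
  folds <- integer(N)
  with_local_seed(seed, {
    for (k in which(counts > 0)) {
      idx <- sample(which(labels == k))
      folds[idx] <- rep_len(seq_len(nf), length(idx))
    }
  })
  list(folds = folds, n_folds = nf)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cross-validated selection of the gating penalty
#'
#' Selects `lambda` on a geometric grid by `n_folds`-fold cross-validation,
#' maximizing the mean held-out responsibility-weighted multinomial
#' log-likelihood.  Patients are the cross-validation unit; folds are
#' stratified by the argmax class of `tau` and are deterministic given
#' `seed`.
#'
#' @inheritParams fit_sparse_multinomial
#' @param n_folds number of folds (>= 2).
#' @param lambda_grid optional decreasing grid; default geometric with
#'   `nlambda` points from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param seed integer seed controlling fold assignment.
#' @param nlambda,lambda_min_ratio default grid shape.
#' @return list with `lambda` (selected), `cv_curve` (data.frame `lambda`,
#'   `mean_loglik`), and `fit` (the full-data `gating_fit` at the selected
#'   penalty, with `cv_curve` attached).
#' @export
select_lambda_cv <- function(geno, tau, n_folds = 5L, lambda_grid = NULL,
                             seed = 1L, reference_class = 1L,
                             nlambda = 100L, lambda_min_ratio = 1e-3,
                             standardize = TRUE, ...) {
  G <- geno_values(geno)
  tau <- as_tau(tau)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (is.null(lambda_grid)) {
    lmax <- gating_lambda_max(G, tau, reference_class, standardize)
    lambda_grid <- default_lambda_grid(lmax, nlambda, lambda_min_ratio)
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  if (length(lambda_grid) == 0L) stop("lambda grid must be nonempty")

  if (length(lambda_grid) == 1L) {
    fit <- fit_sparse_multinomial(G, tau, lambda_grid,
                                  reference_class = reference_class,
                                  standardize = standardize, ...)
    curve <- data.frame(lambda = lambda_grid, mean_loglik = NA_real_)
    fit$cv_curve <- curve
    return(list(lambda = lambda_grid, cv_curve = curve, fit = fit))
  }

  fl <- make_cv_folds(tau, n_folds, seed)
  nl <- length(lambda_grid)
  tot <- rep(0, nl)
  nused <- rep(0, nl)
  for (f in seq_len(fl$n_folds)) {
    tr <- fl$folds != f
    te <- !tr
    path <- multinom_lasso_path(G[tr, , drop = FALSE],
                                tau[tr, , drop = FALSE], lambda_grid,
                                reference_class = reference_class,
                                standardize = standardize, ...)
    for (m in seq_along(path$lambda)) {
      om <- matrix(path$omega[, , m], nrow = nrow(path$omega0))
      ll <- weighted_multinom_loglik(G[te, , drop = FALSE],
                                     tau[te, , drop = FALSE],
                                     path$omega0[, m], om)
      tot[m] <- tot[m] + ll * sum(te)
      nused[m] <- nused[m] + sum(te)
    }
  }
  ok <- nused == max(nused)   # lambdas reached by every fold
  mean_ll <- ifelse(ok, tot / nused, -Inf)
  best <- which.max(mean_ll)
  curve <- data.frame(lambda = lambda_grid, mean_loglik = mean_ll)

  full <- multinom_lasso_path(G, tau, lambda_grid[seq_len(best)],
                              reference_class = reference_class,
                              standardize = standardize, ...)
  m <- length(full$lambda)
  omega <- matrix(full$omega[, , m], nrow = nrow(full$omega0))
  fit <- structure(list(
    omega0 = full$omega0[, m], omega = omega,
    lambda = lambda_grid[best],
    support = support_from_omega(omega, reference_class),
    cv_curve = curve, df = full$df[m], converged = full$converged[m],
    reference_class = reference_class
  ), class = "gating_fit")
  list(lambda = lambda_grid[best], cv_curve = curve, fit = fit)
}

#' Unpenalized refit of the selected gating coefficients
#'
#' Re-estimates, by maximum likelihood without penalty, only the gating
#' coefficients selected by the lasso (plus all intercepts), holding every
#' other coefficient at zero, so the selected support is unchanged.  This
#' removes the shrinkage bias of the penalized estimates.  95% Wald
#' confidence intervals come from the inverse observed information of the
#' free coordinates.
#'
#' @param geno [genotype_matrix()] or plain matrix.
#' @param labels hard class assignments in `1..K` (from a converged fit).
#' @param support data.frame with columns `class`, `marker` (nonzero pairs),
#'   or `NULL`/empty for an intercept-only model.
#' @param K number of classes.
#' @param reference_class pinned class index.
#' @return list with `omega0`, `omega` (debiased, support preserved),
#'   `wald_ci` (data.frame: class, marker, estimate, se, lower, upper,
#'   p_value; marker 0 rows are intercepts), and `non_wald` flag (`TRUE`
#'   when separation forced a stabilized fit and the intervals are not
#'   trustworthy Wald intervals).
#' @export
debias_refit <- function(geno, labels, support, K,
                         reference_class = 1L) {
  G <- geno_values(geno)
  N <- nrow(G); L <- ncol(G)
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L), all(labels <= K))
  tau <- labels_to_tau(labels, K)
  others <- setdiff(seq_len(K), reference_class)
  if (is.null(support) || nrow(support) == 0L) {
    support <- data.frame(class = integer(0), marker = integer(0))
  }
  mask <- matrix(0L, L, length(others))
  if (nrow(support) > 0L) {
    kpos <- match(support$class, others)
    if (anyNA(kpos)) stop("support refers to the reference class")
    mask[cbind(support$marker, kpos)] <- 1L
  }
  path <- multinom_lasso_path(G, tau, lambda = 0, standardize = FALSE,
                              reference_class = reference_class,
                              cand_mask = mask, maxit_outer = 200L,
                              maxit_cd = 1000L, tol = 1e-12, coef_cap = 35)
  omega <- matrix(path$omega[, , 1L], nrow = K)
  omega0 <- path$omega0[, 1L]

  sep <- max(abs(omega)) > 15 || max(abs(omega0)) > 15
  info <- refit_information(G, tau, omega0, omega, support, others,
                            reference_class)
  ridge_flag <- FALSE
  cov <- tryCatch(solve(info$H), error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    sep <- sep || max(sqrt(diag(cov))) > 10   # quasi-separation: useless Wald widths
  }
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0) || sep) {
    warning("separable or ill-conditioned refit; returning ridge-stabilized ",
            "estimates (flagged non-Wald)")
    ridge_flag <- TRUE
    cov <- solve(info$H + diag(1e-2, nrow(info$H)))
  }
  se <- sqrt(pmax(diag(cov), 0))
  est <- info$theta
  ci <- data.frame(
    class = info$coord_class,
    marker = info$coord_marker,
    estimate = est,
    se = se,
    lower = est - 1.96 * se,
    upper = est + 1.96 * se,
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
  list(omega0 = omega0, omega = omega, wald_ci = ci, non_wald = ridge_flag)
}

# observed information (negative Hessian of the unscaled log-likelihood)
# over the free coordinates of the restricted refit
refit_information <- function(G, tau, omega0, omega, support, others,
                              reference_class) {
  N <- nrow(G)
  P <- gating_probs(G, list(omega0 = omega0, omega = omega))
  coord_class <- integer(0); coord_marker <- integer(0); theta <- numeric(0)
  for (k in others) {
    coord_class <- c(coord_class, k); coord_marker <- c(coord_marker, 0L)
    theta <- c(theta, omega0[k])
  }
  if (nrow(support) > 0L) {
    ord <- order(support$class, support$marker)
    for (r in ord) {
      coord_class <- c(coord_class, support$class[r])
      coord_marker <- c(coord_marker, support$marker[r])
      theta <- c(theta, omega[support$class[r], support$marker[r]])
    }
  }
  q <- length(theta)
  H <- matrix(0, q, q)
  xcol <- function(m) if (m == 0L) rep(1, N) else G[, m]
  for (a in seq_len(q)) {
    xa <- xcol(coord_marker[a]); ka <- coord_class[a]
    for (b in a:q) {
      xb <- xcol(coord_marker[b]); kb <- coord_class[b]
      w <- if (ka == kb) P[, ka] * (1 - P[, ka]) else -P[, ka] * P[, kb]
      H[a, b] <- H[b, a] <- sum(xa * xb * w)
    }
  }
  list(H = H, theta = theta, coord_class = coord_class,
       coord_marker = coord_marker)
}
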