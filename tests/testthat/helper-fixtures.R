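# small in-code fixtures shared across test files

make_clinical <- function(ids, times, values) {
  df <- data.frame(patient_id = ids, time = times)
  values <- as.matrix(values)
  colnames(values) <- paste0("score", seq_len(ncol(values)))
  longitudinal_data(cbind(df, as.data.frame(values)))
}

# one visit per patient at time 0, one variable
make_flat_clinical <- function(y) {
  make_clinical(sprintf("p%02d", seq_along(y)), rep(0, length(y)), cbind(y))
}

make_geno <- function(values, ids = sprintf("p%02d", seq_len(nrow(values)))) {
  genotype_matrix(as.matrix(values), patient_ids = ids)
}

random_geno_matrix <- function(N, L, seed) {
  gatemix:::with_local_seed(seed, {
    maf <- runif(L, 0.2, 0.5)
    matrix(rbinom(N * L, 2, rep(maf, each = N)) - 1, N, L)
  })
}

# a deliberately well-separated two-cluster scenario (trajectory means about
# ten within-cluster sd apart, one strong gating marker)
strong_toy_config <- function(seed = 1L, N = 100L) {
  alpha <- array(0, c(2, 2, 2))
  alpha[, , 1] <- rbind(c(0, 0), c(10, -10))
  alpha[, , 2] <- rbind(c(1, -1), c(12, -12))
  simulation_config(
    N = N, V = 2L, K = 2L, P = 1L, L = 6L,
    omega_spec = data.frame(class = 2L, marker = 1L, value = 3),
    visit_windows = list(c(10, 410), c(1800, 2200), c(3600, 4000)),
    alpha = alpha, sigma = matrix(1, 2, 2), maf_range = c(0.2, 0.5),
    time_scale = 4000, seed = seed)
}

# naive densities-by-loops mixture quantities, used as oracles
naive_logpost <- function(clinical, geno, params) {
  G <- gatemix:::geno_values(geno)
  N <- length(clinical$patient_ids)
  K <- params$K
  eta <- gating_probs(G, params)
  out <- matrix(0, N, K)
  for (i in seq_len(N)) {
    rows <- which(clinical$visit_patient == i)
    for (k in seq_len(K)) {
      ll <- 0
      for (r in rows) {
        u <- clinical$visit_time[r] / params$time_scale
        for (v in seq_len(params$V)) {
          y <- clinical$values[r, v]
          if (!is.na(y)) {
            mu <- sum(params$alpha[k, v, ] * u^(0:params$P))
            ll <- ll + dnorm(y, mu, params$sigma[k, v], log = TRUE)
          }
        }
      }
      out[i, k] <- log(eta[i, k]) + ll
    }
  }
  out
}

make_small_params <- function(K, V, L, P = 1, seed = 1, time_scale = 1) {
  gatemix:::with_local_seed(seed, {
    omega <- rbind(0, matrix(rnorm((K - 1) * L, 0, 0.5), K - 1, L))
    model_parameters(array(rnorm(K * V * (P + 1)), c(K, V, P + 1)),
                     matrix(runif(K * V, 0.5, 1.5), K, V),
                     c(0, rnorm(K - 1, 0, 0.3)), omega,
                     time_scale = time_scale)
  })
}

small_instance <- function(seed, N = 40, V = 2, L = 5, K = 2) {
  cfg <- simulation_config(
    N = N, V = V, K = K, P = 1, L = L,
    omega_spec = data.frame(class = 2L, marker = 1L, value = 1.5),
    visit_windows = list(c(0, 100), c(150, 300), c(350, 500)),
    alpha = array(rep(c(0, 1), each = K * V) +
                    rep(seq_len(K) - 1, V * 2), c(K, V, 2)),
    sigma = matrix(1, K, V), time_scale = 500, seed = seed)
  simulate_dataset(cfg)
}

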