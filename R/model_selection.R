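#' BIC grid search over the number of clusters and the polynomial degree
#'
#' Fits the gated mixture for every `(K, P)` pair and returns the cell with
#' the lowest BIC (ties broken toward smaller `K`, then smaller `P`).  The
#' default grids (`K` up to 4, `P` in 1..2) reflect the interpretability
#' bounds typical of disease-subtyping applications.
#'
#' @inheritParams fit_mixture
#' @param K_values candidate cluster counts.
#' @param P_values candidate polynomial degrees.
#' @param config an [em_config()]; its `K` and `P` are overridden cell by
#'   cell.
#' @return list with `best` (the winning `gatemix_fit`) and `grid`
#'   (data.frame: K, P, bic, loglik, nu, converged, failed).
#' @export
select_model <- function(clinical, geno, K_values = 1:4, P_values = 1:2,
                         config = em_config(K = 1)) {
  if (length(K_values) == 0L || length(P_values) == 0L) {
    stop("grids must be nonempty")
  }
  cells <- expand.grid(K = as.integer(K_values), P = as.integer(P_values))
  fits <- vector("list", nrow(cells))
  grid <- cbind(cells, bic = NA_real_, loglik = NA_real_, nu = NA_integer_,
                converged = NA, failed = FALSE, error = NA_character_)
  for (r in seq_len(nrow(cells))) {
    cfg <- config
    cfg$K <- cells$K[r]
    cfg$P <- cells$P[r]
    fit <- tryCatch(fit_mixture(clinical, geno, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      grid$failed[r] <- TRUE
      grid$error[r] <- conditionMessage(fit)
    } else {
      fits[[r]] <- fit
      grid$bic[r] <- fit$bic
      grid$loglik[r] <- fit$loglik
      grid$nu[r] <- fit$nu
      grid$converged[r] <- fit$converged
    }
  }
  if (all(grid$failed)) {
    stop("model selection failed in every grid cell:\n",
         paste(sprintf("  K=%d P=%d: %s", grid$K, grid$P, grid$error),
               collapse = "\n"))
  }
  ok <- which(!grid$failed)
  ord <- ok[order(grid$bic[ok], grid$K[ok], grid$P[ok])]
  list(best = fits[[ord[1L]]], grid = grid)
}
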