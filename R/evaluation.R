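#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement under the permutation model, from the
#' contingency table of the two labelings.  1 for identical partitions (up
#' to relabeling), about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  if (length(labels_a) < 2L) stop("need at least 2 observations")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Pooled sensitivity and specificity of marker selection
#'
#' A marker counts as selected in a replicate when any non-reference class
#' has a nonzero gating coefficient for it.  Sensitivity pools the
#' selected-active counts over replicates; specificity pools the
#' unselected-inactive counts.
#'
#' @param true_support integer indices of the truly active markers.
#' @param selected_per_replicate list of integer vectors (selected marker
#'   indices per replicate).
#' @param L total marker count.
#' @return list with `sensitivity`, `specificity` (both in `[0, 1]`), and
#'   `selection_counts` (per-marker counts over replicates).
#' @export
selection_metrics <- function(true_support, selected_per_replicate, L) {
  if (length(selected_per_replicate) == 0L) {
    stop("at least one replicate is required")
  }
  true_support <- unique(as.integer(true_support))
  if (any(true_support < 1L | true_support > L)) {
    stop("true_support must be within 1..L")
  }
  R <- length(selected_per_replicate)
  counts <- integer(L)
  tp <- 0L; tn <- 0L
  n_active <- length(true_support)
  n_inactive <- L - n_active
  for (sel in selected_per_replicate) {
    sel <- unique(as.integer(sel))
    counts[sel] <- counts[sel] + 1L
    tp <- tp + sum(sel %in% true_support)
    tn <- tn + (n_inactive - sum(!(sel %in% true_support)))
  }
  list(sensitivity = tp / (n_active * R),
       specificity = if (n_inactive > 0L) tn / (n_inactive * R) else NA_real_,
       selection_counts = counts)
}

#' Selected markers of a fit
#'
#' Marker indices with a nonzero penalized gating coefficient in any
#' non-reference class (selection is defined on the penalized fit; the
#' debiasing refit never changes the support).
#' @param fit a `gatemix_fit`.
#' @return sorted integer vector.
#' @export
selected_markers <- function(fit) {
  sort(unique(fit$support$marker))
}

#' Best class permutation matching two labelings
#'
#' The permutation `perm` (est class `k` corresponds to true class
#' `perm[k]`) maximizing agreement, by exhaustive search over the
#' confusion matrix (intended for the small `K` of subtyping problems).
#'
#' @param true_labels,est_labels integer labels in `1..K`.
#' @param K number of classes.
#' @return integer permutation of `1..K`.
#' @export
match_clusters <- function(true_labels, est_labels, K) {
  if (K > 8L) stop("exhaustive matching is limited to K <= 8")
  conf <- matrix(0, K, K)
  tb <- table(factor(est_labels, levels = seq_len(K)),
              factor(true_labels, levels = seq_len(K)))
  conf[] <- tb
  perms <- all_permutations(K)
  agree <- vapply(seq_len(nrow(perms)), function(r)
    sum(conf[cbind(seq_len(K), perms[r, ])]), numeric(1))
  unname(perms[which.max(agree), ])
}

all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(K - 1L)
  out <- matrix(0L, 0L, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                   sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}
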