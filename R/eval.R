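#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form) computed
#' from the contingency table of the two label vectors:
#' `ARI = (Index - E[Index]) / (MaxIndex - E[Index])`. Identical partitions
#' score 1; random agreement scores about 0. When the denominator is zero
#' (both partitions trivial, e.g. all singletons versus one block), the
#' index is undefined and 0 is returned by convention.
#'
#' @param labels_a,labels_b Label vectors of equal length (>= 2); any label
#'   coding is accepted.
#' @return The adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_validation("partitions must have equal length")
  }
  n <- length(labels_a)
  if (n < 2L) stop_validation("need at least 2 items")
  tab <- table(labels_a, labels_b)
  sum_nij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  denom <- max_index - expected
  if (denom == 0) return(0)
  (sum_nij - expected) / denom
}

#' Distribution of K-means recovery of known sample clusters
#'
#' Runs K-means (Lloyd's algorithm, k random initial centres drawn from the
#' data points) on the sample columns of a matrix `n_reps` times with
#' distinct seeds derived from `seed`, scoring each run's agreement with the
#' known labels by the adjusted Rand index. Samples are the points and
#' features the dimensions, with no pre-scaling. Lloyd's iteration can abort
#' when a random initialisation empties a cluster; such repetitions retry
#' deterministically with a follow-on derived seed, keeping the whole
#' distribution reproducible.
#'
#' @param data Numeric feature-by-sample matrix.
#' @param true_labels Known cluster label per sample column.
#' @param k Number of clusters to fit (>= 2, <= number of samples).
#' @param n_reps Number of repetitions (conventionally 1000; default 100).
#' @param seed Master seed.
#' @return Object of class `concordia_clustering`: list with `ari_values`,
#'   `mean_ari`, `n_reps`, `k`, `seed`.
#' @export
kmeans_ari_distribution <- function(data, true_labels, k, n_reps = 100L, seed = 1L) {
  n_samples <- ncol(data)
  if (length(true_labels) != n_samples) {
    stop_validation("true_labels length must equal the number of samples")
  }
  if (k < 2L) stop_validation("k must be >= 2")
  if (k > n_samples) stop_validation("k must be <= number of samples")
  if (n_reps < 1L) stop_validation("n_reps must be >= 1")
  pts <- t(data)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  ari <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- rep_seeds[r]
    fit <- NULL
    attempts <- 0L
    while (is.null(fit)) {
      set.seed(s)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(pts, centers = k,
                                       algorithm = "Lloyd", iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(fit)) {
        s <- (s + 999983L) %% (.Machine$integer.max - 1L) + 1L
        attempts <- attempts + 1L
        if (attempts > 100L) stop("K-means failed to produce a valid fit")
      }
    }
    ari[r] <- adjusted_rand_index(fit$cluster, true_labels)
  }
  structure(list(ari_values = ari, mean_ari = mean(ari),
                 n_reps = n_reps, k = k, seed = seed),
            class = "concordia_clustering")
}

#' @export
print.concordia_clustering <- function(x, ...) {
  cat(sprintf("K-means cluster recovery: k = %d, %d repetitions (seed %d)\n",
              x$k, x$n_reps, x$seed))
  cat(sprintf("  adjusted Rand index: mean %.4f, range [%.4f, %.4f]\n",
              x$mean_ari, min(x$ari_values), max(x$ari_values)))
  invisible(x)
}

#' Per-feature concordance change against a partner matrix
#'
#' For every feature, computes the Spearman correlation of the feature's row
#' with the corresponding partner row before and after adjustment and
#' reports the difference `delta = cor(after, partner) - cor(before,
#' partner)` (average-rank handling of ties). The typical use is expression
#' versus per-gene copy number: adjustment should, on balance, strengthen
#' the expression-copy-number relationship. Also returns the fraction of
#' features with positive delta and a one-tailed paired t-test of the
#' after-versus-before correlations (alternative: after greater).
#'
#' @param before,after,partner Numeric matrices sharing feature and sample
#'   spaces (identical dimnames).
#' @return List with `delta` (named per-feature differences), `cor_before`,
#'   `cor_after`, `fraction_positive`, `t_statistic`, `p_value`.
#' @export
concordance_delta <- function(before, after, partner) {
  if (!identical(dim(before), dim(after)) ||
      !identical(dim(before), dim(partner)) ||
      !identical(dimnames(before), dimnames(after)) ||
      !identical(dimnames(before), dimnames(partner))) {
    stop_validation("before, after and partner must share dimensions and dimnames")
  }
  n <- nrow(before)
  cb <- ca <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- partner[i, ]
    if (!has_variance(p)) next
    if (has_variance(before[i, ])) {
      cb[i] <- stats::cor(before[i, ], p, method = "spearman")
    }
    if (has_variance(after[i, ])) {
      ca[i] <- stats::cor(after[i, ], p, method = "spearman")
    }
  }
  names(cb) <- names(ca) <- rownames(before)
  delta <- ca - cb
  usable <- is.finite(delta)
  frac <- if (any(usable)) mean(delta[usable] > 0) else NA_real_
  tt <- tryCatch(
    stats::t.test(ca[usable], cb[usable], paired = TRUE, alternative = "greater"),
    error = function(e) NULL)
  list(delta = delta, cor_before = cb, cor_after = ca,
       fraction_positive = frac,
       t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value)
}
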