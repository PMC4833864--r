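#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd quantile rnorm kmeans t.test
#' @importFrom utils read.table write.table
NULL

# Validation error with a dedicated condition class so callers (and the CLI)
# can distinguish bad input from computation failures.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("concordia_validation_error", "error")))
}

# A row is usable only if its variance is non-negligible relative to its
# magnitude: variance > 1e-12 * mean square of the row.
has_variance <- function(x) {
  ms <- mean(x^2)
  v <- stats::var(x)
  is.finite(v) && v > 1e-12 * ms && v > 0
}

#' Pearson correlation between two row vectors
#'
#' Thin wrapper around [stats::cor()] that enforces the contract used by the
#' row-adjustment gate: both vectors must have length at least 3 and
#' non-negligible variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The Pearson product-moment correlation, in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 3L) stop_validation("vectors must have length >= 3")
  if (!has_variance(x) || !has_variance(y)) {
    stop_validation("zero-variance vector: correlation undefined (row should be skipped)")
  }
  stats::cor(x, y)
}

#' Standardize a row vector
#'
#' Centers to mean 0 and scales to standard deviation 1, using the sample
#' (n - 1) denominator. This is the `scale()` used throughout the adjustment
#' formulas; centering is immaterial for the final output because every
#' adjusted row is rescaled back to the original row's mean and s.d.
#'
#' @param x Numeric vector with non-negligible variance, length >= 2.
#' @return Numeric vector with mean 0 and s.d. 1.
#' @export
scale_row <- function(x) {
  if (length(x) < 2L) stop_validation("scale_row needs length >= 2")
  if (!has_variance(x)) stop_validation("zero-variance vector cannot be standardized")
  (x - mean(x)) / stats::sd(x)
}

#' Rescale a vector to a target mean and standard deviation
#'
#' Standardizes `x` and then applies `x * target_sd + target_mean`, so the
#' output has exactly the requested first two moments. Used to restore each
#' adjusted row to the mean and s.d. of the original row.
#'
#' @param x Numeric vector with non-negligible variance.
#' @param target_mean,target_sd Target moments; `target_sd` must be positive.
#' @return Numeric vector with mean `target_mean` and s.d. `target_sd`.
#' @export
rescale_to <- function(x, target_mean, target_sd) {
  if (!is.finite(target_sd) || target_sd <= 0) {
    stop_validation("target_sd must be positive")
  }
  scale_row(x) * target_sd + target_mean
}

#' First principal component of a set of rows, as a score vector
#'
#' Standardizes each row, performs PCA on the correlation matrix of the rows
#' (equivalently, an SVD of the standardized row matrix), and returns the
#' leading component's score vector across the n samples: the linear
#' combination of standardized rows weighted by the leading eigenvector. If
#' the result correlates negatively with `reference`, its sign is flipped so
#' the summary always points in the reference row's direction.
#'
#' Rows with negligible variance are not accepted here; callers drop them
#' first. With a single row the score is simply the standardized row,
#' sign-aligned to the reference.
#'
#' @param rows Numeric matrix (k features x n samples), or a single vector.
#' @param reference Numeric vector of length n used only to fix the sign,
#'   or `NULL` to skip sign alignment.
#' @return Numeric score vector of length n.
#' @export
first_pc_rows <- function(rows, reference = NULL) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1L)
  k <- nrow(rows)
  n <- ncol(rows)
  if (k < 1L) stop_validation("need at least one row")
  if (n < 3L) stop_validation("need at least 3 samples")
  ok <- apply(rows, 1L, has_variance)
  if (!all(ok)) stop_validation("all rows must have non-negligible variance")
  z <- t(apply(rows, 1L, scale_row))
  if (k == 1L) {
    s <- z[1L, ]
  } else {
    sv <- svd(z, nu = 0L, nv = 2L)
    s <- sv$d[1L] * sv$v[, 1L]
    # Leading-eigenvalue tie: prefer the component best aligned with the
    # reference; exact ties keep the first index.
    if (sv$d[1L] - sv$d[2L] <= 1e-9 * sv$d[1L] &&
        !is.null(reference) && has_variance(reference)) {
      s2 <- sv$d[2L] * sv$v[, 2L]
      if (has_variance(s) && has_variance(s2) &&
          abs(stats::cor(s2, reference)) > abs(stats::cor(s, reference))) {
        s <- s2
      }
    }
  }
  if (!is.null(reference) && has_variance(reference) && has_variance(s)) {
    if (stats::cor(s, reference) < 0) s <- -s
  }
  s
}

check_cutoffs <- function(cutoff1, cutoff2) {
  if (!is.numeric(cutoff1) || !is.numeric(cutoff2) ||
      length(cutoff1) != 1L || length(cutoff2) != 1L ||
      !is.finite(cutoff1) || !is.finite(cutoff2)) {
    stop_validation("cutoff1 and cutoff2 must be finite scalars")
  }
  if (cutoff1 < -1 || cutoff1 > 1 || cutoff2 < -1 || cutoff2 > 1) {
    stop_validation("cutoffs must lie in [-1, 1]")
  }
  if (cutoff1 >= cutoff2) {
    stop_validation("cutoff1 (", cutoff1, ") must be smaller than cutoff2 (", cutoff2, ")")
  }
  invisible(TRUE)
}

#' Adjust a single main-matrix row using its associated partner row
#'
#' Implements the three-way update gated by the Pearson correlation
#' `rho = cor(c, m)`:
#' \describe{
#'   \item{scenario1 (`rho <= cutoff1`)}{the row is kept unchanged;}
#'   \item{scenario2 (`cutoff1 < rho <= cutoff2`)}{the correlation-weighted
#'     sum `scale(m) + rho * scale(c)`;}
#'   \item{scenario3 (`rho > cutoff2`)}{the first principal component of the
#'     two standardized rows (PCA on the 2 x 2 correlation matrix),
#'     sign-aligned with `m`.}
#' }
#' Scenario 2 and 3 outputs are rescaled to the mean and s.d. of the input
#' `m`, so adjustment never changes a row's first two moments. Rows where
#' either vector has negligible variance are returned unchanged with label
#' `"skipped"`.
#'
#' @param m Main row vector.
#' @param c_row Associated (summarized) partner row vector, same length.
#' @param cutoff1,cutoff2 Correlation gates, `cutoff1 < cutoff2`;
#'   defaults 0 and 0.5.
#' @return List with elements `row` (adjusted vector), `scenario` (one of
#'   `"skipped"`, `"scenario1"`, `"scenario2"`, `"scenario3"`) and `rho`
#'   (the gating correlation, `NA` when skipped).
#' @export
adjust_row <- function(m, c_row, cutoff1 = 0, cutoff2 = 0.5) {
  check_cutoffs(cutoff1, cutoff2)
  if (length(m) != length(c_row)) stop_validation("m and c_row must have equal length")
  if (length(m) < 3L) stop_validation("rows must have length >= 3")
  if (!has_variance(m) || !has_variance(c_row)) {
    return(list(row = m, scenario = "skipped", rho = NA_real_))
  }
  rho <- stats::cor(c_row, m)
  if (rho <= cutoff1) {
    return(list(row = m, scenario = "scenario1", rho = rho))
  }
  v <- if (rho <= cutoff2) {
    scale_row(m) + rho * scale_row(c_row)
  } else {
    first_pc_rows(rbind(m, c_row), reference = m)
  }
  if (!has_variance(v)) {
    return(list(row = m, scenario = "skipped", rho = rho))
  }
  out <- rescale_to(v, mean(m), stats::sd(m))
  list(row = out,
       scenario = if (rho <= cutoff2) "scenario2" else "scenario3",
       rho = rho)
}

#' Adjust a main matrix row by row against a row-matched associated matrix
#'
#' Applies [adjust_row()] independently to every row of `main` against the
#' corresponding row of `assoc`, which must already be in main's feature
#' space (either one-to-one matched input or the output of
#' [summarize_associated()]). Rows flagged in `skip` pass through unchanged.
#'
#' @param main Numeric feature-by-sample matrix with row and column names.
#' @param assoc Numeric matrix of identical dimensions and sample order.
#' @param cutoff1,cutoff2 Correlation gates (see [adjust_row()]).
#' @param skip Optional logical vector, one entry per row of `main`, marking
#'   rows with no summarized counterpart.
#' @return Object of class `concordia_adjustment`: list with `adjusted`
#'   (matrix shaped like `main`), `row_correlation` (named numeric, `NA` for
#'   skipped rows), `scenario` (named character) and `cutoffs`.
#' @export
adjust_matrix <- function(main, assoc, cutoff1 = 0, cutoff2 = 0.5, skip = NULL) {
  check_cutoffs(cutoff1, cutoff2)
  if (!is.matrix(main) || !is.matrix(assoc)) stop_validation("inputs must be matrices")
  if (!all(dim(main) == dim(assoc))) {
    stop_validation("main and associated matrices must have identical dimensions (",
                    nrow(main), "x", ncol(main), " vs ", nrow(assoc), "x", ncol(assoc), ")")
  }
  if (!is.null(colnames(main)) && !is.null(colnames(assoc)) &&
      !identical(colnames(main), colnames(assoc))) {
    bad <- which(colnames(main) != colnames(assoc))[1L]
    stop_validation("sample order mismatch at column ", bad, ": '",
                    colnames(main)[bad], "' vs '", colnames(assoc)[bad], "'")
  }
  n_rows <- nrow(main)
  if (is.null(skip)) skip <- rep(FALSE, n_rows)
  if (length(skip) != n_rows) stop_validation("skip mask length must equal nrow(main)")

  adjusted <- main
  rho <- rep(NA_real_, n_rows)
  scenario <- rep("skipped", n_rows)
  for (i in seq_len(n_rows)) {
    if (skip[i]) next
    res <- adjust_row(main[i, ], assoc[i, ], cutoff1, cutoff2)
    adjusted[i, ] <- res$row
    rho[i] <- res$rho
    scenario[i] <- res$scenario
  }
  names(rho) <- rownames(main)
  names(scenario) <- rownames(main)
  structure(list(adjusted = adjusted,
                 row_correlation = rho,
                 scenario = scenario,
                 cutoffs = c(cutoff1 = cutoff1, cutoff2 = cutoff2)),
            class = "concordia_adjustment")
}

#' @export
print.concordia_adjustment <- function(x, ...) {
  cat("Row-wise concordance adjustment\n")
  cat(sprintf("  %d features x %d samples\n", nrow(x$adjusted), ncol(x$adjusted)))
  cat(sprintf("  cutoffs: cutoff1 = %g, cutoff2 = %g\n",
              x$cutoffs[["cutoff1"]], x$cutoffs[["cutoff2"]]))
  counts <- table(factor(x$scenario,
                         levels = c("scenario1", "scenario2", "scenario3", "skipped")))
  for (nm in names(counts)) cat(sprintf("  %-10s %6d\n", nm, counts[[nm]]))
  invisible(x)
}

#' Choose cutoff2 empirically from the row correlations
#'
#' Returns the (1 - `target_fraction`) empirical quantile (linear
#' interpolation, [stats::quantile()] type 7) of the finite row correlations,
#' so that roughly `target_fraction` of the rows fall in scenario 3
#' (`rho > cutoff2`). The default target of one third reflects the rule of
#' thumb that about a third of rows should take the principal-component
#' update.
#'
#' @param row_correlations Numeric vector of per-row gating correlations;
#'   non-finite entries (skipped rows) are ignored.
#' @param target_fraction Desired scenario-3 fraction, in (0, 1).
#' @return The cutoff value.
#' @export
select_cutoff2 <- function(row_correlations, target_fraction = 1 / 3) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      !is.finite(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
    stop_validation("target_fraction must lie strictly between 0 and 1")
  }
  rho <- row_correlations[is.finite(row_correlations)]
  if (length(rho) == 0L) stop_validation("no finite row correlations supplied")
  unname(stats::quantile(rho, probs = 1 - target_fraction, type = 7, names = FALSE))
}
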