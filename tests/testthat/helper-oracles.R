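# Independent reference implementations used as oracles. These deliberately
# take different code paths from the package (closed-form arithmetic, dense
# eigendecomposition, explicit pair counting).

# Pearson correlation by direct evaluation of the closed form.
oracle_pearson <- function(x, y) {
  n <- length(x)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / ((n - 1) *
                    sqrt(sum(dx^2) / (n - 1)) * sqrt(sum(dy^2) / (n - 1)))
}

oracle_scale <- function(x) {
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}

# First-PC score vector via explicit eigendecomposition of the formed
# correlation matrix (the package uses an SVD of the standardized rows).
oracle_first_pc <- function(rows, reference = NULL) {
  z <- t(apply(rows, 1L, oracle_scale))
  if (nrow(rows) == 1L) {
    s <- z[1L, ]
  } else {
    r <- stats::cor(t(rows))
    w <- eigen(r, symmetric = TRUE)$vectors[, 1L]
    s <- drop(w %*% z)
  }
  if (!is.null(reference) && stats::cor(s, reference) < 0) s <- -s
  s
}

# ARI by brute-force enumeration of all item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_label) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      recurse(c(prefix, lab), max(max_label, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Random matrix whose rows all have clearly nonzero variance.
random_matrix <- function(k, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(k * n), k, n)
  dimnames(m) <- list(sprintf("f%03d", seq_len(k)), sprintf("s%03d", seq_len(n)))
  m
}

# A pair (m, c) whose sample correlation is exactly rho: c is built from
# scale(m) and an orthogonalized standardized residual.
pair_with_correlation <- function(m, rho) {
  z <- oracle_scale(m)
  repeat {
    w <- rnorm(length(m))
    r <- w - mean(w)
    r <- r - sum(r * z) / sum(z * z) * z
    if (sum(r^2) > 1e-8) break
  }
  u <- r / sqrt(sum(r^2) / (length(m) - 1))
  rho * z + sqrt(1 - rho^2) * u
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

write_tsv_matrix <- function(x, path) {
  lines <- c(paste(c("feature_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(x, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  path
}
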