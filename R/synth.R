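#' Generate a paired synthetic dataset with a planted cluster signal
#'
#' Emulates the data regime the adjustment method assumes: two platforms
#' profiling the same samples share a latent, cluster-structured signal,
#' each observed through independent Gaussian noise, while a subset of
#' samples in the main matrix additionally carries a strong platform-specific
#' bias. Concretely:
#' \itemize{
#'   \item samples are assigned round-robin to `k_clusters` clusters; each
#'     latent feature draws one mean per cluster from `N(0, signal_sd^2)`;
#'   \item every main feature observes its latent feature plus
#'     `N(0, noise_sd^2)` noise; each associated feature is assigned to a
#'     latent feature (about `n_assoc_features / n_main_features` partners
#'     each) and observes the same latent signal through independent noise;
#'   \item `n_biased_samples` randomly chosen samples receive a single
#'     Gaussian column offset (s.d. `bias_sd`) added to every main-matrix
#'     feature — a batch-like effect that displaces those columns in sample
#'     space without touching the associated matrix.
#' }
#' Annotations place each main feature (a gene-like TSS anchor) and its
#' partner features (peak-like midpoint anchors) inside one shared window
#' per latent feature; windows are tiled `10 * max_distance` apart so
#' neighbor search never leaks across latent features. Bias draws happen
#' after all signal and noise draws, so two generations at the same seed
#' that differ only in `bias_sd` are identical outside the biased columns.
#'
#' With `matched_ids = TRUE` the associated matrix instead gets exactly the
#' main matrix's feature IDs (requires `n_assoc_features ==
#' n_main_features`), emulating one-to-one designs such as expression paired
#' with per-gene copy number; annotations are still produced but unused by
#' the matched pipeline path.
#'
#' @param n_samples,n_main_features,n_assoc_features Dimensions. The default
#'   `n_assoc_features` is `n_main_features * neighbors_per_gene`.
#' @param k_clusters Number of planted sample clusters (<= `n_samples`).
#' @param signal_sd S.d. of the per-cluster latent means (default 1).
#' @param noise_sd S.d. of the per-platform observation noise (default 0.5).
#' @param n_biased_samples Number of main-matrix columns receiving bias
#'   (default 10).
#' @param bias_sd S.d. of the per-sample column offset (default 2, i.e.
#'   twice the signal scale).
#' @param neighbors_per_gene Associated partners per main feature used for
#'   the default `n_assoc_features` and for annotation spacing (default 5).
#' @param max_distance Neighbor window the annotations are built for
#'   (default 1e5 bp).
#' @param seed Integer seed fixing all randomness.
#' @param matched_ids Generate a one-to-one row-matched pair instead of the
#'   neighbor-structured pair.
#' @return Object of class `concordia_sim`: list with `main`, `assoc`,
#'   `main_annot`, `assoc_annot`, `true_labels`, `bias_mask` and `params`.
#' @export
generate_paired_dataset <- function(n_samples = 60L,
                                    n_main_features = 300L,
                                    n_assoc_features = NULL,
                                    k_clusters = 4L,
                                    signal_sd = 1,
                                    noise_sd = 0.5,
                                    n_biased_samples = 10L,
                                    bias_sd = 2,
                                    neighbors_per_gene = 5L,
                                    max_distance = 100000L,
                                    seed = 1L,
                                    matched_ids = FALSE) {
  if (is.null(n_assoc_features)) {
    n_assoc_features <- if (matched_ids) n_main_features else
      n_main_features * neighbors_per_gene
  }
  if (k_clusters > n_samples) stop_validation("k_clusters must be <= n_samples")
  if (k_clusters < 1L) stop_validation("k_clusters must be >= 1")
  if (n_biased_samples > n_samples) {
    stop_validation("n_biased_samples must be <= n_samples")
  }
  if (signal_sd < 0 || noise_sd < 0 || bias_sd < 0) {
    stop_validation("standard deviations must be >= 0")
  }
  if (matched_ids && n_assoc_features != n_main_features) {
    stop_validation("matched_ids requires n_assoc_features == n_main_features")
  }
  if (n_samples < 3L) stop_validation("need at least 3 samples")

  set.seed(seed)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  main_ids <- sprintf("gene_%04d", seq_len(n_main_features))
  assoc_ids <- if (matched_ids) main_ids else
    sprintf("peak_%05d", seq_len(n_assoc_features))

  labels <- stats::setNames(rep_len(seq_len(k_clusters), n_samples), sample_ids)

  # latent cluster means: one per (latent feature, cluster)
  mu <- matrix(stats::rnorm(n_main_features * k_clusters, sd = signal_sd),
               n_main_features, k_clusters)
  signal <- mu[, labels, drop = FALSE]

  main <- signal + matrix(stats::rnorm(n_main_features * n_samples, sd = noise_sd),
                          n_main_features, n_samples)
  # round-robin assignment of associated features to latent features
  unit <- ((seq_len(n_assoc_features) - 1L) %% n_main_features) + 1L
  assoc <- signal[unit, , drop = FALSE] +
    matrix(stats::rnorm(n_assoc_features * n_samples, sd = noise_sd),
           n_assoc_features, n_samples)
  dimnames(main) <- list(main_ids, sample_ids)
  dimnames(assoc) <- list(assoc_ids, sample_ids)

  # bias last in the RNG stream: bias_sd only scales these draws
  biased <- sample.int(n_samples, n_biased_samples)
  bias_mask <- stats::setNames(rep(FALSE, n_samples), sample_ids)
  bias_mask[biased] <- TRUE
  offsets <- stats::rnorm(n_biased_samples) * bias_sd
  if (n_biased_samples > 0L) {
    main[, biased] <- main[, biased] +
      matrix(offsets, nrow = n_main_features, ncol = n_biased_samples, byrow = TRUE)
  }

  # one shared window per latent feature, tiled far apart
  tile <- 10L * as.integer(max_distance)
  gene_start <- (seq_len(n_main_features) - 1L) * tile
  main_annot <- data.frame(feature_id = main_ids, chrom = "chr1",
                           start = gene_start, end = gene_start + 1000L,
                           strand = "+", stringsAsFactors = FALSE)
  per_unit <- ceiling(n_assoc_features / n_main_features)
  spacing <- max(1L, as.integer(max_distance) %/% (per_unit + 1L))
  rank_in_unit <- ((seq_len(n_assoc_features) - 1L) %/% n_main_features) + 1L
  centre <- gene_start[unit] + rank_in_unit * spacing
  assoc_annot <- data.frame(feature_id = assoc_ids, chrom = "chr1",
                            start = pmax(centre - 75L, 0L), end = centre + 75L,
                            strand = ".", stringsAsFactors = FALSE)

  structure(list(main = main, assoc = assoc,
                 main_annot = main_annot, assoc_annot = assoc_annot,
                 true_labels = labels, bias_mask = bias_mask,
                 params = list(n_samples = n_samples,
                               n_main_features = n_main_features,
                               n_assoc_features = n_assoc_features,
                               k_clusters = k_clusters,
                               signal_sd = signal_sd, noise_sd = noise_sd,
                               n_biased_samples = n_biased_samples,
                               bias_sd = bias_sd,
                               neighbors_per_gene = neighbors_per_gene,
                               max_distance = max_distance, seed = seed,
                               matched_ids = matched_ids)),
            class = "concordia_sim")
}

#' @export
print.concordia_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic paired dataset: %d samples in %d clusters\n  main %d x %d, associated %d x %d (%s)\n",
    p$n_samples, p$k_clusters, nrow(x$main), ncol(x$main),
    nrow(x$assoc), ncol(x$assoc),
    if (p$matched_ids) "row-matched" else "neighbor-structured"))
  cat(sprintf("  signal_sd %g, noise_sd %g, bias_sd %g on %d sample(s); seed %d\n",
              p$signal_sd, p$noise_sd, p$bias_sd, p$n_biased_samples, p$seed))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the two matrices as TSV, the annotations as BED, the true cluster
#' labels as a two-column TSV and the generator parameters as YAML-like
#' key-value text, under a common file prefix.
#'
#' @param sim A `concordia_sim` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim <- function(sim, prefix) {
  if (!inherits(sim, "concordia_sim")) stop_validation("sim must be a concordia_sim")
  paths <- c(main = paste0(prefix, "_main.tsv"),
             assoc = paste0(prefix, "_assoc.tsv"),
             main_annot = paste0(prefix, "_main.bed"),
             assoc_annot = paste0(prefix, "_assoc.bed"),
             labels = paste0(prefix, "_labels.tsv"),
             params = paste0(prefix, "_params.txt"))
  write_omics_matrix(sim$main, paths[["main"]])
  write_omics_matrix(sim$assoc, paths[["assoc"]])
  write_bed <- function(ann, path) {
    utils::write.table(
      data.frame(ann$chrom, ann$start, ann$end, ann$feature_id, 0L, ann$strand),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_bed(sim$main_annot, paths[["main_annot"]])
  write_bed(sim$assoc_annot, paths[["assoc_annot"]])
  utils::write.table(
    data.frame(sample_id = names(sim$true_labels), cluster = sim$true_labels,
               biased = as.integer(sim$bias_mask)),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(names(sim$params), ": ", unlist(sim$params)), paths[["params"]])
  invisible(paths)
}
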