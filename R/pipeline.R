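#' Run the full concordance-adjustment pipeline on a matrix pair
#'
#' Orchestrates the end-to-end method: validate the matched-column contract,
#' decide whether the rows are one-to-one matched, otherwise build the
#' coordinate-based neighbor map and summarize the associated matrix into
#' the main feature space, optionally choose `cutoff2` empirically from the
#' realized row correlations, and apply the row-wise three-scenario
#' adjustment.
#'
#' When the feature ID sets of the two matrices are identical the associated
#' matrix is row-reordered to the main matrix and used directly; otherwise
#' both annotations are required. The main and associated roles are freely
#' swappable: rerunning with the matrices exchanged adjusts the other
#' platform.
#'
#' @param main Numeric feature-by-sample matrix to adjust (rownames =
#'   feature IDs, colnames = sample IDs).
#' @param assoc Associated numeric matrix on the same samples.
#' @param main_annot,assoc_annot Annotation data frames (see
#'   [read_feature_annotation()]); required only when rows are not
#'   one-to-one matched.
#' @param cutoff1,cutoff2 Correlation gates (defaults 0 and 0.5).
#' @param auto_cutoff2 If `TRUE`, replace `cutoff2` by the empirical
#'   `(1 - target_fraction)` quantile of the realized row correlations, so
#'   about `target_fraction` of the rows take the scenario-3 update.
#' @param target_fraction Scenario-3 target for `auto_cutoff2` (default 1/3).
#' @param max_neighbors,max_distance Neighbor-search caps (defaults 50
#'   partners within 100 kb; use `max_neighbors = 20` when summarizing
#'   gene-type features around peaks).
#' @param anchor_main,anchor_assoc Anchor rule per matrix, `"tss"` or
#'   `"midpoint"` (see [add_anchors()]).
#' @return Object of class `concordia_fit`: list with `result` (a
#'   `concordia_adjustment`: adjusted matrix plus per-row diagnostics),
#'   `summarized` (the matched or summarized partner matrix), `skip`
#'   (named logical) and `report` (scenario counts, cutoffs used, mode,
#'   timings, input fingerprints).
#' @examples
#' sim <- generate_paired_dataset(n_samples = 20, n_main_features = 40,
#'                                k_clusters = 2, seed = 7)
#' fit <- concordia(sim$main, sim$assoc, sim$main_annot, sim$assoc_annot)
#' fit$report$scenario_counts
#' @export
concordia <- function(main, assoc,
                      main_annot = NULL, assoc_annot = NULL,
                      cutoff1 = 0, cutoff2 = 0.5,
                      auto_cutoff2 = FALSE, target_fraction = 1 / 3,
                      max_neighbors = 50L, max_distance = 100000L,
                      anchor_main = "tss", anchor_assoc = "midpoint") {
  t0 <- proc.time()[["elapsed"]]
  pair <- validate_pair(main, assoc)
  main <- pair$main
  assoc <- pair$assoc
  mode <- detect_row_matching(main, assoc)

  if (mode == "matched") {
    partner <- assoc[rownames(main), , drop = FALSE]
    skip <- stats::setNames(rep(FALSE, nrow(main)), rownames(main))
    nmap <- NULL
  } else {
    if (is.null(main_annot) || is.null(assoc_annot)) {
      stop_validation(
        "feature IDs of the two matrices are not one-to-one matched; ",
        "provide coordinate annotations for both matrices so the associated ",
        "matrix can be summarized by genomic neighborhood")
    }
    main_annot <- add_anchors(main_annot, anchor_main)
    assoc_annot <- add_anchors(assoc_annot, anchor_assoc)
    nmap <- build_neighbor_map(main_annot, assoc_annot,
                               max_neighbors = max_neighbors,
                               max_distance = max_distance)
    summ <- summarize_associated(assoc, nmap, main)
    partner <- summ$summarized
    skip <- summ$skip
  }

  # degenerate main rows are skipped regardless of the partner
  degenerate <- !apply(main, 1L, has_variance)
  skip <- skip | degenerate

  cutoff2_mode <- if (auto_cutoff2) "empirical" else "fixed"
  if (auto_cutoff2) {
    rho <- rep(NA_real_, nrow(main))
    for (i in seq_len(nrow(main))) {
      if (!skip[i] && has_variance(partner[i, ])) {
        rho[i] <- stats::cor(partner[i, ], main[i, ])
      }
    }
    cutoff2 <- select_cutoff2(rho, target_fraction)
    if (cutoff2 <= cutoff1) {
      stop_validation("empirical cutoff2 (", signif(cutoff2, 4),
                      ") does not exceed cutoff1 (", cutoff1,
                      "); the matrices are too discordant for scenario-3 gating")
    }
  }

  result <- adjust_matrix(main, partner, cutoff1, cutoff2, skip = skip)
  counts <- table(factor(result$scenario,
                         levels = c("scenario1", "scenario2", "scenario3", "skipped")))
  report <- list(
    n_features = nrow(main), n_samples = ncol(main),
    mode = mode,
    scenario_counts = counts,
    n_skipped = sum(result$scenario == "skipped"),
    cutoff1 = cutoff1, cutoff2 = cutoff2, cutoff2_mode = cutoff2_mode,
    runtime_sec = proc.time()[["elapsed"]] - t0,
    fingerprint = c(main_rows = nrow(main), main_cols = ncol(main),
                    assoc_rows = nrow(assoc), assoc_cols = ncol(assoc),
                    main_sum = sum(main), assoc_sum = sum(assoc)))
  structure(list(result = result, summarized = partner, skip = skip,
                 neighbor_map = nmap, report = report),
            class = "concordia_fit")
}

#' @export
print.concordia_fit <- function(x, ...) {
  r <- x$report
  cat("Concordance-adjustment run\n")
  cat(sprintf("  %d features x %d samples; rows %s\n",
              r$n_features, r$n_samples,
              if (r$mode == "matched") "one-to-one matched" else
                "summarized by genomic neighborhood"))
  cat(sprintf("  cutoff1 = %g, cutoff2 = %g (%s)\n",
              r$cutoff1, r$cutoff2, r$cutoff2_mode))
  for (nm in names(r$scenario_counts)) {
    cat(sprintf("  %-10s %6d\n", nm, r$scenario_counts[[nm]]))
  }
  cat(sprintf("  runtime: %.2f s\n", r$runtime_sec))
  invisible(x)
}

#' File-level pipeline run
#'
#' Reads the matrices (and annotations when given) from disk, runs
#' [concordia()], and writes the adjusted matrix, a per-feature diagnostics
#' TSV (`feature_id`, `rho`, `scenario`) and a plain-text run report. All
#' computation completes before any output file is opened, so a failing run
#' never leaves partial outputs.
#'
#' @param main_path,assoc_path Matrix TSV paths.
#' @param out_path Output path for the adjusted matrix.
#' @param main_annot_path,assoc_annot_path Optional BED-like annotation
#'   paths.
#' @param diagnostics_path,report_path Optional output paths.
#' @param ... Further arguments passed to [concordia()].
#' @return The `concordia_fit`, invisibly.
#' @export
concordia_files <- function(main_path, assoc_path, out_path,
                            main_annot_path = NULL, assoc_annot_path = NULL,
                            diagnostics_path = NULL, report_path = NULL, ...) {
  main <- read_omics_matrix(main_path)
  assoc <- read_omics_matrix(assoc_path)
  main_annot <- if (!is.null(main_annot_path)) read_feature_annotation(main_annot_path)
  assoc_annot <- if (!is.null(assoc_annot_path)) read_feature_annotation(assoc_annot_path)
  fit <- concordia(main, assoc, main_annot, assoc_annot, ...)
  write_omics_matrix(fit$result$adjusted, out_path)
  if (!is.null(diagnostics_path)) {
    utils::write.table(
      data.frame(feature_id = rownames(main),
                 rho = sprintf("%.6g", fit$result$row_correlation),
                 scenario = fit$result$scenario),
      diagnostics_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report_path)) {
    r <- fit$report
    writeLines(c(
      sprintf("features: %d", r$n_features),
      sprintf("samples: %d", r$n_samples),
      sprintf("mode: %s", r$mode),
      sprintf("cutoff1: %g", r$cutoff1),
      sprintf("cutoff2: %g", r$cutoff2),
      sprintf("cutoff2_mode: %s", r$cutoff2_mode),
      sprintf("%s: %d", names(r$scenario_counts), as.integer(r$scenario_counts)),
      sprintf("runtime_sec: %.3f", r$runtime_sec)), report_path)
  }
  invisible(fit)
}
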