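#' Read a BED-like feature annotation table
#'
#' Tab-separated, 0-based half-open coordinates (BED convention), columns:
#' chromosome, start, end, feature_id, optional score (ignored), optional
#' strand (`+`, `-` or `.`). Lines starting with `#` are skipped. Duplicate
#' feature IDs are a hard error: silent disambiguation risks wrong matching.
#'
#' @param path Path to the annotation file.
#' @return Data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_feature_annotation <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop_validation("annotation '", path,
                    "' needs at least 4 columns (chrom, start, end, feature_id)")
  }
  strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else rep(".", nrow(df))
  ann <- data.frame(feature_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    strand = strand,
                    stringsAsFactors = FALSE)
  validate_annotation(ann, path)
}

validate_annotation <- function(ann, label = "annotation") {
  required <- c("feature_id", "chrom", "start", "end")
  if (!all(required %in% names(ann))) {
    stop_validation(label, " must have columns ", paste(required, collapse = ", "))
  }
  if (is.null(ann$strand)) ann$strand <- rep(".", nrow(ann))
  ann$strand[!ann$strand %in% c("+", "-")] <- "."
  dup <- ann$feature_id[duplicated(ann$feature_id)]
  if (length(dup)) {
    stop_validation("duplicate feature ID(s) in ", label, ": ",
                    paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(ann$start)) || any(!is.finite(ann$end))) {
    stop_validation(label, ": start/end must be integers")
  }
  if (any(ann$start < 0L)) stop_validation(label, ": start must be >= 0")
  if (any(ann$end < ann$start)) stop_validation(label, ": end must be >= start")
  ann
}

#' Compute per-feature anchor coordinates
#'
#' Two anchoring rules are supported, both in 0-based coordinates:
#' \describe{
#'   \item{`"tss"`}{strand-aware transcription start site: `start` for `+`
#'     or unknown strand, `end` for `-` strand (genes);}
#'   \item{`"midpoint"`}{`floor((start + end) / 2)` (interval features such
#'     as accessibility peaks).}
#' }
#'
#' @param annot Annotation data frame (see [read_feature_annotation()]).
#' @param rule `"tss"` or `"midpoint"`.
#' @return The annotation with an added integer `anchor` column.
#' @export
add_anchors <- function(annot, rule = c("tss", "midpoint")) {
  rule <- match.arg(rule)
  annot <- validate_annotation(annot)
  annot$anchor <- if (rule == "tss") {
    ifelse(annot$strand == "-", annot$end, annot$start)
  } else {
    (annot$start + annot$end) %/% 2L
  }
  annot
}

#' Build the main-to-associated neighbor map from genomic anchors
#'
#' For each main feature, finds associated features on the same chromosome
#' whose anchors lie within `max_distance` base pairs of the main anchor,
#' sorted nearest first and truncated to `max_neighbors`. Distance ties are
#' broken by the lower anchor coordinate, then lexicographic feature ID, so
#' the map is byte-identical regardless of input record order. Candidate
#' pairs are found with [GenomicRanges::findOverlaps()] on anchor points.
#'
#' @param main_annot,assoc_annot Annotation data frames carrying an `anchor`
#'   column (see [add_anchors()]).
#' @param max_neighbors Maximum partners per main feature (>= 1). The
#'   convention is 50 when summarizing peaks around genes and 20 when
#'   summarizing genes around peaks.
#' @param max_distance Maximum anchor distance in base pairs (default 1e5).
#' @return Object of class `neighbor_map`: list with `neighbors` and
#'   `distances` (named lists keyed by main feature ID, sorted), plus the
#'   caps used. An empty neighbor vector marks a feature to be skipped.
#' @export
build_neighbor_map <- function(main_annot, assoc_annot,
                               max_neighbors = 50L, max_distance = 100000L) {
  if (is.null(main_annot$anchor) || is.null(assoc_annot$anchor)) {
    stop_validation("annotations must carry an 'anchor' column; see add_anchors()")
  }
  if (nrow(main_annot) == 0L || nrow(assoc_annot) == 0L) {
    stop_validation("annotation sets must be non-empty")
  }
  if (max_neighbors < 1L) stop_validation("max_neighbors must be >= 1")
  if (max_distance < 0L) stop_validation("max_distance must be >= 0")

  mg <- GenomicRanges::GRanges(main_annot$chrom,
                               IRanges::IRanges(start = main_annot$anchor + 1L, width = 1L))
  ag <- GenomicRanges::GRanges(assoc_annot$chrom,
                               IRanges::IRanges(start = assoc_annot$anchor + 1L, width = 1L))
  # disjoint chromosome sets legitimately yield no hits; GenomicRanges warns
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(mg, ag, maxgap = max_distance),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- abs(main_annot$anchor[qi] - assoc_annot$anchor[si])
  keep <- d <= max_distance
  qi <- qi[keep]; si <- si[keep]; d <- d[keep]

  ids <- sort(main_annot$feature_id)
  neighbors <- stats::setNames(vector("list", length(ids)), ids)
  distances <- stats::setNames(vector("list", length(ids)), ids)
  ord <- order(qi, d, assoc_annot$anchor[si], assoc_annot$feature_id[si],
               method = "radix")
  qi <- qi[ord]; si <- si[ord]; d <- d[ord]
  split_s <- split(si, main_annot$feature_id[qi])
  split_d <- split(d, main_annot$feature_id[qi])
  for (id in ids) {
    s <- split_s[[id]]
    if (is.null(s)) {
      neighbors[[id]] <- character(0)
      distances[[id]] <- integer(0)
    } else {
      take <- seq_len(min(length(s), max_neighbors))
      neighbors[[id]] <- assoc_annot$feature_id[s[take]]
      distances[[id]] <- as.integer(split_d[[id]][take])
    }
  }
  structure(list(neighbors = neighbors, distances = distances,
                 max_neighbors = as.integer(max_neighbors),
                 max_distance = as.integer(max_distance)),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  sizes <- lengths(x$neighbors)
  cat(sprintf("Neighbor map: %d main features, caps %d neighbors / %d bp\n",
              length(sizes), x$max_neighbors, x$max_distance))
  cat(sprintf("  features with neighbors: %d (median %d per feature); skipped: %d\n",
              sum(sizes > 0), if (any(sizes > 0)) stats::median(sizes[sizes > 0]) else 0L,
              sum(sizes == 0)))
  invisible(x)
}

#' Summarize the associated matrix into the main matrix's feature space
#'
#' For every main feature, extracts the neighbor sub-matrix from the
#' associated matrix and reduces it to one row: the first principal
#' component score of the standardized neighbor rows (PCA on their
#' correlation matrix), sign-aligned with the main feature's row so that the
#' summarized partner never anti-correlates with it. Main features with no
#' neighbors, missing annotation, or only degenerate (zero-variance)
#' neighbor rows are flagged skipped and receive a zero placeholder row.
#'
#' @param assoc Associated numeric matrix (features x samples).
#' @param nmap Neighbor map from [build_neighbor_map()].
#' @param main Main numeric matrix; supplies the feature order and the
#'   per-row reference vectors for sign alignment.
#' @return List with `summarized` (matrix shaped like `main`) and `skip`
#'   (named logical vector).
#' @export
summarize_associated <- function(assoc, nmap, main) {
  if (!inherits(nmap, "neighbor_map")) stop_validation("nmap must be a neighbor_map")
  ids <- rownames(main)
  summarized <- matrix(0, nrow = nrow(main), ncol = ncol(main),
                       dimnames = dimnames(main))
  skip <- stats::setNames(rep(FALSE, length(ids)), ids)
  unannotated <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    nb <- nmap$neighbors[[id]]
    if (is.null(nb)) {
      skip[i] <- TRUE
      unannotated <- c(unannotated, id)
      next
    }
    nb <- nb[nb %in% rownames(assoc)]
    if (length(nb) == 0L) {
      skip[i] <- TRUE
      next
    }
    sub <- assoc[nb, , drop = FALSE]
    ok <- apply(sub, 1L, has_variance)
    if (!any(ok)) {
      skip[i] <- TRUE
      next
    }
    ref <- main[i, ]
    if (!has_variance(ref)) ref <- NULL
    summarized[i, ] <- first_pc_rows(sub[ok, , drop = FALSE], reference = ref)
  }
  if (length(unannotated)) {
    warning("main feature(s) absent from annotation, skipped: ",
            paste(unannotated, collapse = ", "), call. = FALSE)
  }
  list(summarized = summarized, skip = skip)
}

#' Decide whether two matrices are row-matched
#'
#' Returns `"matched"` when the two feature ID sets are identical (one row
#' in each matrix measures the same entity, e.g. a gene's expression and its
#' copy number), in which case summarization is bypassed and the associated
#' matrix is simply row-reordered to the main matrix's order. Any other ID
#' relationship returns `"unmatched"` and requires coordinate annotations.
#'
#' @param main,assoc Numeric matrices with feature IDs as rownames.
#' @return `"matched"` or `"unmatched"`.
#' @export
detect_row_matching <- function(main, assoc) {
  if (is.null(rownames(main)) || is.null(rownames(assoc))) return("unmatched")
  if (setequal(rownames(main), rownames(assoc)) &&
      nrow(main) == nrow(assoc)) "matched" else "unmatched"
}
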