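#' Read a feature-by-sample matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers; the body must be fully numeric and finite. The header may or
#' may not carry a label for the feature-ID column. Ragged rows, duplicate
#' feature or sample identifiers, and non-numeric or non-finite cells are
#' rejected with the offending coordinates in the message.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  header <- scan(path, what = character(), sep = "\t", nlines = 1L,
                 quiet = TRUE, quote = "")
  body <- tryCatch(
    utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                      colClasses = "character", quote = "", comment.char = "",
                      fill = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop_validation("matrix file '", path, "' is empty")
      }
      stop_validation("malformed matrix file '", path, "': ",
                      conditionMessage(e))
    })
  if (nrow(body) == 0L || ncol(body) < 2L) {
    stop_validation("matrix file '", path, "' is empty")
  }
  if (length(header) == ncol(body)) {
    sample_ids <- header[-1L]             # header labels the feature-ID column
  } else if (length(header) == ncol(body) - 1L) {
    sample_ids <- header
  } else {
    stop_validation("header of '", path, "' has ", length(header),
                    " fields but data rows have ", ncol(body))
  }
  feature_ids <- body[[1L]]
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) {
    stop_validation("duplicate feature ID(s) in '", path, "': ",
                    paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop_validation("duplicate sample ID(s) in '", path, "': ",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  values <- suppressWarnings(
    vapply(body[-1L], as.numeric, numeric(nrow(body))))
  values <- matrix(values, nrow = nrow(body))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation("non-numeric or non-finite cell in '", path, "' at feature '",
                    feature_ids[bad[1L, 1L]], "', sample '",
                    sample_ids[bad[1L, 2L]], "' (value '",
                    body[bad[1L, 1L], bad[1L, 2L] + 1L], "')")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Write a feature-by-sample matrix as tab-separated text
#'
#' Mirrors the dialect read by [read_omics_matrix()]: a `feature_id` header
#' column followed by sample IDs, numeric values formatted with 12
#' significant digits so round trips are stable.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(x, path) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop_validation("x must be a matrix with feature and sample names")
  }
  body <- matrix(sprintf("%.12g", x), nrow = nrow(x))
  lines <- c(paste(c("feature_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Validate and align a main/associated matrix pair on samples
#'
#' The two matrices must profile exactly the same samples. If the sample ID
#' sets are equal but ordered differently, the associated matrix's columns
#' are reordered to the main matrix's order; any set difference is a hard
#' error listing the offending IDs on each side.
#'
#' @param main,assoc Numeric matrices with sample IDs as colnames.
#' @return List with elements `main` and `assoc`, column-aligned.
#' @export
validate_pair <- function(main, assoc) {
  ms <- colnames(main)
  as_ <- colnames(assoc)
  if (is.null(ms) || is.null(as_)) stop_validation("both matrices need sample IDs")
  only_main <- setdiff(ms, as_)
  only_assoc <- setdiff(as_, ms)
  if (length(only_main) || length(only_assoc)) {
    stop_validation(
      "sample sets differ; only in main: {",
      paste(only_main, collapse = ", "), "}; only in associated: {",
      paste(only_assoc, collapse = ", "), "}")
  }
  list(main = main, assoc = assoc[, ms, drop = FALSE])
}
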