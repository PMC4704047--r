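#' Count matrix with a sample design
#'
#' A thin container pairing an integer feature-by-sample count matrix with
#' the sample design (caste, replicate).
#'
#' @param counts integer matrix, rows = features, columns = samples; must
#'   carry row and column names.
#' @param design data.frame with columns `sample`, `caste` (and optionally
#'   `replicate`); `design$sample` must match `colnames(counts)` in order.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("count_matrix: counts must have row and column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("count_matrix: duplicate feature or sample IDs", call. = FALSE)
  if (!identical(colnames(counts), design$sample))
    stop("count_matrix: design samples must match count columns in order",
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers",
         call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", paste(unique(x$design$caste), collapse = "/"), ")\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' TSV layout: first column `feature`, remaining columns one per sample
#' (header row = sample IDs).
#'
#' @param x a [count_matrix()].
#' @param path file path.
#' @return `path` (write) / a [count_matrix()] (read).
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path file path.
#' @param design sample design matching the file's columns.
#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, design) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  missing <- setdiff(design$sample, colnames(m))
  if (length(missing))
    stop("read_count_matrix: sample(s) missing from ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  count_matrix(m[, design$sample, drop = FALSE], design)
}
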