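#' Construct a hairpin-by-sample count matrix
#'
#' Counts are non-negative integers with hairpins as rows and samples as
#' columns; per-sample library sizes are the column sums and are always
#' recomputed, never user-set.
#'
#' @param counts integer matrix (or coercible) with rownames = hairpin ids
#'   and colnames = sample ids.
#' @return a `count_matrix`: an integer matrix with a `lib_sizes` attribute.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have hairpin rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated hairpin row(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, lib_sizes = colSums(counts),
            class = c("count_matrix", class(counts)))
}

#' Per-sample library sizes of a count matrix
#' @param cm a [count_matrix] (or plain matrix; column sums are used).
#' @return named numeric vector of column sums.
#' @export
lib_sizes <- function(cm) {
  ls <- attr(cm, "lib_sizes")
  if (is.null(ls)) ls <- colSums(cm)
  ls
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix: %d hairpins x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(lib_sizes(x)), big.mark = ",")))
  invisible(x)
}

#' Read / write hairpin count tables
#'
#' TSV with first column `hairpin_id` and one integer column per sample.
#' `write_counts` then `read_counts` round-trips the matrix, sample order
#' included; library sizes are recomputed on read.
#'
#' @param path TSV path.
#' @return [read_counts] returns a [count_matrix].
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "hairpin_id") {
    stop("counts TSV must have 'hairpin_id' as its first column")
  }
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell(s) in ", path)
  rownames(m) <- ids
  count_matrix(m)
}

#' @rdname read_counts
#' @param cm a [count_matrix].
#' @export
write_counts <- function(cm, path) {
  tab <- data.frame(hairpin_id = rownames(cm), as.data.frame(unclass(cm)),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Counts per million
#'
#' `cpm[i, j] = 1e6 * counts[i, j] / lib_size[j]`, the abundance scale used
#' for the low-count filter.
#'
#' @param cm a [count_matrix] or integer matrix.
#' @param lib.sizes optional per-sample totals; defaults to column sums.
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(cm, lib.sizes = NULL) {
  if (is.null(lib.sizes)) lib.sizes <- lib_sizes(cm)
  if (any(lib.sizes <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(cm)[lib.sizes <= 0], collapse = ", "))
  }
  sweep(unclass(cm), 2L, lib.sizes, "/") * 1e6
}
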