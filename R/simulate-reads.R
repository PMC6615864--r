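#' Simulate barcode sequencing reads from a count matrix
#'
#' Emits one single-end read per count: the hairpin guide at the read start,
#' random bases appended up to `read_len` (36 bp in the screens modelled
#' here), and uniform per-base substitutions at `error_rate`. Qualities are
#' constant Phred+33. With `error_rate = 0`, counting the output with
#' [quantify()] reproduces the input matrix exactly.
#'
#' @param cm a [count_matrix] whose rows appear in `lib`.
#' @param lib an [shrna_library] providing guide sequences.
#' @param dir output directory (created if needed).
#' @param error_rate per-base substitution probability.
#' @param read_len read length, >= the guide length.
#' @param quality_char single Phred+33 quality character for every base.
#' @param seed integer RNG seed.
#' @return named character vector of FASTQ paths, one per sample column.
#' @export
simulate_fastq <- function(cm, lib, dir, error_rate = 0, read_len = 36L,
                           quality_char = "F", seed = 1L) {
  L <- attr(lib, "guide_length")
  if (read_len < L) stop("read_len must be >= the guide length (", L, ")")
  idx <- match(rownames(cm), lib$hairpin_id)
  if (anyNA(idx)) stop("count rows missing from library")
  guides <- lib$guide_seq[idx]
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")

  paths <- character(0)
  for (j in seq_len(ncol(cm))) {
    sample_id <- colnames(cm)[j]
    n <- sum(cm[, j])
    path <- file.path(dir, paste0(sample_id, ".fastq"))
    if (n == 0L) {
      file.create(path)
      paths[sample_id] <- path
      next
    }
    seqs <- rep(guides, cm[, j])
    if (read_len > L) {
      tail_mat <- matrix(sample(bases, n * (read_len - L), replace = TRUE),
                         nrow = n)
      seqs <- paste0(seqs, apply(tail_mat, 1L, paste, collapse = ""))
    }
    if (error_rate > 0) {
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      nrow = n, byrow = TRUE)
      hit <- which(matrix(stats::runif(n * read_len) < error_rate, nrow = n))
      if (length(hit)) {
        # substitute with one of the three other bases
        old <- chars[hit]
        sub <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
        chars[hit] <- sub
        seqs <- apply(chars, 1L, paste, collapse = "")
      }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("%s_read%d", sample_id, seq_len(n))
    qual <- Biostrings::BStringSet(rep(strrep(quality_char, read_len), n))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
    paths[sample_id] <- path
  }
  paths
}
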