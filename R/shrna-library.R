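#' Construct and validate an shRNA hairpin library
#'
#' An `shrna_library` maps hairpin identifiers to guide sequences, target
#' genes and pool labels. It is the reference against which barcode reads
#' are counted and the gene map used for gene-level aggregation.
#'
#' @param hairpin_id character vector of unique hairpin identifiers.
#' @param guide_seq character vector of guide sequences (alphabet A/C/G/T/N),
#'   all of one common length (22 nt in the screens this package models).
#' @param gene character vector of gene symbols (uppercased on construction).
#' @param pool pool labels (e.g. `"1"`..`"12"` or `"custom"`).
#' @param class hairpin class, `"target"` or `"control"`.
#'
#' @return A data frame of class `shrna_library` with columns
#'   `hairpin_id`, `guide_seq`, `gene`, `pool`, `class` and attribute
#'   `guide_length`. Duplicate guide sequences are permitted but recorded in
#'   the `duplicated_guides` attribute.
#' @export
shrna_library <- function(hairpin_id, guide_seq, gene,
                          pool = "1", class = "target") {
  hairpin_id <- as.character(hairpin_id)
  guide_seq <- toupper(as.character(guide_seq))
  gene <- normalize_gene_symbols(gene)
  n <- length(hairpin_id)
  stopifnot(length(guide_seq) == n, length(gene) == n)
  pool <- rep_len(as.character(pool), n)
  class <- rep_len(as.character(class), n)

  if (anyDuplicated(hairpin_id)) {
    stop("duplicate hairpin_id: ",
         paste(unique(hairpin_id[duplicated(hairpin_id)]), collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", guide_seq))) {
    bad <- hairpin_id[grepl("[^ACGTN]", guide_seq)]
    stop("non-DNA characters in guide_seq for: ", paste(bad, collapse = ", "))
  }
  lens <- unique(nchar(guide_seq))
  if (length(lens) > 1L) {
    stop("all guide sequences must have the same length; found lengths ",
         paste(lens, collapse = ", "))
  }
  if (!all(class %in% c("target", "control"))) {
    stop("class must be 'target' or 'control'")
  }
  lib <- data.frame(hairpin_id = hairpin_id, guide_seq = guide_seq,
                    gene = gene, pool = pool, class = class,
                    stringsAsFactors = FALSE)
  attr(lib, "guide_length") <- if (n > 0L) lens else NA_integer_
  dup <- unique(guide_seq[duplicated(guide_seq)])
  attr(lib, "duplicated_guides") <- dup
  class(lib) <- c("shrna_library", "data.frame")
  lib
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shRNA library: %d hairpins, %d genes, %d pool(s), guide length %s nt\n",
              nrow(x), length(unique(x$gene)), length(unique(x$pool)),
              attr(x, "guide_length")))
  ndup <- length(attr(x, "duplicated_guides"))
  if (ndup > 0L) cat(sprintf("  note: %d duplicated guide sequence(s)\n", ndup))
  invisible(x)
}

#' Uppercase and whitespace-strip gene symbols
#'
#' Canonical gene keys are required for set operations across screens.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_symbols <- function(x) {
  toupper(gsub("\\s+", "", as.character(x)))
}

#' Read an shRNA library from TSV or FASTA
#'
#' The TSV dialect has columns `hairpin_id`, `guide_seq`, `gene`, `pool`
#' and optionally `class`. The FASTA dialect encodes the metadata in the
#' header as pipe-delimited fields `>hairpin_id|gene|pool`, the guide being
#' the sequence itself.
#'
#' @param path path to the library file.
#' @param format `"tsv"` or `"fasta"`.
#' @return an [shrna_library].
#' @export
read_library <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("hairpin_id", "guide_seq", "gene", "pool")
    missing <- setdiff(need, names(tab))
    if (length(missing)) {
      stop("library TSV is missing column(s): ", paste(missing, collapse = ", "))
    }
    cls <- if ("class" %in% names(tab)) tab$class else "target"
    shrna_library(tab$hairpin_id, tab$guide_seq, tab$gene, tab$pool, cls)
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    fields <- strsplit(names(seqs), "|", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("FASTA headers must be 'hairpin_id|gene|pool'")
    }
    shrna_library(vapply(fields, `[`, "", 1L),
                  as.character(seqs),
                  vapply(fields, `[`, "", 2L),
                  vapply(fields, `[`, "", 3L))
  }
}

#' Write an shRNA library to TSV
#'
#' @param lib an [shrna_library].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
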