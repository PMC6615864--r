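#' Read a FASTQ file into an in-memory read set
#'
#' @param path FASTQ (optionally gzipped) path.
#' @return a `read_set`: list with character vectors `id`, `seq`, `qual` and
#'   a `dropped` counter carried through the processing chain.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) {
    return(structure(list(id = character(0), seq = character(0),
                          qual = character(0), dropped = 0L),
                     class = "read_set"))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  structure(list(id = names(x),
                 seq = as.character(x),
                 qual = as.character(S4Vectors::mcols(x)$qualities),
                 dropped = 0L),
            class = "read_set")
}

.read_set <- function(id, seq, qual, dropped) {
  structure(list(id = id, seq = seq, qual = qual, dropped = dropped),
            class = "read_set")
}

#' Trim reads to a fixed length from the 5' end
#'
#' Reads shorter than `length` are dropped and counted in the `dropped`
#' field; qualities are trimmed in lockstep with the bases.
#'
#' @param reads a `read_set` from [read_fastq()].
#' @param length target length (default 22, the guide length).
#' @return a `read_set` in which every read is exactly `length` nt.
#' @export
trim_reads <- function(reads, length = 22L) {
  keep <- nchar(reads$seq) >= length
  .read_set(reads$id[keep],
            substr(reads$seq[keep], 1L, length),
            substr(reads$qual[keep], 1L, length),
            reads$dropped + sum(!keep))
}

#' Trim low-quality bases from the 3' end
#'
#' Removes the maximal trailing run of bases with Phred quality below
#' `min_q` (Phred+33 encoding). Reads left empty are dropped and counted.
#'
#' @param reads a `read_set`.
#' @param min_q minimum Phred quality score retained at the 3' end.
#' @return a quality-trimmed `read_set`.
#' @export
quality_filter <- function(reads, min_q = 20L) {
  n <- length(reads$seq)
  if (n == 0L) return(reads)
  keep_len <- vapply(reads$qual, function(q) {
    qs <- utf8ToInt(q) - 33L
    if (any(qs < 0L)) stop("quality character below the Phred+33 floor")
    good <- which(qs >= min_q)
    if (length(good)) max(good) else 0L
  }, 0L, USE.NAMES = FALSE)
  keep <- keep_len > 0L
  .read_set(reads$id[keep],
            substr(reads$seq[keep], 1L, keep_len[keep]),
            substr(reads$qual[keep], 1L, keep_len[keep]),
            reads$dropped + sum(!keep))
}

#' Count reads against a hairpin library by hash matching
#'
#' The reference is a fixed set of equal-length guides, so counting is a
#' dictionary lookup rather than positional alignment. In `exact` mode a
#' read must equal a guide. In `one_mismatch` mode a read is assigned iff
#' exactly one hairpin's guide lies at the minimal Hamming distance (0 or
#' 1); reads with two or more guides at that distance (including exact hits
#' on guides shared by several hairpins) are discarded as ambiguous.
#'
#' @param reads a `read_set` or a character vector of read sequences, all of
#'   the library's guide length.
#' @param lib an [shrna_library].
#' @param mode `"exact"` or `"one_mismatch"`.
#' @return list with `counts` (named integer vector over `lib$hairpin_id`)
#'   and `stats` (a `quant_stats` list: total/matched/ambiguous reads,
#'   match rate, hairpins detected).
#' @export
match_hairpins <- function(reads, lib, mode = c("exact", "one_mismatch")) {
  mode <- match.arg(mode)
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  L <- attr(lib, "guide_length")
  if (length(seqs) && any(nchar(seqs) != L)) {
    stop("reads must match the library guide length (", L, " nt)")
  }
  counts <- integer(nrow(lib))
  names(counts) <- lib$hairpin_id
  n_amb <- 0L

  if (length(seqs)) {
    guide_tab <- table(factor(lib$guide_seq, levels = unique(lib$guide_seq)))
    uniq_guides <- names(guide_tab)
    # hairpin index of each unique guide; NA when the guide is shared
    hp_of_guide <- match(uniq_guides, lib$guide_seq)
    hp_of_guide[guide_tab > 1L] <- NA_integer_

    hit <- match(seqs, uniq_guides)
    exact_assign <- hp_of_guide[hit]
    amb_exact <- !is.na(hit) & is.na(exact_assign)
    ok <- !is.na(exact_assign)
    if (any(ok)) {
      t0 <- tabulate(exact_assign[ok], nbins = nrow(lib))
      counts <- counts + t0
    }
    n_amb <- n_amb + sum(amb_exact)

    if (mode == "one_mismatch") {
      todo <- which(is.na(hit))
      if (length(todo)) {
        sub <- seqs[todo]
        pair_read <- integer(0)   # index into `todo`
        pair_guide <- integer(0)  # index into `uniq_guides`
        for (i in seq_len(L)) {
          pre <- substr(sub, 1L, i - 1L)
          post <- substr(sub, i + 1L, L)
          for (b in c("A", "C", "G", "T")) {
            v <- match(paste0(pre, b, post), uniq_guides)
            found <- which(!is.na(v))
            if (length(found)) {
              pair_read <- c(pair_read, found)
              pair_guide <- c(pair_guide, v[found])
            }
          }
        }
        if (length(pair_read)) {
          guide_sets <- split(pair_guide, pair_read)
          for (k in names(guide_sets)) {
            gidx <- unique(guide_sets[[k]])
            hps <- which(!is.na(match(lib$guide_seq, uniq_guides[gidx])))
            if (length(hps) == 1L) {
              counts[hps] <- counts[hps] + 1L
            } else {
              n_amb <- n_amb + 1L
            }
          }
        }
      }
    }
  }

  matched <- sum(counts)
  stats <- structure(list(total_reads = length(seqs),
                          matched_reads = matched,
                          ambiguous_reads = n_amb,
                          match_rate = if (length(seqs)) matched / length(seqs) else NA_real_,
                          hairpins_detected = sum(counts > 0L),
                          fraction_reference_detected = sum(counts > 0L) / nrow(lib)),
                     class = "quant_stats")
  list(counts = counts, stats = stats)
}

#' Quantify hairpin abundance from FASTQ files
#'
#' Composes the read-processing chain: trim to the guide length, 3' quality
#' filter, drop reads shorter than the guide, then hash-match against the
#' library. Hairpins never observed keep a zero-count row.
#'
#' @param fastq_paths character vector of FASTQ paths, named by sample id.
#' @param lib an [shrna_library].
#' @param mode matching mode, see [match_hairpins()].
#' @param min_q 3' quality threshold, see [quality_filter()].
#' @return list with `counts` (a [count_matrix], rows = all library
#'   hairpins) and `stats` (per-sample `quant_stats`, including read-QC
#'   attrition).
#' @export
quantify <- function(fastq_paths, lib, mode = c("exact", "one_mismatch"),
                     min_q = 20L) {
  mode <- match.arg(mode)
  if (is.null(names(fastq_paths)) || any(!nzchar(names(fastq_paths)))) {
    stop("fastq_paths must be named by sample id")
  }
  L <- attr(lib, "guide_length")
  cols <- matrix(0L, nrow(lib), length(fastq_paths),
                 dimnames = list(lib$hairpin_id, names(fastq_paths)))
  stats <- vector("list", length(fastq_paths))
  names(stats) <- names(fastq_paths)
  for (j in seq_along(fastq_paths)) {
    rs <- read_fastq(fastq_paths[[j]])
    total <- length(rs$seq)
    rs <- trim_reads(rs, length = L)
    rs <- quality_filter(rs, min_q = min_q)
    rs <- trim_reads(rs, length = L)  # drop reads shortened below L
    if (length(rs$seq) == 0L) {
      warning("sample ", names(fastq_paths)[j],
              ": no reads survived QC; all-zero column")
    }
    res <- match_hairpins(rs, lib, mode = mode)
    cols[, j] <- res$counts
    st <- res$stats
    st$total_reads <- total
    st$reads_after_qc <- length(rs$seq)
    st$match_rate <- if (st$reads_after_qc) st$matched_reads / st$reads_after_qc else NA_real_
    stats[[j]] <- st
  }
  list(counts = count_matrix(cols), stats = stats)
}
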