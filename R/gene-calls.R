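#' Call one gene from its hairpins' differential statistics
#'
#' A gene is significantly depleted for a contrast if at least
#' `ceiling(frac * n_hairpins)` OR at least `min_n` of its hairpins are
#' significantly depleted (FDR <= alpha and log2FC < 0) and the median
#' log2FC is negative; it is a sensitiser if that median additionally
#' falls at or below `fc_cut`. Both sides of the "50% or 3 hairpins"
#' disjunction suffice on their own. The median is taken over the
#' significantly depleted hairpins by default (`median_over = "significant"`),
#' or over all hairpins of the gene.
#'
#' @param hairpin_rows rows of a `differential_result` for one gene and one
#'   contrast (columns `log2FC`, `FDR`).
#' @param alpha FDR threshold (default 0.05).
#' @param frac fraction-of-hairpins rule (default 0.5, applied as ceiling).
#' @param min_n absolute-count rule (default 3).
#' @param fc_cut sensitiser median log2FC threshold (default -1, inclusive).
#' @param median_over `"significant"` or `"all"`.
#' @return one-row data frame: `n_hairpins`, `n_sig_depleted`,
#'   `median_log2FC`, `class` (`not_called`, `depleted` or `sensitiser`).
#' @export
call_gene <- function(hairpin_rows, alpha = 0.05, frac = 0.5, min_n = 3L,
                      fc_cut = -1, median_over = c("significant", "all")) {
  median_over <- match.arg(median_over)
  n <- nrow(hairpin_rows)
  if (is.null(n) || n == 0L) stop("empty hairpin slice")
  sig <- !is.na(hairpin_rows$FDR) & hairpin_rows$FDR <= alpha &
    hairpin_rows$log2FC < 0
  n_sig <- sum(sig)
  med <- if (median_over == "significant") {
    if (n_sig > 0L) stats::median(hairpin_rows$log2FC[sig]) else NA_real_
  } else {
    stats::median(hairpin_rows$log2FC)
  }
  hit <- (n_sig >= ceiling(frac * n) || n_sig >= min_n) &&
    n_sig > 0L && !is.na(med) && med < 0
  cls <- if (!hit) "not_called" else if (med <= fc_cut) "sensitiser" else "depleted"
  data.frame(n_hairpins = n, n_sig_depleted = n_sig,
             median_log2FC = if (is.na(med)) NA_real_ else med,
             class = cls, stringsAsFactors = FALSE)
}

#' Gene-level calls for every gene and contrast of a screen
#'
#' Applies [call_gene()] per gene x contrast over a `differential_result`.
#' Library genes whose hairpins were all removed by the abundance filter
#' (hence absent from the result) are reported as `untested`.
#'
#' @param dr a `differential_result` from [run_differential()] with a
#'   `gene` column.
#' @param lib optional [shrna_library] used to report untested genes.
#' @param ... thresholds passed to [call_gene()].
#' @return data frame: `gene`, `contrast`, `n_hairpins`, `n_sig_depleted`,
#'   `median_log2FC`, `class`.
#' @export
classify_screen <- function(dr, lib = NULL, ...) {
  if (all(is.na(dr$gene))) stop("differential result has no gene annotation")
  out <- list()
  for (ctr in unique(dr$contrast)) {
    d <- dr[dr$contrast == ctr, , drop = FALSE]
    calls <- do.call(rbind, lapply(split(d, d$gene), call_gene, ...))
    calls <- data.frame(gene = rownames(calls), contrast = ctr, calls,
                        stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(lib)) {
      missing <- setdiff(unique(lib$gene), calls$gene)
      if (length(missing)) {
        calls <- rbind(calls, data.frame(
          gene = missing, contrast = ctr, n_hairpins = 0L,
          n_sig_depleted = 0L, median_log2FC = NA_real_,
          class = "untested", stringsAsFactors = FALSE))
      }
    }
    out[[ctr]] <- calls
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes called under a ligand but not under vehicle
#'
#' Set difference of a ligand's called-gene set against the DMSO
#' depleted-gene set: the screen's definition of ligand-specific effects.
#' Idempotent: applying it twice changes nothing.
#'
#' @param ligand_set character vector of genes called under the ligand.
#' @param dmso_set character vector of genes depleted under vehicle.
#' @return character vector.
#' @export
ligand_specific <- function(ligand_set, dmso_set) {
  setdiff(ligand_set, dmso_set)
}

#' Cross-screen set logic for sensitiser gene sets
#'
#' Given, per screen, the (already ligand-specific) sensitiser sets for each
#' ligand, computes per-ligand Venn counts across screens, the per-screen
#' "common to both ligands" sets, the union totals, and the key genes:
#' genes present for BOTH ligands in ALL screens. Overlap percentages are
#' reported as `100 * |intersection| / |reference set|`.
#'
#' @param screens named list; each element a named list of character gene
#'   vectors, one per ligand (same ligand names across screens).
#' @return list with `per_ligand` (per ligand: per-screen sizes,
#'   intersection, union and Venn region counts), `both_ligands_per_screen`,
#'   `key_genes`, and `totals`.
#' @export
combine_and_intersect <- function(screens) {
  if (!length(screens) || is.null(names(screens))) {
    stop("screens must be a non-empty named list")
  }
  ligands <- names(screens[[1L]])
  for (s in screens) {
    if (!identical(sort(names(s)), sort(ligands))) {
      stop("all screens must provide the same ligand sets")
    }
  }
  per_ligand <- lapply(ligands, function(lg) {
    sets <- lapply(screens, `[[`, lg)
    venn <- venn_counts(sets)
    list(sizes = lengths(sets),
         union = Reduce(union, sets),
         intersection = Reduce(intersect, sets),
         venn = venn)
  })
  names(per_ligand) <- ligands
  both <- lapply(screens, function(s) Reduce(intersect, s))
  key <- Reduce(intersect, both)
  list(per_ligand = per_ligand,
       both_ligands_per_screen = both,
       key_genes = key,
       totals = vapply(per_ligand, function(x) length(x$union), 0L))
}

#' Overlap percentage of one gene set against a reference set
#'
#' @param set,reference character vectors.
#' @return list with `n_overlap` and `percent` (= 100 * overlap / |reference|).
#' @export
overlap_percent <- function(set, reference) {
  n <- length(intersect(set, reference))
  list(n_overlap = n, percent = 100 * n / length(reference))
}

#' Venn region counts for 1-3 named sets
#'
#' Exclusive region sizes; they sum to the union cardinality.
#'
#' @param sets named list of character vectors.
#' @return named integer vector of exclusive region counts.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 1L, k <= 3L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  all_el <- Reduce(union, sets)
  member <- vapply(sets, function(s) all_el %in% s, logical(length(all_el)))
  member <- matrix(member, ncol = k)
  pattern <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- table(pattern)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
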