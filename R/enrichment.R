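#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, tab-separated genes per line).
#' @return named list of uppercase-normalized gene symbol vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, normalize_gene_symbols)
}

#' Fisher fold enrichment of a hit list in a target gene set
#'
#' With a full universe: `fold = (a/n) / (K/N)` and a one-sided (greater)
#' Fisher exact p, the hypergeometric tail `P(X >= a)`. Alternatively the
#' background may be supplied as a plain proportion (as when only the
#' percentage of genes in the target collection is known): then
#' `fold = (a/n) / background_prop` and the p-value is the binomial tail,
#' labelled `"binomial"` in the output.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param universe character vector of all tested genes; or `NULL` when
#'   `background_prop` is given.
#' @param target character vector, the gene set tested for enrichment
#'   (intersected with the universe first); ignored in proportion mode.
#' @param background_prop optional background proportion in (0, 1).
#' @param a_override hit-in-set count when using `background_prop` without
#'   an explicit target set.
#' @return data frame: `a`, `n`, `K`, `N`, `fold`, `p`, `method`.
#' @export
fisher_enrichment <- function(hits, universe = NULL, target = NULL,
                              background_prop = NULL, a_override = NULL) {
  hits <- normalize_gene_symbols(hits)
  if (!length(hits)) stop("empty hit list")
  n <- length(unique(hits))
  if (!is.null(background_prop)) {
    if (background_prop <= 0 || background_prop >= 1) {
      stop("background_prop must lie in (0, 1)")
    }
    a <- if (!is.null(a_override)) a_override else
      length(intersect(hits, normalize_gene_symbols(target)))
    fold <- (a / n) / background_prop
    p <- stats::pbinom(a - 1L, n, background_prop, lower.tail = FALSE)
    return(data.frame(a = a, n = n, K = NA_integer_, N = NA_integer_,
                      fold = fold, p = p, method = "binomial",
                      stringsAsFactors = FALSE))
  }
  universe <- unique(normalize_gene_symbols(universe))
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(unique(hits), universe)
  if (length(outside)) {
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(outside, 10L), collapse = ", "))
  }
  target <- intersect(unique(normalize_gene_symbols(target)), universe)
  N <- length(universe)
  K <- length(target)
  a <- length(intersect(unique(hits), target))
  fold <- if (K > 0) (a / n) / (K / N) else NA_real_
  p <- if (K > 0) fisher_exact_p(a, n, K, N) else 1
  data.frame(a = a, n = n, K = K, N = N, fold = fold, p = p,
             method = "hypergeometric", stringsAsFactors = FALSE)
}

#' Right-sided hypergeometric enrichment over a gene-set collection
#'
#' One test per set, with Bonferroni (`p_adj = min(1, m p)`, m = number of
#' sets) or BH adjustment. Sets with zero overlap with the universe are
#' tested with K = 0 (p = 1) and flagged.
#'
#' @param hits,universe as in [fisher_enrichment()].
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param correction `"bonferroni"` or `"bh"`.
#' @return data frame, one row per set, with the [fisher_enrichment()]
#'   columns plus `set`, `p_adj` and `empty_set` flag, ordered as the
#'   collection.
#' @export
hypergeom_rightsided_batch <- function(hits, universe, collection,
                                       correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  if (!length(collection)) stop("empty gene-set collection")
  rows <- lapply(collection, function(tg) {
    fisher_enrichment(hits, universe, tg)
  })
  res <- do.call(rbind, rows)
  res <- data.frame(set = names(collection), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$empty_set <- res$K == 0L
  res$p_adj <- if (correction == "bonferroni") {
    pmin(1, length(collection) * res$p)
  } else {
    bh_adjust(res$p)
  }
  res
}

#' One-sided (greater) Fisher exact p for a 2x2 enrichment table
#'
#' The hypergeometric tail `P(X >= a)` for `a` hits among `n` draws from a
#' universe of `N` genes of which `K` are in the set.
#'
#' @param a hits in the set.
#' @param n total hits.
#' @param K set size within the universe.
#' @param N universe size.
#' @return the one-sided p-value.
#' @export
fisher_exact_p <- function(a, n, K, N) {
  stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
}

#' EASE score: jackknifed one-sided Fisher p-value
#'
#' The one-sided Fisher p computed after removing one hit from the overlap
#' cell (`a` replaced by `a - 1` with margins fixed), a conservative
#' penalization of small overlaps; `a = 1` gives p = 1.
#'
#' @param a hits in the set (>= 1).
#' @param n total hits.
#' @param K set size within the universe.
#' @param N universe size.
#' @return the EASE p-value.
#' @export
ease_score <- function(a, n, K, N) {
  if (a < 1L) stop("EASE requires at least one hit in the set (a >= 1)")
  fisher_exact_p(a - 1L, n, K, N)
}
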