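#' Construct / read a screen sample sheet
#'
#' One row per sequenced sample with the experimental design annotation:
#' pool, timepoint (`t0` is the post-selection reference; `tF`, or free
#' labels such as `t7`/`t15`, the endpoint), treatment
#' (`none`/`DMSO`/`PDS`/`PhenDC3`/other) and replicate number.
#' `(pool, timepoint, treatment, replicate)` must be unique.
#'
#' @param sample_id,pool,timepoint,treatment,replicate vectors of equal length.
#' @return data frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, pool, timepoint, treatment, replicate) {
  ss <- data.frame(sample_id = as.character(sample_id),
                   pool = as.character(pool),
                   timepoint = as.character(timepoint),
                   treatment = as.character(treatment),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id")
  if (any(ss$replicate < 1L)) stop("replicate must be a positive integer")
  key <- with(ss, paste(pool, timepoint, treatment, replicate, sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (pool, timepoint, treatment, replicate) combination")
  }
  class(ss) <- c("sample_sheet", "data.frame")
  ss
}

#' @rdname sample_sheet
#' @param path CSV with columns sample_id,pool,timepoint,treatment,replicate.
#' @export
read_samplesheet <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pool", "timepoint", "treatment", "replicate")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  sample_sheet(tab$sample_id, tab$pool, tab$timepoint, tab$treatment,
               tab$replicate)
}

#' @rdname sample_sheet
#' @param ss a `sample_sheet`.
#' @export
write_samplesheet <- function(ss, path) {
  utils::write.csv(as.data.frame(ss), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group label of each sample within its pool
#'
#' The unit of replication for the differential analysis: `t0` samples form
#' the reference group, endpoint samples are grouped by treatment.
#'
#' @param ss a [sample_sheet].
#' @return character vector, one label per row of `ss`.
#' @export
sample_groups <- function(ss) {
  ifelse(ss$timepoint == "t0", "t0", paste0(ss$treatment, ".", ss$timepoint))
}

#' Cross-check a count matrix against its sample sheet
#'
#' Verifies that every endpoint treatment group has a matching `t0` group in
#' its pool (fatal if not), reports replicate counts per group, and warns
#' about count columns absent from the sheet.
#'
#' @param cm a [count_matrix].
#' @param ss a [sample_sheet].
#' @return invisibly, a list with `groups` (replicate counts per
#'   pool x group) and `orphan_samples`.
#' @export
validate_design <- function(cm, ss) {
  orphans <- setdiff(colnames(cm), ss$sample_id)
  if (length(orphans)) {
    warning("count column(s) not in sample sheet: ",
            paste(orphans, collapse = ", "))
  }
  grp <- sample_groups(ss)
  tab <- as.data.frame(table(pool = ss$pool, group = grp))
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "n_replicates"
  for (p in unique(ss$pool)) {
    in_pool <- ss$pool == p
    if (any(ss$timepoint[in_pool] != "t0") && !any(ss$timepoint[in_pool] == "t0")) {
      stop("pool ", p, " has endpoint samples but no t0 reference group")
    }
  }
  invisible(list(groups = tab, orphan_samples = orphans))
}
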