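# Small in-code fixtures shared across test files.

toy_library <- function(n_genes = 2L, k = 3L, len = 6L, seed = 42L) {
  set.seed(seed)
  H <- n_genes * k
  guides <- character(0)
  while (length(guides) < H) {
    guides <- unique(c(guides, paste(
      sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  }
  genes <- rep(sprintf("G%02d", seq_len(n_genes)), each = k)
  shrna_library(sprintf("h%02d", seq_len(H)), guides[seq_len(H)], genes)
}

toy_counts <- function(H = 6L, n = 4L, lambda = 50, seed = 9L,
                       sample_ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  m <- matrix(rpois(H * n, lambda), H, n,
              dimnames = list(sprintf("h%02d", seq_len(H)), sample_ids))
  count_matrix(m)
}

# A 12-sample one-pool design: t0 + three endpoint arms, three replicates.
toy_design <- function() {
  sample_sheet(
    sample_id = c(paste0("t0_r", 1:3), paste0("DMSO_tF_r", 1:3),
                  paste0("PDS_tF_r", 1:3), paste0("PhenDC3_tF_r", 1:3)),
    pool = "1",
    timepoint = rep(c("t0", "tF", "tF", "tF"), each = 3),
    treatment = rep(c("none", "DMSO", "PDS", "PhenDC3"), each = 3),
    replicate = rep(1:3, 4))
}

# Differential-result-like slice for call_gene tests.
fake_slice <- function(fdr, log2fc) {
  data.frame(FDR = fdr, log2FC = log2fc)
}
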