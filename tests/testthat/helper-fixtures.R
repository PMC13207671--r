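# Small in-code fixtures shared across test files.

tiny_meta <- function(n_per_group = 3, n_blanks = 0, batches = c("b1", "b2")) {
  n <- 2 * n_per_group
  ids <- sprintf("s%02d", seq_len(n + n_blanks))
  data.frame(
    sample_id = ids,
    group = c(rep(c("control", "storage"), each = n_per_group),
              rep(NA_character_, n_blanks)),
    batch = c(rep(batches, length.out = n),
              rep(batches, length.out = n_blanks)),
    is_blank = c(rep(FALSE, n), rep(TRUE, n_blanks)),
    stringsAsFactors = FALSE)
}

tiny_matrix <- function(values, n_prot, n_samp, prot_prefix = "p",
                        samp_ids = NULL) {
  m <- matrix(values, n_prot, n_samp)
  dimnames(m) <- list(sprintf("%s%02d", prot_prefix, seq_len(n_prot)),
                      if (is.null(samp_ids))
                        sprintf("s%02d", seq_len(n_samp)) else samp_ids)
  m
}

# Complete two-group two-batch log2 dataset with known planted structure.
planted_dataset <- function(n_proteins = 300, n_per_group = 12, seed = 1,
                            lfc = 1.5, frac_up = 0.1, sigma_cell = 0.5,
                            batch_shift = 0) {
  set.seed(seed)
  meta <- tiny_meta(n_per_group)
  n <- nrow(meta)
  mu <- rnorm(n_proteins, 20, 2)
  n_up <- round(frac_up * n_proteins)
  truth <- c(rep(lfc, n_up), rep(0, n_proteins - n_up))
  is_sto <- as.numeric(meta$group == "storage")
  is_b2 <- as.numeric(meta$batch == "b2")
  m <- outer(mu, rep(1, n)) + outer(truth, is_sto) +
    outer(rep(batch_shift, n_proteins), is_b2) +
    matrix(rnorm(n_proteins * n, 0, sigma_cell), n_proteins, n)
  dimnames(m) <- list(sprintf("p%03d", seq_len(n_proteins)),
                      meta$sample_id)
  list(matrix = m, meta = meta, true_lfc = truth)
}
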