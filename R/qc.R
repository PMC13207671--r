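# QC stages: procedural-blank background subtraction, sample-depth filter,
# replicate-detection filter, group overlap counts, correlation matrix.

#' Subtract procedural-blank background
#'
#' For each protein, the mean linear intensity across blank samples
#' (missing treated as 0) is subtracted from every cell sample's linear
#' intensity. Results <= 0 become missing; blank columns are dropped from
#' the output. A per-protein mean (rather than max) blank is used to be
#' robust to a single noisy blank, and flooring to missing keeps the
#' left-censored missing-data semantics.
#'
#' @param m Linear-intensity matrix (`NA` = missing).
#' @param meta Sample metadata (must flag >= 1 blank present in `m`).
#' @return Matrix restricted to cell samples, background-subtracted.
#' @export
subtract_blank_background <- function(m, meta) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("sample(s) in matrix absent from metadata: ",
         paste(colnames(m)[is.na(meta$sample_id)], collapse = ", "))
  blank_cols <- which(meta$is_blank)
  if (length(blank_cols) == 0)
    stop("no blank samples in matrix; skip blank subtraction explicitly ",
         "if the design has no procedural blanks")
  blanks <- m[, blank_cols, drop = FALSE]
  blanks[is.na(blanks)] <- 0
  bg <- rowMeans(blanks)
  out <- m[, -blank_cols, drop = FALSE] - bg
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Filter samples by identification depth
#'
#' Removes samples with fewer than `min_proteins` non-missing protein
#' identifications (strictly fewer: a sample at exactly the threshold is
#' kept).
#'
#' @param m Intensity matrix.
#' @param min_proteins Minimum identifications (default 900).
#' @return List with `matrix` (retained samples) and `report` (data.frame
#'   `sample_id`, `n_proteins`, `retained`, `reason`).
#' @export
filter_samples_by_depth <- function(m, min_proteins = 900) {
  stopifnot(min_proteins >= 0)
  counts <- colSums(!is.na(m))
  keep <- counts >= min_proteins
  if (!any(keep))
    stop("all samples excluded at min_proteins = ", min_proteins)
  report <- data.frame(sample_id = colnames(m),
                       n_proteins = as.integer(counts),
                       retained = keep,
                       reason = ifelse(keep, "",
                                       sprintf("fewer than %d protein identifications",
                                               min_proteins)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = m[, keep, drop = FALSE], report = report)
}

#' Filter proteins by replicate detection
#'
#' A protein is retained iff it is detected (non-missing) in at least
#' `min_reps` samples within at least one of the two biological groups.
#'
#' @param m Intensity matrix (cell samples).
#' @param meta Sample metadata.
#' @param min_reps Minimum replicates in some group (default 4).
#' @return Filtered matrix.
#' @export
filter_proteins_by_detection <- function(m, meta, min_reps = 4) {
  idx <- group_indices(m, meta)
  sizes <- vapply(idx, length, integer(1))
  if (all(min_reps > sizes))
    stop("min_reps = ", min_reps, " exceeds both group sizes (",
         paste(sizes, collapse = ", "), "); no protein can pass")
  cnt_a <- rowSums(!is.na(m[, idx[[1]], drop = FALSE]))
  cnt_b <- rowSums(!is.na(m[, idx[[2]], drop = FALSE]))
  keep <- cnt_a >= min_reps | cnt_b >= min_reps
  m[keep, , drop = FALSE]
}

#' Group-wise detection overlap
#'
#' A protein counts as detected in a group if it is non-missing in at
#' least one of that group's samples. Returns the shared count and the
#' counts exclusive to each group (alphabetical group order).
#'
#' @param m Intensity matrix.
#' @param meta Sample metadata.
#' @return Named list `shared`, `only_a`, `only_b`, `groups`.
#' @export
overlap_counts <- function(m, meta) {
  idx <- group_indices(m, meta)
  det_a <- rowSums(!is.na(m[, idx[[1]], drop = FALSE])) > 0
  det_b <- rowSums(!is.na(m[, idx[[2]], drop = FALSE])) > 0
  list(shared = sum(det_a & det_b),
       only_a = sum(det_a & !det_b),
       only_b = sum(!det_a & det_b),
       groups = names(idx))
}

#' Pairwise Pearson correlation between samples
#'
#' On a log2-scale matrix. Before imputation (`use = "pairwise"`) each
#' pair's r is computed over proteins observed in both samples; after
#' imputation (`use = "all"`) over all proteins. Pairs with fewer than 3
#' mutually observed proteins get `NA` with a warning.
#'
#' @param m Log2-scale matrix.
#' @param use `"pairwise"` (default) or `"all"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m, use = c("pairwise", "all")) {
  use <- match.arg(use)
  if (ncol(m) < 2) stop("need >= 2 samples for a correlation matrix")
  if (use == "all") {
    if (anyNA(m)) stop("use = 'all' requires a complete matrix")
    r <- stats::cor(m)
  } else {
    suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
    mutual <- crossprod(!is.na(m))
    thin <- mutual < 3
    diag(thin) <- FALSE
    if (any(thin)) {
      warning("sample pair(s) with < 3 mutually observed proteins; r set to NA")
      r[thin] <- NA_real_
    }
  }
  diag(r) <- 1
  r
}

#' Assemble a QC report
#'
#' Combines per-sample identification counts, retention flags, overlap
#' counts, and the pairwise correlation matrix.
#'
#' @param depth_report Report from [filter_samples_by_depth()].
#' @param overlap Result of [overlap_counts()].
#' @param cor_matrix Result of [correlation_matrix()].
#' @return List of class `qc_report`.
#' @export
qc_report <- function(depth_report, overlap, cor_matrix) {
  structure(list(sample_depth = depth_report, overlap = overlap,
                 correlation = cor_matrix), class = "qc_report")
}
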