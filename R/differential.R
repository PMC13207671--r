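# Differential abundance: pooled-variance two-sample t-tests,
# Benjamini-Hochberg FDR, DEP classes at FDR < 0.05 and |FC| >= 1.5,
# top-k z-score clustering, and a PCA-silhouette group-separation score.

#' Two-tailed pooled-variance Student's t-test
#'
#' @param x,y Numeric vectors (log2 values) with >= 2 values each.
#' @param welch Use Welch's unequal-variance form instead (default FALSE).
#' @return List `t`, `df`, `p`. Zero pooled variance yields `t = NA`,
#'   `p = NA` with a warning (the protein is unclassifiable).
#' @export
students_t_test <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) {
      warning("zero variance; t undefined")
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) {
      warning("zero pooled variance; t undefined")
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Adjusted q-values in input order, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m > 0) {
    pv <- p[ok]
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  q
}

#' Per-protein differential abundance table
#'
#' Runs a pooled two-sample t-test per protein on the adjusted complete
#' log2 matrix, BH-adjusts across the full protein list, and classifies:
#' `up` iff q < `fdr_threshold` and linear FC >= `fc_threshold`; `down`
#' iff q < `fdr_threshold` and FC <= 1/`fc_threshold`; otherwise `ns`.
#' The fold-change boundary is inclusive (|FC| = 1.5 passes); the FDR
#' boundary is strict (q = 0.05 fails). `log2fc` is mean(test group) -
#' mean(reference group); the reference is the alphabetically first group
#' label unless `ref_group` is given.
#'
#' @param m Complete log2-scale matrix (imputed, batch-adjusted).
#' @param meta Sample metadata (two groups, >= 2 cells each).
#' @param fdr_threshold FDR cutoff (default 0.05, strict).
#' @param fc_threshold Linear fold-change cutoff (default 1.5, inclusive).
#' @param ref_group Reference (control) group label.
#' @param welch Use Welch's t instead of pooled (default FALSE).
#' @return data.frame: `protein_id`, per-group means, `log2fc`,
#'   `fc_linear`, `t`, `p`, `q`, `class`.
#' @export
differential_table <- function(m, meta, fdr_threshold = 0.05,
                               fc_threshold = 1.5, ref_group = NULL,
                               welch = FALSE) {
  idx <- group_indices(m, meta)
  groups <- names(idx)
  if (is.null(ref_group)) ref_group <- groups[1]
  if (!ref_group %in% groups) stop("unknown ref_group: ", ref_group)
  test_group <- setdiff(groups, ref_group)
  ia <- idx[[test_group]]; ib <- idx[[ref_group]]
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("each group needs >= 2 cells")
  A <- m[, ia, drop = FALSE]; B <- m[, ib, drop = FALSE]
  if (anyNA(A) || anyNA(B)) stop("matrix must be complete")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    se2 <- (((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)) *
      (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), NA_real_)
  if (anyNA(t_stat))
    warning(sum(is.na(t_stat)), " protein(s) with zero pooled variance; ",
            "reported unclassifiable")
  p <- 2 * stats::pt(-abs(t_stat), df)
  q <- bh_adjust(p)
  log2fc <- ma - mb
  fc_linear <- 2^log2fc
  class <- ifelse(is.na(q), "unclassifiable",
           ifelse(q < fdr_threshold & fc_linear >= fc_threshold, "up",
           ifelse(q < fdr_threshold & fc_linear <= 1 / fc_threshold, "down",
                  "ns")))
  out <- data.frame(protein_id = rownames(m), stringsAsFactors = FALSE)
  out[[paste0("mean_", ref_group)]] <- mb
  out[[paste0("mean_", test_group)]] <- ma
  out$log2fc <- log2fc
  out$fc_linear <- fc_linear
  out$t <- t_stat
  out$p <- p
  out$q <- q
  out$class <- class
  attr(out, "ref_group") <- ref_group
  attr(out, "test_group") <- test_group
  out
}

#' Z-scored top-k differential proteins with clustering order
#'
#' Selects the k smallest-q proteins (ties broken by larger |log2fc|,
#' then protein id), z-scores each row across cells, and orders rows by
#' average-linkage hierarchical clustering on correlation distance.
#'
#' @param m Complete log2-scale matrix.
#' @param table A [differential_table()] result.
#' @param k Number of proteins (default 60).
#' @return List `matrix` (k x cells, row-standardized, in clustering
#'   order) and `order` (selected protein ids in that order).
#' @export
zscore_top_k <- function(m, table, k = 60) {
  tab <- table[!is.na(table$q), , drop = FALSE]
  if (k > nrow(tab))
    stop("k = ", k, " exceeds the ", nrow(tab), " proteins with finite q")
  o <- order(tab$q, -abs(tab$log2fc), tab$protein_id)
  sel <- tab$protein_id[o[seq_len(k)]]
  sub <- m[sel, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  if (any(sdv == 0)) stop("selected protein(s) with zero variance cannot be z-scored")
  z <- (sub - mu) / sdv
  if (k > 2) {
    d <- stats::as.dist(1 - stats::cor(t(z)))
    ord <- stats::hclust(d, method = "average")$order
  } else ord <- seq_len(k)
  list(matrix = z[ord, , drop = FALSE], order = rownames(z)[ord])
}

#' PCA-silhouette group separation score
#'
#' Projects cells onto the top-2 principal components of the (cells x
#' proteins) matrix and returns the mean silhouette coefficient of the
#' two group labels in that plane (Euclidean distance). Values near 0
#' indicate no separation; values above ~0.5 indicate strong separation.
#'
#' @param m Complete log2-scale matrix.
#' @param meta Sample metadata.
#' @return Mean silhouette width (scalar in [-1, 1]).
#' @export
group_separation <- function(m, meta) {
  idx <- group_indices(m, meta)
  cells <- c(idx[[1]], idx[[2]])
  lab <- rep(names(idx), times = vapply(idx, length, integer(1)))
  X <- t(m[, cells, drop = FALSE])
  if (all(apply(X, 2, stats::var) == 0))
    stop("zero-variance matrix; separation undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  S <- pc$x[, seq_len(k), drop = FALSE]
  D <- as.matrix(stats::dist(S))
  n <- nrow(S)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- mean(D[i, !own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
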