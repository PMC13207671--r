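# Log2 transform + median centering, global-distribution parameter
# estimation, and left-censored (downshifted normal) imputation:
# mu_imp = mu_obs - shift * sigma_obs, sigma_imp = width * sigma_obs,
# with shift = 1.8 and width = 0.3 by default.

#' Log2-transform and median-center an intensity matrix
#'
#' Each value x becomes log2(x); each sample is then shifted so that its
#' median (over observed values) equals the global median of per-sample
#' medians. Centering to the median-of-medians (rather than zero)
#' preserves the interpretability of the log2 intensity scale. The
#' missingness pattern is unchanged.
#'
#' @param m Linear-intensity matrix (`NA` = missing; all observed > 0).
#' @return Log2-scale matrix, median-centered per sample.
#' @export
log2_and_center <- function(m) {
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive intensity at protein '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  lm <- log2(m)
  med <- apply(lm, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) stop("sample(s) with no observed values: ",
                       paste(colnames(m)[is.na(med)], collapse = ", "))
  target <- stats::median(med)
  sweep(lm, 2, med - target, "-")
}

#' Estimate global imputation parameters
#'
#' Pools ALL observed log2 intensities across samples and computes their
#' mean and (n-1 denominator) standard deviation; the derived imputation
#' distribution is Normal(mu_obs - shift * sigma_obs,
#' (width * sigma_obs)^2).
#'
#' @param m Log2-scale matrix.
#' @param shift Downshift in multiples of sigma_obs (default 1.8).
#' @param width Imputation SD in multiples of sigma_obs (default 0.3).
#' @return List of class `imputation_params` with `mu_obs`, `sigma_obs`,
#'   `shift`, `width`, `mu_imp`, `sigma_imp`.
#' @export
estimate_global_params <- function(m, shift = 1.8, width = 0.3) {
  if (shift < 0) stop("shift must be >= 0")
  if (width <= 0) stop("width must be > 0")
  obs <- m[!is.na(m)]
  if (length(obs) < 2) stop("need >= 2 observed values")
  mu_obs <- mean(obs)
  sigma_obs <- stats::sd(obs)
  if (sigma_obs == 0)
    stop("observed values are constant; sigma_obs = 0 violates invariant")
  structure(list(mu_obs = mu_obs, sigma_obs = sigma_obs,
                 shift = shift, width = width,
                 mu_imp = mu_obs - shift * sigma_obs,
                 sigma_imp = width * sigma_obs),
            class = "imputation_params")
}

#' Impute missing values from the left-censored global distribution
#'
#' Every missing entry is replaced by an independent draw from
#' Normal(mu_imp, sigma_imp^2); observed entries are untouched. Draws are
#' generated in a fixed protein-major traversal order from one seeded
#' generator, so results do not depend on storage layout.
#'
#' @param m Log2-scale matrix with `NA` for missing values.
#' @param params An `imputation_params` object.
#' @param seed RNG seed.
#' @return Complete log2-scale matrix.
#' @export
impute_left_censored <- function(m, params, seed = 1L) {
  stopifnot(inherits(params, "imputation_params"))
  miss <- which(is.na(m))
  if (length(miss) == 0) return(m)
  # protein-major order: sort linear indices by (row, then column)
  rows <- (miss - 1L) %% nrow(m) + 1L
  cols <- (miss - 1L) %/% nrow(m) + 1L
  ord <- order(rows, cols)
  set.seed(as.integer(seed) %% 2147480000L)
  draws <- stats::rnorm(length(miss), params$mu_imp, params$sigma_imp)
  m[miss[ord]] <- draws
  m
}
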