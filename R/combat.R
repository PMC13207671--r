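# Parametric empirical-Bayes batch correction (location-scale model) with
# the biological condition carried as a covariate so true group signal is
# standardized out before the batch moments are estimated and restored
# unadjusted afterwards.

#' Empirical-Bayes batch adjustment with a condition covariate
#'
#' Implements the parametric location-scale empirical-Bayes procedure on a
#' complete log2 matrix: (1) per-protein least-squares fit on a design
#' with batch indicators and the biological condition; (2) residual
#' standardization against the pooled variance; (3) batch-wise additive
#' (gamma) and scale (delta^2) estimates with method-of-moments normal /
#' inverse-gamma priors; (4) iterative EB posterior updates to
#' convergence; (5) back-adjustment: subtract gamma*, divide by delta*,
#' restore the condition-preserving standardized mean.
#'
#' Degenerate designs are refused: a single batch, or batch perfectly
#' confounded with condition. Blanks are excluded from fitting and output.
#' When a prior's dispersion collapses to zero (e.g. an identical planted
#' shift on every protein) the posterior point-mass limit is used instead
#' of the moment formulas, which would otherwise divide by zero.
#'
#' @param m Complete log2-scale matrix (post-imputation).
#' @param meta Sample metadata; `group` is the preserved covariate,
#'   `batch` the factor removed.
#' @param tolerance Absolute convergence tolerance on the EB updates
#'   (default 1e-8).
#' @param max_iter Maximum EB iterations (default 500).
#' @param override Optional list with matrices `gamma_star` and
#'   `delta_star` (batches x proteins) substituted for the EB posteriors;
#'   used for limit checks (gamma* = 0, delta* = 1 returns the input).
#' @return List with `matrix` (adjusted, cells only) and `params` (class
#'   `batch_model_params`: design estimates, EB posteriors, priors,
#'   iteration count).
#' @export
combat_adjust <- function(m, meta, tolerance = 1e-8, max_iter = 500,
                          override = NULL) {
  cm <- cell_meta(m, meta)
  Y <- m[, cm$sample_id, drop = FALSE]
  if (anyNA(Y)) stop("matrix must be complete (impute before batch correction)")
  batch <- factor(cm$batch)
  if (nlevels(batch) < 2)
    stop("single batch; skip batch correction for this design")
  if (any(table(batch) < 2))
    stop("every batch needs >= 2 samples")
  group <- factor(cm$group)

  B <- stats::model.matrix(~ 0 + batch)
  C <- if (nlevels(group) > 1)
    stats::model.matrix(~ group)[, -1, drop = FALSE] else NULL
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with condition (design matrix rank deficient: ",
         "batches ", paste(levels(batch), collapse = "/"),
         " vs groups ", paste(levels(group), collapse = "/"), ")")

  G <- nrow(Y); n <- ncol(Y)
  nb <- nlevels(batch)
  n_b <- as.integer(table(batch))

  B_hat <- solve(crossprod(X), t(X) %*% t(Y))          # p x G
  grand_mean <- crossprod(n_b / n, B_hat[seq_len(nb), , drop = FALSE])  # 1 x G
  fitted <- t(X %*% B_hat)
  var_pooled <- rowSums((Y - fitted)^2) / n
  var_pooled <- pmax(var_pooled, 1e-12)

  stand_mean <- matrix(grand_mean, G, n)
  if (!is.null(C))
    stand_mean <- stand_mean +
      t(C %*% B_hat[nb + seq_len(ncol(C)), , drop = FALSE])
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(0, nb, G, dimnames = list(levels(batch), rownames(Y)))
  delta_hat <- gamma_hat
  for (i in seq_len(nb)) {
    Zi <- Z[, batch == levels(batch)[i], drop = FALSE]
    gamma_hat[i, ] <- rowMeans(Zi)
    delta_hat[i, ] <- rowSums((Zi - gamma_hat[i, ])^2) / (n_b[i] - 1)
  }

  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  d_m <- rowMeans(delta_hat)
  d_s2 <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * d_s2 + d_m^2) / d_s2
  b_prior <- (d_m * d_s2 + d_m^3) / d_s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iterations <- integer(nb)
  if (!is.null(override)) {
    gamma_star <- override$gamma_star
    delta_star <- override$delta_star
  } else {
    for (i in seq_len(nb)) {
      Zi <- Z[, batch == levels(batch)[i], drop = FALSE]
      g_degen <- !is.finite(tau2[i]) || tau2[i] < 1e-12
      d_degen <- !is.finite(a_prior[i]) || !is.finite(b_prior[i]) ||
        d_s2[i] < 1e-24
      g_old <- gamma_hat[i, ]
      # a within-batch residual variance this far below the pooled variance
      # only arises in (near-)noiseless degenerate inputs; treat it as "no
      # scale effect" rather than dividing by a vanishing delta*
      d_old <- ifelse(delta_hat[i, ] < 1e-8, 1, delta_hat[i, ])
      iter <- 0L
      repeat {
        iter <- iter + 1L
        g_new <- if (g_degen) rep(gamma_bar[i], G) else
          (n_b[i] * tau2[i] * gamma_hat[i, ] + d_old * gamma_bar[i]) /
            (n_b[i] * tau2[i] + d_old)
        sum2 <- rowSums((Zi - g_new)^2)
        d_new <- if (d_degen) d_old else
          (0.5 * sum2 + b_prior[i]) / (n_b[i] / 2 + a_prior[i] - 1)
        change <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new; d_old <- d_new
        if (change <= tolerance) break
        if (iter >= max_iter)
          stop("EB updates did not converge after ", iter,
               " iterations (last change ", signif(change, 3), ")")
      }
      gamma_star[i, ] <- g_old
      delta_star[i, ] <- pmax(d_old, 1e-12)
      iterations[i] <- iter
    }
  }

  Z_adj <- Z
  for (i in seq_len(nb)) {
    j <- batch == levels(batch)[i]
    Z_adj[, j] <- (Z[, j, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  out <- Z_adj * sqrt(var_pooled) + stand_mean

  params <- structure(list(
    alpha = drop(grand_mean), beta = if (is.null(C)) NULL else
      B_hat[nb + seq_len(ncol(C)), , drop = FALSE],
    gamma_hat = gamma_hat, gamma_star = gamma_star,
    delta_hat = delta_hat, delta_star = delta_star,
    gamma_bar = gamma_bar, tau2 = tau2,
    a_prior = a_prior, b_prior = b_prior,
    batches = levels(batch), n_per_batch = n_b,
    iterations = iterations, tolerance = tolerance),
    class = "batch_model_params")

  list(matrix = out, params = params)
}
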