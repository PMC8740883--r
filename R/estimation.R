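#' Fit a linear mixed model with crossed batch and sample random intercepts
#'
#' Fits `y ~ 1 + (1|batch) + (1|sample)` by REML (via [lme4::lmer()]) and
#' extracts the quantities the simulation framework needs: the unconditional
#' intercept (cluster centroid along one PC), the variance contributed by
#' batch and by sample identity (tau^2 for each random effect), and the
#' per-cell residuals.
#'
#' When a grouping factor has fewer than 2 levels its random effect cannot be
#' estimated; the term is dropped, its tau^2 recorded as 0, and the fit
#' flagged (`dropped`). With both factors degenerate the model reduces to an
#' intercept-only fit. Variance estimates at the optimizer boundary come back
#' as exactly 0 with `singular = TRUE` (lme4's boundary behavior).
#'
#' @param y Numeric response vector, one value per cell (a PC coordinate).
#' @param batch,sample Factors (or coercible) of batch and sample identity,
#'   same length as `y`.
#' @return An object of class `lmm_fit`: list with `intercept`, `tau2_batch`,
#'   `tau2_sample`, `residuals`, `loglik`, `singular`, `dropped` (character
#'   vector of dropped terms), and `model` (the underlying fit, or NULL for
#'   degenerate cases).
#' @export
fit_two_random_intercepts <- function(y, batch, sample) {
  n <- length(y)
  if (n < 2) abort("Need at least 2 cells to fit variance components.")
  stopifnot(length(batch) == n, length(sample) == n)
  batch <- factor(batch)
  sample <- factor(sample)

  if (isTRUE(all.equal(var(y), 0)) || var(y) == 0) {
    return(new_lmm_fit(intercept = y[[1]], tau2_batch = 0, tau2_sample = 0,
                       residuals = rep(0, n), loglik = NA_real_,
                       singular = TRUE, dropped = c("batch", "sample")))
  }

  terms <- character()
  if (nlevels(batch) >= 2) terms <- c(terms, "(1 | batch)")
  if (nlevels(sample) >= 2) terms <- c(terms, "(1 | sample)")
  dropped <- setdiff(c("batch", "sample"),
                     c(if (nlevels(batch) >= 2) "batch",
                       if (nlevels(sample) >= 2) "sample"))

  if (length(terms) == 0) {
    mu <- mean(y)
    return(new_lmm_fit(intercept = mu, tau2_batch = 0, tau2_sample = 0,
                       residuals = y - mu, loglik = NA_real_,
                       singular = FALSE, dropped = dropped))
  }

  dat <- data.frame(y = y, batch = batch, sample = sample)
  form <- stats::as.formula(paste("y ~ 1 +", paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) max(v, 0) else 0
  }
  new_lmm_fit(
    intercept = unname(lme4::fixef(fit)[["(Intercept)"]]),
    tau2_batch = tau2("batch"),
    tau2_sample = tau2("sample"),
    residuals = unname(resid(fit)),
    loglik = as.numeric(logLik(fit)),
    singular = lme4::isSingular(fit),
    dropped = dropped,
    model = fit)
}

new_lmm_fit <- function(intercept, tau2_batch, tau2_sample, residuals, loglik,
                        singular, dropped = character(), model = NULL) {
  structure(
    list(intercept = intercept, tau2_batch = tau2_batch,
         tau2_sample = tau2_sample, residuals = residuals, loglik = loglik,
         singular = singular, dropped = dropped, model = model),
    class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> intercept %.4g; tau2 batch %.4g, sample %.4g%s\n",
              x$intercept, x$tau2_batch, x$tau2_sample,
              if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Glance at a variance-component fit
#'
#' @param x An `lmm_fit` object.
#' @param ... Unused.
#' @return One-row tibble: intercept, tau2 components, residual variance,
#'   log-likelihood, singularity flag.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(intercept = x$intercept, tau2_batch = x$tau2_batch,
         tau2_sample = x$tau2_sample,
         sigma2 = stats::var(x$residuals) * (length(x$residuals) - 1) /
           length(x$residuals),
         loglik = x$loglik, singular = x$singular)
}

#' Estimate per-cluster PC variance components from a prototype
#'
#' For every cluster and every PC, fits `PC ~ 1 + (1|batch) + (1|sample)` and
#' deconvolutes the cluster's variance along that PC into batch, sample, and
#' residual parts. Per cluster this yields the centroid mu (intercepts across
#' PCs), diagonal Sigma_B and Sigma_S (per-PC tau^2 for batch and sample),
#' and a full nPC x nPC residual covariance Sigma_C (empirical covariance of
#' the per-cell residual matrix).
#'
#' Clusters observed in a single batch (or sample) drop that random effect
#' and record zero variance for it.
#'
#' @param data A `proto_data` object.
#' @param n_pc Number of leading PCs to model (default 20, capped at the
#'   number available).
#' @return List with `centroids`, `batch_var`, `sample_var` (k x nPC
#'   matrices) and `residual_cov` (named list of nPC x nPC matrices), plus
#'   `clusters` (sorted label order).
#' @export
estimate_pc_params <- function(data, n_pc = 20) {
  stopifnot(inherits(data, "proto_data"))
  if (n_pc > ncol(data$embeddings)) {
    abort(sprintf("n_pc = %d exceeds available PCs (%d).",
                  n_pc, ncol(data$embeddings)))
  }
  emb <- data$embeddings[, seq_len(n_pc), drop = FALSE]
  meta <- data$meta
  clusters <- sort(unique(meta$cluster))
  k <- length(clusters)

  centroids <- matrix(NA_real_, k, n_pc, dimnames = list(clusters, NULL))
  batch_var <- sample_var <- centroids
  residual_cov <- vector("list", k)
  names(residual_cov) <- clusters

  for (cl in clusters) {
    idx <- which(meta$cluster == cl)
    if (length(idx) < 2) {
      abort(sprintf("Cluster '%s' has fewer than 2 cells; cannot estimate variance.", cl))
    }
    b <- factor(meta$batch[idx])
    s <- factor(meta$sample[idx])
    res_mat <- matrix(NA_real_, length(idx), n_pc)
    for (j in seq_len(n_pc)) {
      f <- fit_two_random_intercepts(emb[idx, j], b, s)
      centroids[cl, j] <- f$intercept
      batch_var[cl, j] <- f$tau2_batch
      sample_var[cl, j] <- f$tau2_sample
      res_mat[, j] <- f$residuals
    }
    residual_cov[[cl]] <- cov(res_mat)
  }
  list(clusters = clusters, centroids = centroids, batch_var = batch_var,
       sample_var = sample_var, residual_cov = residual_cov)
}

#' Estimate cluster-frequency mean and covariance across samples
#'
#' Counts cells per (sample, cluster), adds a pseudo-count of 1 to every
#' count (so clusters absent from a sample still get positive mass), and
#' converts to within-sample proportions. The returned mean is the natural
#' log of the across-sample mean proportion per cluster (mu_cf); the
#' covariance is the unbiased covariance of the per-sample log-proportion
#' vectors (Sigma_cf).
#'
#' @param data A `proto_data` object, or a data frame with `sample` and
#'   `cluster` columns (one row per cell). At least 2 samples.
#' @return List with `mean_logfreq` (length k, named) and `logfreq_cov`
#'   (k x k), cluster order sorted.
#' @export
estimate_freq_params <- function(data) {
  meta <- if (inherits(data, "proto_data")) data$meta else as_tibble(data)
  stopifnot(all(c("sample", "cluster") %in% names(meta)))
  samples <- sort(unique(meta$sample))
  clusters <- sort(unique(meta$cluster))
  if (length(samples) < 2) {
    abort("Frequency covariance is undefined with a single sample.")
  }
  counts <- table(factor(meta$sample, levels = samples),
                  factor(meta$cluster, levels = clusters))
  counts <- matrix(as.numeric(counts), nrow = length(samples),
                   dimnames = list(samples, clusters)) + 1
  props <- counts / rowSums(counts)
  mean_logfreq <- log(colMeans(props))
  logfreq_cov <- cov(log(props))
  list(mean_logfreq = mean_logfreq, logfreq_cov = logfreq_cov)
}

#' Estimate all simulation parameters from a prototype dataset
#'
#' Convenience wrapper running [estimate_pc_params()] and
#' [estimate_freq_params()] and assembling an [est_params] object.
#'
#' @inheritParams estimate_pc_params
#' @return An `est_params` object.
#' @export
estimate_params <- function(data, n_pc = 20) {
  pc <- estimate_pc_params(data, n_pc = n_pc)
  fr <- estimate_freq_params(data)
  est_params(clusters = pc$clusters, centroids = pc$centroids,
             batch_var = pc$batch_var, sample_var = pc$sample_var,
             residual_cov = pc$residual_cov,
             mean_logfreq = fr$mean_logfreq, logfreq_cov = fr$logfreq_cov)
}
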