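#' Specify a synthetic prototype dataset
#'
#' Describes a fully synthetic prototype — multiple clusters with distinct PC
#' centroids, batch- and sample-associated centroid shifts, and log-normal
#' cluster-frequency variation across samples — so every stage of the
#' framework can be exercised against known ground truth without any real
#' dataset.
#'
#' Defaults sketch a modest human case-control cohort: 5 cell states in 20
#' PCs, 20 samples of 500 cells processed in 5 batches (4 samples per
#' batch), cluster centroids separated by 6 units against residual noise of
#' SD 1 (distinct but touching states), technical batch/sample shifts of SD
#' 0.3 per PC, and inter-sample frequency variation of SD 0.5 in log space
#' (the magnitude typical of human tissue cohorts).
#'
#' @param k Number of clusters (>= 2).
#' @param n_pc PC dimensionality.
#' @param n_samples,n_batches,cells_per_sample Cohort layout.
#' @param centroid_separation Scale of the pairwise centroid distances.
#' @param batch_sd,sample_sd Per-PC SDs of the batch and sample shifts
#'   (tau for each random effect).
#' @param residual_sd Per-PC residual SD (isotropic Sigma_C).
#' @param logfreq_mean Length-k log mean proportions; default: geometrically
#'   decaying frequencies normalized to 1.
#' @param logfreq_cov k x k log-space covariance; default `0.25 * I` (SD 0.5).
#' @param seed Optional integer seed.
#' @return An object of class `proto_spec`.
#' @export
prototype_spec <- function(k = 5, n_pc = 20, n_samples = 20, n_batches = 5,
                           cells_per_sample = 500, centroid_separation = 6,
                           batch_sd = 0.3, sample_sd = 0.3, residual_sd = 1,
                           logfreq_mean = NULL, logfreq_cov = NULL,
                           seed = NULL) {
  stopifnot(k >= 2, n_pc >= 2, n_samples >= 1, n_batches >= 1,
            cells_per_sample >= 1, batch_sd >= 0, sample_sd >= 0,
            residual_sd >= 0, centroid_separation >= 0)
  if (n_batches > n_samples) {
    abort("Infeasible spec: more batches than samples.")
  }
  if (is.null(logfreq_mean)) {
    p <- 0.7^(seq_len(k) - 1)
    logfreq_mean <- log(p / sum(p))
  }
  if (is.null(logfreq_cov)) logfreq_cov <- diag(0.25, k)
  logfreq_cov <- as.matrix(logfreq_cov)
  stopifnot(length(logfreq_mean) == k, all(dim(logfreq_cov) == c(k, k)))
  ev <- eigen(logfreq_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("logfreq_cov must be positive semidefinite.")
  structure(
    list(k = k, n_pc = n_pc, n_samples = n_samples, n_batches = n_batches,
         cells_per_sample = cells_per_sample,
         centroid_separation = centroid_separation, batch_sd = batch_sd,
         sample_sd = sample_sd, residual_sd = residual_sd,
         logfreq_mean = logfreq_mean, logfreq_cov = logfreq_cov, seed = seed),
    class = "proto_spec")
}

#' Generate a synthetic prototype dataset with known ground truth
#'
#' Places `k` cluster centroids along random orthogonal directions scaled by
#' `centroid_separation` (one knob controls cluster distinctness), assembles
#' the implied [est_params] object, and generates cells with the package's
#' own simulation machinery (log-normal frequency profiles, batch/sample
#' shifts, multivariate-normal PC coordinates). The generating parameters
#' are returned alongside the data for recovery testing.
#'
#' @param spec A [prototype_spec()].
#' @return List with `data` (a validated `proto_data`; `cluster` holds the
#'   true generative labels) and `truth` (the exact `est_params` used).
#' @export
generate_prototype <- function(spec) {
  stopifnot(inherits(spec, "proto_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  # random orthonormal directions (QR of a Gaussian matrix), scaled so any
  # two centroids are centroid_separation * sqrt(2) apart
  g <- matrix(rnorm(spec$n_pc * spec$k), spec$n_pc, spec$k)
  if (spec$k <= spec$n_pc) {
    dirs <- qr.Q(qr(g))[, seq_len(spec$k), drop = FALSE]
  } else {
    dirs <- sweep(g, 2, sqrt(colSums(g^2)), "/")  # unit vectors; k > nPC
  }
  centroids <- t(dirs) * spec$centroid_separation
  clusters <- paste0("state", seq_len(spec$k))
  rownames(centroids) <- clusters

  truth <- est_params(
    clusters = clusters,
    centroids = centroids,
    batch_var = matrix(spec$batch_sd^2, spec$k, spec$n_pc),
    sample_var = matrix(spec$sample_sd^2, spec$k, spec$n_pc),
    residual_cov = rep(list(diag(spec$residual_sd^2, spec$n_pc)), spec$k),
    mean_logfreq = stats::setNames(spec$logfreq_mean, clusters),
    logfreq_cov = spec$logfreq_cov)

  design <- study_design(
    n_case = spec$n_samples, n_control = 0,
    cells_per_sample = spec$cells_per_sample, n_batches = spec$n_batches,
    b_scale = 1, s_scale = 1, cf_scale = 1, fold_change = 1,
    target_cluster = truth$clusters[[1]], seed = NULL)
  sim <- simulate_dataset(truth, design)

  meta <- tibble(cell = sim$meta$cell,
                 sample = sub("^case", "s", sim$meta$sample),
                 batch = sim$meta$batch,
                 cluster = sim$meta$origin_cluster)
  data <- prototype_dataset(sim$embeddings, meta)
  list(data = data, truth = truth)
}

#' Preset synthetic prototype specifications
#'
#' Three presets encoding qualitative contrasts between typical experimental
#' settings: `"ra_like"` and `"uc_like"` emulate tissue cohorts with fewer
#' samples, widely spread centroids, and high inter-sample frequency
#' variation; `"tb_like"` emulates a large blood cohort with many samples
#' and low frequency variation. Numeric values are illustrative defaults,
#' not calibrated to any real dataset.
#'
#' @param name One of `"ra_like"`, `"tb_like"`, `"uc_like"`.
#' @param seed Optional seed stored in the spec.
#' @return A [prototype_spec()].
#' @export
preset_prototype <- function(name = c("ra_like", "tb_like", "uc_like"),
                             seed = NULL) {
  name <- match.arg(name)
  switch(
    name,
    ra_like = prototype_spec(
      k = 6, n_pc = 20, n_samples = 20, n_batches = 5, cells_per_sample = 500,
      centroid_separation = 7, batch_sd = 0.4, sample_sd = 0.4,
      residual_sd = 1, logfreq_cov = diag(0.5, 6), seed = seed),
    tb_like = prototype_spec(
      k = 6, n_pc = 20, n_samples = 48, n_batches = 12, cells_per_sample = 500,
      centroid_separation = 5, batch_sd = 0.3, sample_sd = 0.2,
      residual_sd = 1, logfreq_cov = diag(0.1, 6), seed = seed),
    uc_like = prototype_spec(
      k = 8, n_pc = 20, n_samples = 30, n_batches = 8, cells_per_sample = 500,
      centroid_separation = 7, batch_sd = 0.35, sample_sd = 0.35,
      residual_sd = 1, logfreq_cov = diag(0.4, 8), seed = seed))
}
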