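#' Construct an estimated-parameter set
#'
#' Container for the quantities estimated from a prototype (or set directly
#' for fully synthetic studies): per-cluster PC centroids and variance
#' components, plus the global cluster-frequency model.
#'
#' Cluster order is fixed by `clusters` (sorted labels by convention) and
#' defines vector/matrix positions in `mean_logfreq` and `logfreq_cov`.
#'
#' @param clusters Character vector of k cluster labels (defines ordering).
#' @param centroids k x nPC matrix of cluster centroids (mu).
#' @param batch_var k x nPC matrix; row c is the diagonal of Sigma_B for
#'   cluster c (per-PC batch variance tau^2).
#' @param sample_var k x nPC matrix; diagonal of Sigma_S per cluster.
#' @param residual_cov List of k nPC x nPC residual covariance matrices
#'   (Sigma_C), named by cluster.
#' @param mean_logfreq Length-k vector: natural log of the mean
#'   cluster-frequency proportions across samples (mu_cf).
#' @param logfreq_cov k x k covariance of per-sample log proportions
#'   (Sigma_cf).
#' @return An object of class `est_params`.
#' @export
est_params <- function(clusters, centroids, batch_var, sample_var,
                       residual_cov, mean_logfreq, logfreq_cov) {
  k <- length(clusters)
  clusters <- as.character(clusters)
  centroids <- as.matrix(centroids)
  batch_var <- as.matrix(batch_var)
  sample_var <- as.matrix(sample_var)
  stopifnot(nrow(centroids) == k, nrow(batch_var) == k, nrow(sample_var) == k,
            length(residual_cov) == k, length(mean_logfreq) == k,
            all(dim(logfreq_cov) == c(k, k)))
  if (any(batch_var < 0) || any(sample_var < 0)) {
    abort("Batch/sample variance diagonals must be non-negative.")
  }
  residual_cov <- lapply(residual_cov, as.matrix)
  for (s in residual_cov) {
    if (max(abs(s - t(s))) > 1e-8) abort("residual_cov matrices must be symmetric.")
  }
  if (max(abs(logfreq_cov - t(logfreq_cov))) > 1e-8) {
    abort("logfreq_cov must be symmetric.")
  }
  rownames(centroids) <- rownames(batch_var) <- rownames(sample_var) <- clusters
  names(residual_cov) <- clusters
  names(mean_logfreq) <- clusters
  dimnames(logfreq_cov) <- list(clusters, clusters)
  structure(
    list(clusters = clusters, centroids = centroids, batch_var = batch_var,
         sample_var = sample_var, residual_cov = residual_cov,
         mean_logfreq = as.numeric(mean_logfreq) |> stats::setNames(clusters),
         logfreq_cov = as.matrix(logfreq_cov)),
    class = "est_params")
}

#' @exportS3Method base::print
print.est_params <- function(x, ...) {
  cat("<est_params> ", length(x$clusters), " clusters x ",
      ncol(x$centroids), " PCs\n", sep = "")
  cat("  mean frequencies: ",
      paste(sprintf("%s=%.3f", x$clusters, exp(x$mean_logfreq)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy per-cluster parameter estimates
#'
#' @param x An `est_params` object.
#' @param ... Unused.
#' @return A tibble with one row per (cluster, PC): centroid coordinate,
#'   batch and sample variance (tau^2), and residual variance.
#' @export
tidy.est_params <- function(x, ...) {
  npc <- ncol(x$centroids)
  tidyr::expand_grid(cluster = x$clusters, pc = seq_len(npc)) |>
    dplyr::mutate(
      centroid = purrr::map2_dbl(.data$cluster, .data$pc, ~ x$centroids[.x, .y]),
      batch_var = purrr::map2_dbl(.data$cluster, .data$pc, ~ x$batch_var[.x, .y]),
      sample_var = purrr::map2_dbl(.data$cluster, .data$pc, ~ x$sample_var[.x, .y]),
      residual_var = purrr::map2_dbl(.data$cluster, .data$pc,
                                     ~ x$residual_cov[[.x]][.y, .y]))
}

#' Serialize estimated parameters to JSON
#'
#' Cluster-label ordering is written explicitly so deserialization is
#' deterministic.
#'
#' @param params An `est_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "est_params"))
  obj <- list(
    clusters = params$clusters,
    centroids = unname(params$centroids),
    batch_var = unname(params$batch_var),
    sample_var = unname(params$sample_var),
    residual_cov = lapply(unname(params$residual_cov), unname),
    mean_logfreq = unname(params$mean_logfreq),
    logfreq_cov = unname(params$logfreq_cov))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read estimated parameters from JSON written by [write_params()]
#'
#' @param path File path.
#' @return An `est_params` object.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  est_params(
    clusters = obj$clusters,
    centroids = obj$centroids,
    batch_var = obj$batch_var,
    sample_var = obj$sample_var,
    residual_cov = if (is.array(obj$residual_cov)) {
      lapply(seq_along(obj$clusters), function(i) obj$residual_cov[i, , ])
    } else obj$residual_cov,
    mean_logfreq = obj$mean_logfreq,
    logfreq_cov = obj$logfreq_cov)
}
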