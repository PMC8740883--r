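#' Draw per-sample cluster-frequency profiles
#'
#' Samples each profile in log space from a multivariate normal with mean
#' `mean_logfreq` and covariance `logfreq_cov * cf_scale` (negative
#' frequencies are impossible), exponentiates, and normalizes to sum 1.
#' With `cf_scale = 0` every sample receives the identical profile, the
#' normalized exponential of `mean_logfreq`, with no randomness consumed.
#'
#' @param mean_logfreq Length-k vector (log mean proportions, mu_cf).
#' @param logfreq_cov k x k covariance in log space (Sigma_cf).
#' @param cf_scale Non-negative multiplier on the whole covariance matrix.
#' @param sample_ids Character vector naming the samples to draw for.
#' @return Matrix (samples x clusters) of proportions; rows sum to 1.
#' @export
sample_cf_profiles <- function(mean_logfreq, logfreq_cov, cf_scale, sample_ids) {
  k <- length(mean_logfreq)
  logfreq_cov <- as.matrix(logfreq_cov)
  stopifnot(all(dim(logfreq_cov) == c(k, k)), cf_scale >= 0)
  n <- length(sample_ids)
  cl <- names(mean_logfreq) %||% colnames(logfreq_cov) %||% paste0("c", seq_len(k))
  if (cf_scale == 0) {
    p <- exp(mean_logfreq)
    p <- p / sum(p)
    out <- matrix(rep(p, each = n), nrow = n, dimnames = list(sample_ids, cl))
    return(out)
  }
  sigma <- logfreq_cov * cf_scale
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("Scaled log-frequency covariance is not positive semidefinite.")
  }
  g <- rmvn(n, mean_logfreq, sigma)
  f <- exp(g)
  out <- f / rowSums(f)
  dimnames(out) <- list(sample_ids, cl)
  out
}

#' Induce a fold-change expansion of one cluster in a frequency profile
#'
#' Scales the target cluster's frequency by `fc` (capped at 1), then rescales
#' the remaining clusters proportionally so the profile sums to 1 again: the
#' others are divided by their sum and multiplied by the leftover probability
#' mass. If the cap fires with no mass left, the other clusters get exactly 0.
#'
#' @param profile Numeric vector of proportions summing to 1 (named, or a
#'   matrix of profiles with one row per sample).
#' @param target Cluster label (or index) to expand.
#' @param fc Fold change >= 0; 1 leaves the profile unchanged.
#' @return Profile(s) of the same shape, summing to 1.
#' @export
induce_fold_change <- function(profile, target, fc) {
  if (fc < 0) abort("`fc` must be >= 0.")
  if (is.matrix(profile)) {
    out <- t(apply(profile, 1, induce_fold_change, target = target, fc = fc))
    dimnames(out) <- dimnames(profile)
    return(out)
  }
  idx <- if (is.character(target)) match(target, names(profile)) else as.integer(target)
  if (is.na(idx) || idx < 1 || idx > length(profile)) {
    abort(paste0("Unknown target cluster: ", target))
  }
  new_f <- min(fc * profile[idx], 1)
  rest <- profile[-idx]
  remaining <- 1 - new_f
  rest <- if (sum(rest) > 0 && remaining > 0) rest / sum(rest) * remaining else rest * 0
  out <- profile
  out[idx] <- new_f
  out[-idx] <- rest
  out
}

#' Allocate an integer cell count per cluster from a frequency profile
#'
#' Deterministic largest-remainder rounding of `profile * n_cells`: each
#' cluster gets the floor, and leftover cells go to the largest fractional
#' remainders, ties broken by cluster position. Counts always sum exactly to
#' `n_cells`, so at `cf_scale = 0` the induced fold change is realized
#' exactly up to integer resolution.
#'
#' @param profile Numeric vector of proportions summing to 1.
#' @param n_cells Total number of cells to allocate.
#' @return Integer vector of counts, same names as `profile`, summing to
#'   `n_cells`.
#' @export
allocate_cells <- function(profile, n_cells) {
  stopifnot(n_cells >= 0, all(profile >= 0))
  stopifnot(abs(sum(profile) - 1) < 1e-6)
  raw <- profile * n_cells
  base <- floor(raw + 1e-9)
  left <- n_cells - sum(base)
  if (left > 0) {
    frac <- raw - base
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(profile)
  out
}

#' Draw a batch- or sample-level linear shift for one cluster
#'
#' Shifts are mean-zero multivariate normal with diagonal covariance
#' `var_diag * scale`; they displace the cluster centroid for all cells of
#' one (cluster, batch) or (cluster, sample) combination. `scale = 0`
#' returns an exact zero vector without consuming randomness.
#'
#' @param var_diag Non-negative vector: per-PC variance (diagonal of Sigma_B
#'   or Sigma_S for the cluster).
#' @param scale Non-negative multiplier (b_scale or s_scale).
#' @return Numeric vector, length `length(var_diag)`.
#' @export
sample_shift <- function(var_diag, scale) {
  stopifnot(all(var_diag >= 0), scale >= 0)
  if (scale == 0) return(numeric(length(var_diag)))
  rnorm(length(var_diag), 0, sqrt(var_diag * scale))
}

#' Sample PC coordinates for cells of one cluster in one (batch, sample)
#'
#' Cells are i.i.d. multivariate normal around the adjusted centroid
#' `mu + b_m + s_d` (cluster centroid plus its batch and sample shifts) with
#' the cluster's residual covariance Sigma_C.
#'
#' @param centroid Length-nPC centroid mu.
#' @param shift_batch,shift_sample Length-nPC linear shifts (b_m, s_d).
#' @param residual_cov nPC x nPC covariance Sigma_C.
#' @param n_cells Number of rows to draw.
#' @return Matrix n_cells x nPC.
#' @export
sample_pc_coords <- function(centroid, shift_batch, shift_sample,
                             residual_cov, n_cells) {
  mu <- centroid + shift_batch + shift_sample
  rmvn(n_cells, mu, as.matrix(residual_cov))
}

# MVN draws via (pivoted) Cholesky; exact zero columns for zero variance.
rmvn <- function(n, mu, sigma, chol_sigma = NULL) {
  d <- length(mu)
  if (n == 0) return(matrix(numeric(), 0, d))
  r <- chol_sigma %||% chol_psd(sigma)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% r, 2, mu, "+")
}

chol_psd <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (all(sigma == 0)) return(matrix(0, nrow(sigma), ncol(sigma)))
  tryCatch(chol(sigma), error = function(e) {
    ev <- eigen(sigma, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    # upper-triangular factor not needed; any square root works
    t(ev$vectors %*% (t(ev$vectors) * sqrt(ev$values)))
  })
}

#' Simulate a multi-sample case-control single-cell dataset in PC space
#'
#' Runs the generative model end to end for one study: draws a
#' cluster-frequency profile per sample (log-normal around the estimated
#' mean), induces the design's fold change into the target cluster of case
#' samples, converts profiles to integer cell counts, draws cluster-specific
#' batch and sample shifts, and samples every cell's PC coordinates around
#' its cluster's adjusted centroid.
#'
#' The draw order is fixed (profiles, target, shifts by sorted cluster then
#' batch/sample, then coordinates by sample and cluster), so a given
#' `design$seed` fully determines the output.
#'
#' @param params An [est_params] object.
#' @param design A [study_design()].
#' @return A `sim_data` object: `embeddings` (cells x nPC), `meta` tibble
#'   (`cell`, `sample`, `batch`, `condition`, `origin_cluster`),
#'   `target_cluster`, and the design used.
#' @export
simulate_dataset <- function(params, design) {
  stopifnot(inherits(params, "est_params"), inherits(design, "study_design"))
  if (!is.null(design$seed)) set.seed(design$seed)

  case_ids <- sprintf("case%02d", seq_len(design$n_case))
  ctrl_ids <- if (design$n_control > 0) {
    sprintf("ctrl%02d", seq_len(design$n_control))
  } else character()

  if (!is.null(design$batch_map)) {
    bm <- design$batch_map
    samples <- bm$sample
    condition <- if ("condition" %in% names(bm)) bm$condition else
      rep(c("case", "control"), c(design$n_case, design$n_control))
    batch_of <- stats::setNames(bm$batch, bm$sample)
  } else {
    bm <- distribute_samples(case_ids, ctrl_ids, design$n_batches)
    samples <- bm$sample
    condition <- bm$condition
    batch_of <- stats::setNames(bm$batch, bm$sample)
  }
  cond_of <- stats::setNames(condition, samples)

  cells_per <- design$cells_per_sample
  if (length(cells_per) == 1) {
    cells_per <- stats::setNames(rep(cells_per, length(samples)), samples)
  }
  stopifnot(all(samples %in% names(cells_per)))

  clusters <- params$clusters
  k <- length(clusters)

  # 1. frequency profiles
  profiles <- sample_cf_profiles(params$mean_logfreq, params$logfreq_cov,
                                 design$cf_scale, samples)

  # 2. target cluster and induced expansion in case samples
  target <- design$target_cluster
  if (identical(target, "random")) target <- sample(clusters, 1)
  if (!target %in% clusters) abort(paste0("Unknown target cluster: ", target))
  case_rows <- which(cond_of[samples] == "case")
  if (length(case_rows) && design$fold_change != 1) {
    profiles[case_rows, ] <- induce_fold_change(
      profiles[case_rows, , drop = FALSE], target, design$fold_change)
  }

  # 3. integer cell counts
  counts <- t(vapply(samples, function(s)
    allocate_cells(profiles[s, ], cells_per[[s]]), integer(k)))
  dimnames(counts) <- list(samples, clusters)

  # 4. cluster-specific batch and sample shifts
  batches <- unique(unname(batch_of[samples]))
  bshift <- sshift <- list()
  for (cl in clusters) {
    bshift[[cl]] <- t(vapply(batches, function(b)
      sample_shift(params$batch_var[cl, ], design$b_scale),
      numeric(ncol(params$centroids))))
    rownames(bshift[[cl]]) <- batches
    sshift[[cl]] <- t(vapply(samples, function(s)
      sample_shift(params$sample_var[cl, ], design$s_scale),
      numeric(ncol(params$centroids))))
    rownames(sshift[[cl]]) <- samples
  }

  # 5. PC coordinates
  chols <- lapply(params$residual_cov, chol_psd)
  npc <- ncol(params$centroids)
  total <- sum(counts)
  emb <- matrix(NA_real_, total, npc)
  meta_sample <- meta_cluster <- character(total)
  pos <- 0L
  for (s in samples) {
    b <- batch_of[[s]]
    for (cl in clusters) {
      n <- counts[s, cl]
      if (n == 0) next
      emb[pos + seq_len(n), ] <- rmvn(
        n, params$centroids[cl, ] + bshift[[cl]][b, ] + sshift[[cl]][s, ],
        sigma = NULL, chol_sigma = chols[[cl]])
      meta_sample[pos + seq_len(n)] <- s
      meta_cluster[pos + seq_len(n)] <- cl
      pos <- pos + n
    }
  }
  cell_ids <- sprintf("cell%06d", seq_len(total))
  rownames(emb) <- cell_ids
  colnames(emb) <- paste0("PC", seq_len(npc))
  meta <- tibble(
    cell = cell_ids,
    sample = meta_sample,
    batch = unname(batch_of[meta_sample]),
    condition = unname(cond_of[meta_sample]),
    origin_cluster = meta_cluster)

  out <- new_sim_data(emb, meta, target_cluster = target, design = design)
  attr(out, "profiles") <- profiles
  out
}
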