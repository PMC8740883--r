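#' Specify a case-control study design for simulation
#'
#' Collects the knobs of a simulated multi-sample study: how many case and
#' control samples, how many cells each contributes, how samples are laid out
#' across processing batches, the scaling factors applied to the estimated
#' batch / sample / cluster-frequency variances, and the fold change induced
#' in the target cluster of case samples.
#'
#' @param n_case,n_control Numbers of case and control samples.
#' @param cells_per_sample Cells simulated per sample (single count, or a
#'   named vector over samples).
#' @param n_batches Number of batches; samples are distributed with
#'   [distribute_samples()] (4 samples per batch when left `NULL`). Ignored
#'   when `batch_map` is given.
#' @param batch_map Optional tibble (`sample`, `batch`) fixing the layout
#'   explicitly (e.g. from [distribute_sample_per_batch()]).
#' @param b_scale,s_scale,cf_scale Non-negative multipliers on the estimated
#'   batch variance, sample variance, and cluster-frequency covariance.
#'   1 reproduces the prototype's noise levels; 0 removes that source.
#' @param fold_change Multiplicative expansion (>= 0) of the target cluster's
#'   frequency in case samples; 1 induces no effect.
#' @param target_cluster Cluster label to expand, or `"random"` to draw one
#'   uniformly per simulation.
#' @param resolution Louvain resolution used when re-clustering simulated
#'   data (default 1.2).
#' @param seed Optional integer seed making [simulate_dataset()] reproducible.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_case, n_control, cells_per_sample,
                         n_batches = NULL, batch_map = NULL,
                         b_scale = 1, s_scale = 1, cf_scale = 1,
                         fold_change = 1, target_cluster = "random",
                         resolution = 1.2, seed = NULL) {
  stopifnot(n_case >= 1, n_control >= 0, all(cells_per_sample >= 1))
  if (fold_change < 0) abort("`fold_change` must be >= 0.")
  if (any(c(b_scale, s_scale, cf_scale) < 0)) abort("Scale factors must be >= 0.")
  n_samples <- n_case + n_control
  if (is.null(n_batches) && is.null(batch_map)) {
    n_batches <- max(1L, floor(n_samples / 4))
  }
  if (!is.null(batch_map)) {
    batch_map <- as_tibble(batch_map)
    stopifnot(all(c("sample", "batch") %in% names(batch_map)))
    if (anyDuplicated(batch_map$sample)) {
      abort("`batch_map` assigns a sample to more than one batch.")
    }
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         cells_per_sample = cells_per_sample, n_batches = n_batches,
         batch_map = batch_map, b_scale = b_scale, s_scale = s_scale,
         cf_scale = cf_scale, fold_change = fold_change,
         target_cluster = target_cluster, resolution = resolution,
         seed = seed),
    class = "study_design")
}

#' @exportS3Method base::print
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d case + %d control samples; fc = %g on '%s'; scales b=%g s=%g cf=%g\n",
    x$n_case, x$n_control, x$fold_change, x$target_cluster,
    x$b_scale, x$s_scale, x$cf_scale))
  invisible(x)
}

#' Distribute case and control samples evenly across batches
#'
#' Round-robin assignment that balances cases and controls within each batch
#' (cases dealt out first, then controls, both in round-robin order), so a
#' batch never carries a condition imbalance larger than unavoidable.
#'
#' @param case_ids,control_ids Character vectors of sample IDs.
#' @param n_batches Number of batches (must not exceed the sample count).
#' @return Tibble with columns `sample`, `batch`, `condition`.
#' @export
distribute_samples <- function(case_ids, control_ids, n_batches) {
  all_ids <- c(case_ids, control_ids)
  if (n_batches > length(all_ids)) {
    abort(sprintf("Cannot fill %d batches with only %d samples.",
                  n_batches, length(all_ids)))
  }
  if (anyDuplicated(all_ids)) abort("Duplicated sample IDs.")
  batches <- paste0("batch", seq_len(n_batches))
  assign_rr <- function(ids, offset = 0L) {
    if (!length(ids)) return(character())
    batches[((seq_along(ids) - 1L + offset) %% n_batches) + 1L]
  }
  tibble(
    sample = all_ids,
    batch = c(assign_rr(case_ids), assign_rr(control_ids, offset = length(case_ids))),
    condition = rep(c("case", "control"), c(length(case_ids), length(control_ids))))
}

#' Assign each sample its own batch
#'
#' The "sequential" design: every batch contains cells from exactly one
#' sample, e.g. samples processed one run at a time.
#'
#' @param sample_ids Character vector of sample IDs.
#' @return Tibble (`sample`, `batch`), a bijection.
#' @export
distribute_sample_per_batch <- function(sample_ids) {
  if (anyDuplicated(sample_ids)) abort("Duplicated sample IDs.")
  tibble(sample = sample_ids,
         batch = paste0("batch", seq_along(sample_ids)))
}

#' Split samples into subsamples and multiplex them across batches
#'
#' The "multiplexed" design: each sample is split into `n_subsamples` equal
#' units, and units are distributed so that every batch mixes units from
#' different samples and no two units of the same sample share a batch.
#' Subsample units retain their parent sample identity for downstream
#' differential-abundance testing.
#'
#' @param sample_ids Character vector of sample IDs.
#' @param n_subsamples Units each sample is split into.
#' @param n_batches Number of batches.
#' @return Tibble with columns `unit`, `sample`, `batch`.
#' @export
distribute_split_sample <- function(sample_ids, n_subsamples, n_batches) {
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) abort("Duplicated sample IDs.")
  if (n_subsamples < 1) abort("`n_subsamples` must be >= 1.")
  if (n_batches > n * n_subsamples) {
    abort("More batches than subsample units.")
  }
  if (n_subsamples > n_batches) {
    abort("Cannot keep a sample's units in distinct batches: n_subsamples > n_batches.")
  }
  units <- tidyr::expand_grid(sample = sample_ids, sub = seq_len(n_subsamples)) |>
    dplyr::mutate(unit = paste0(.data$sample, "_u", .data$sub))
  # unit j of sample i -> batch (i + (j-1)*ceil(n_batches/n_subsamples)) mod n_batches:
  # a fixed stride > 0 guarantees distinct batches for one sample's units while
  # cycling all batches evenly.
  stride <- max(1L, floor(n_batches / n_subsamples))
  i <- match(units$sample, sample_ids) - 1L
  j <- units$sub - 1L
  units$batch <- paste0("batch", ((i + j * stride) %% n_batches) + 1L)
  dplyr::select(units, "unit", "sample", "batch")
}
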