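# Shared fixtures, built in code. Everything is seeded and cheap.

# small synthetic prototype: 3 well-separated states, 8 samples in 4 batches
toy_prototype <- function(seed = 11, k = 3, n_pc = 4, n_samples = 8,
                          n_batches = 4, cells_per_sample = 60, ...) {
  generate_prototype(prototype_spec(
    k = k, n_pc = n_pc, n_samples = n_samples, n_batches = n_batches,
    cells_per_sample = cells_per_sample, centroid_separation = 8,
    batch_sd = 0.2, sample_sd = 0.2, residual_sd = 0.5, seed = seed, ...))
}

# hand-rolled parameters for a tiny simulation-side fixture
toy_params <- function(k = 3, n_pc = 4, sep = 8, batch_var = 0.04,
                       sample_var = 0.04, resid_var = 0.25,
                       logfreq_var = 0.09) {
  centroids <- matrix(0, k, n_pc)
  for (i in seq_len(k)) centroids[i, i] <- sep
  est_params(
    clusters = paste0("c", seq_len(k)),
    centroids = centroids,
    batch_var = matrix(batch_var, k, n_pc),
    sample_var = matrix(sample_var, k, n_pc),
    residual_cov = rep(list(diag(resid_var, n_pc)), k),
    mean_logfreq = rep(log(1 / k), k),
    logfreq_cov = diag(logfreq_var, k))
}

# per-cell metadata with binomially sampled membership in cluster "A";
# logit-linear condition effect beta on case samples
masc_fixture <- function(n_case, n_control, cells_per_sample, p_base,
                         beta = 0, n_batches = 4, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("case%02d", seq_len(n_case)),
               sprintf("ctrl%02d", seq_len(n_control)))
  condition <- rep(c("case", "control"), c(n_case, n_control))
  batch <- paste0("b", ((seq_along(samples) - 1L) %% n_batches) + 1L)
  purrr::map_dfr(seq_along(samples), function(i) {
    eta <- stats::qlogis(p_base) + beta * (condition[i] == "case")
    in_a <- stats::rbinom(cells_per_sample, 1, stats::plogis(eta))
    tibble::tibble(
      cell = sprintf("%s_cell%03d", samples[i], seq_len(cells_per_sample)),
      sample = samples[i], batch = batch[i], condition = condition[i],
      new_cluster = ifelse(in_a == 1, "A", "B"))
  })
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / abs(truth)), tol)
}
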