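test_that("cf_scale = 0 collapses every sample onto the normalized mean profile", {
  mu <- log(c(a = 0.5, b = 0.3, c = 0.2))
  prof <- sample_cf_profiles(mu, diag(0.3, 3), 0, paste0("s", 1:4))
  expect_equal(dim(prof), c(4, 3))
  for (i in 1:4) expect_equal(unname(prof[i, ]), c(0.5, 0.3, 0.2))
})

test_that("log-space frequency draws carry the scaled covariance", {
  set.seed(41)
  sig <- matrix(c(0.20, 0.05, 0.05, 0.10), 2, 2)
  cf_scale <- 0.5
  prof <- sample_cf_profiles(log(c(0.6, 0.4)), sig, cf_scale,
                             paste0("s", 1:10000))
  expect_equal(unname(rowSums(prof)), rep(1, 10000))
  # normalization subtracts a common term from each log proportion, so
  # log-ratios recover the generating covariance exactly:
  # var(log p1 - log p2) = S11 + S22 - 2 S12 (scaled)
  lr <- log(prof[, 1]) - log(prof[, 2])
  truth <- (sig[1, 1] + sig[2, 2] - 2 * sig[1, 2]) * cf_scale
  expect_rel_error(var(lr), truth, 0.10)
})

test_that("non-PSD log-frequency covariance is rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_cf_profiles(c(0, 0), bad, 1, "s1"),
               "positive semidefinite")
})

test_that("fold-change induction follows the cap-and-renormalize rule", {
  p <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(induce_fold_change(p, "a", 1), p)
  expect_equal(unname(induce_fold_change(p, "a", 2)), c(0.4, 0.225, 0.375))
  # cap: 0.3 * 5 > 1 -> target gets everything
  p2 <- c(a = 0.3, b = 0.3, c = 0.4)
  out <- induce_fold_change(p2, "a", 5)
  expect_equal(unname(out), c(1, 0, 0))
  expect_error(induce_fold_change(p, "zz", 2), "Unknown target")

  # brute-force renormalization oracle on random profiles
  set.seed(42)
  for (i in 1:25) {
    q <- stats::runif(4)
    q <- q / sum(q)
    names(q) <- letters[1:4]
    fc <- stats::runif(1, 0, 3)
    got <- induce_fold_change(q, "b", fc)
    tgt <- min(fc * q[["b"]], 1)
    rest <- q[c("a", "c", "d")] / sum(q[c("a", "c", "d")]) * (1 - tgt)
    expect_equal(got[["b"]], tgt)
    expect_equal(got[c("a", "c", "d")], rest)
    expect_equal(sum(got), 1)
  }
})

test_that("cell allocation is deterministic largest-remainder rounding", {
  expect_equal(unname(allocate_cells(c(0.5, 0.5), 100)), c(50, 50))
  # remainders tie: extra cell goes to the earliest cluster
  expect_equal(unname(allocate_cells(rep(1 / 3, 3), 100)), c(34, 33, 33))
  # brute-force largest-remainder oracle + conservation on random profiles
  set.seed(43)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    p <- stats::runif(k); p <- p / sum(p)
    n <- sample(10:500, 1)
    got <- allocate_cells(p, n)
    expect_equal(sum(got), n)
    base <- floor(p * n + 1e-9)
    extra <- order(-(p * n - base), seq_len(k))[seq_len(n - sum(base))]
    want <- base; want[extra] <- want[extra] + 1
    expect_equal(got, as.integer(want))
  }
})

test_that("technical shifts have the requested scaled variance", {
  expect_identical(sample_shift(c(1, 2, 3), 0), c(0, 0, 0))
  set.seed(44)
  draws <- t(replicate(20000, sample_shift(c(0.5, 2), 0.5)))
  expect_rel_error(apply(draws, 2, var), c(0.25, 1), 0.10)
  expect_lt(abs(cor(draws[, 1], draws[, 2])), 0.03)
})

test_that("PC coordinates are drawn around the adjusted centroid", {
  mu <- c(1, -2, 3)
  zero <- sample_pc_coords(mu, c(0.5, 0, 0), c(0, 0.5, 0), diag(0, 3), 5)
  expect_equal(zero, matrix(rep(mu + c(0.5, 0.5, 0), each = 5), 5, 3))

  set.seed(45)
  sig <- diag(c(1, 2, 0.5)); sig[1, 2] <- sig[2, 1] <- 0.4
  x <- sample_pc_coords(mu, c(1, 0, 0), c(0, 1, 0), sig, 50000)
  se <- sqrt(diag(sig) / 50000)
  expect_true(all(abs(colMeans(x) - (mu + c(1, 1, 0))) < 3 * se))
  expect_lt(norm(cov(x) - sig, "F") / norm(sig, "F"), 0.10)
})

test_that("simulation conserves the design's cell counts and labels", {
  params <- toy_params()
  d <- study_design(2, 2, 100, n_batches = 2, seed = 9)
  sim <- simulate_dataset(params, d)
  expect_equal(nrow(sim$embeddings), 400)
  expect_equal(unname(table(sim$meta$sample)), rep(100L, 4), ignore_attr = TRUE)
  cond_by_sample <- dplyr::distinct(sim$meta, sample, condition)
  expect_equal(nrow(cond_by_sample), 4)  # condition constant within sample
})

test_that("with cf_scale = 0 the induced fold change is exact on profiles", {
  params <- toy_params()
  # target starts at 1/3, fc = 2 keeps it below the cap
  d <- study_design(3, 3, 200, n_batches = 3, cf_scale = 0, fold_change = 2,
                    target_cluster = "c2", seed = 10)
  sim <- simulate_dataset(params, d)
  prof <- attr(sim, "profiles")
  case_mean <- mean(prof[paste0("case0", 1:3), "c2"])
  ctrl_mean <- mean(prof[paste0("ctrl0", 1:3), "c2"])
  expect_equal(case_mean / ctrl_mean, 2)
  # after integer allocation the ratio holds to within 1/cells_per_sample
  counts <- table(sim$meta$condition, sim$meta$origin_cluster)
  obs <- (counts["case", "c2"] / 600) / (counts["control", "c2"] / 600)
  expect_equal(obs, 2, tolerance = 1 / 100)
})

test_that("simulation is deterministic under its seed", {
  params <- toy_params()
  d <- study_design(2, 2, 50, n_batches = 2, seed = 12)
  s1 <- simulate_dataset(params, d)
  s2 <- simulate_dataset(params, d)
  expect_identical(s1$embeddings, s2$embeddings)
  expect_identical(s1$meta, s2$meta)
  d2 <- study_design(2, 2, 50, n_batches = 2, seed = 13)
  expect_false(identical(simulate_dataset(params, d2)$embeddings,
                         s1$embeddings))
})

test_that("zero batch/sample scales leave coordinates exchangeable across batches", {
  params <- toy_params(batch_var = 0.5, sample_var = 0.5)
  d <- study_design(4, 4, 150, n_batches = 2, b_scale = 0, s_scale = 0,
                    seed = 14)
  sim <- simulate_dataset(params, d)
  m <- dplyr::filter(sim$meta, origin_cluster == "c1")
  x <- sim$embeddings[m$cell, 1]
  ks <- stats::ks.test(x[m$batch == "batch1"], x[m$batch == "batch2"])
  expect_gt(ks$p.value, 0.01)
})

test_that("estimation round-trips the generating parameters of a simulation", {
  # the primary estimation test surface: simulate from known parameters at a
  # size where Monte-Carlo noise on aggregate variance summaries is small,
  # then re-estimate
  gp <- generate_prototype(prototype_spec(
    k = 4, n_pc = 6, n_samples = 40, n_batches = 20, cells_per_sample = 250,
    centroid_separation = 6, batch_sd = 0.25, sample_sd = 0.25,
    residual_sd = 1, logfreq_mean = rep(log(0.25), 4),
    logfreq_cov = diag(0.09, 4), seed = 51))
  est <- estimate_params(gp$data, n_pc = 6)
  truth <- gp$truth
  # centroids: per-cluster RMSE small relative to the separation scale
  rmse <- sqrt(rowMeans((est$centroids - truth$centroids)^2))
  expect_lt(max(rmse), 0.12)
  # variance components: aggregate diagonals within 25%
  expect_rel_error(mean(est$batch_var), 0.0625, 0.25)
  expect_rel_error(mean(est$sample_var), 0.0625, 0.25)
  expect_rel_error(mean(sapply(est$residual_cov, function(m) mean(diag(m)))),
                   1, 0.25)
})
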