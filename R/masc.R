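#' Mixed-effects association testing of single cells (MASC)
#'
#' Tests every cluster for differential abundance between conditions with a
#' logistic mixed model on per-cell cluster membership. For cluster K the
#' full model is `in_K ~ condition + (1|batch) + (1|sample)` and the null
#' drops `condition`; both are fitted by maximum likelihood (Laplace
#' approximation) and compared with a likelihood-ratio test on 1 df.
#'
#' Because condition, batch, and sample are constant within a sample, the
#' per-cell Bernoulli likelihood factorizes exactly into per-sample binomial
#' counts; the models are fitted on those counts (identical likelihood-ratio
#' statistic, far fewer rows).
#'
#' @param data Data frame with one row per cell; columns named by the
#'   `cluster`, `condition`, `batch`, `sample` arguments.
#' @param cluster,condition,batch,sample Column names (strings) holding the
#'   cluster label tested, the binary condition, and the grouping factors.
#' @return Tibble with one row per cluster: `cluster`, `n_cells`,
#'   `lrt_statistic` (>= 0), `p_value` (chi-square 1 df upper tail),
#'   `converged`, `note`.
#' @export
masc_test <- function(data, cluster = "new_cluster", condition = "condition",
                      batch = "batch", sample = "sample") {
  data <- as_tibble(data)
  miss <- setdiff(c(cluster, condition, batch, sample), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))

  cl <- as.character(data[[cluster]])
  cond <- as.character(data[[condition]])
  if (dplyr::n_distinct(cond) > 2) abort("`condition` must be binary.")

  agg <- tibble(sample = as.character(data[[sample]]),
                batch = as.character(data[[batch]]),
                condition = cond, cl = cl) |>
    dplyr::count(.data$sample, .data$batch, .data$condition, .data$cl) |>
    tidyr::pivot_wider(names_from = "cl", values_from = "n", values_fill = 0L)
  clusters <- sort(setdiff(names(agg), c("sample", "batch", "condition")))
  totals <- rowSums(agg[clusters])

  purrr::map_dfr(clusters, function(K) {
    y <- agg[[K]]
    res <- masc_fit_one(y, totals, agg$condition, agg$batch, agg$sample)
    tibble(cluster = K, n_cells = sum(y), lrt_statistic = res$lrt,
           p_value = res$p, converged = res$converged, note = res$note)
  })
}

masc_fit_one <- function(y, n, condition, batch, sample) {
  if (dplyr::n_distinct(condition) < 2) {
    return(list(lrt = 0, p = 1, converged = TRUE, note = "condition constant"))
  }
  d <- data.frame(y = y, n = n, condition = factor(condition),
                  batch = factor(batch), sample = factor(sample))
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  fit_quiet <- function(form) {
    warned <- FALSE
    fit <- withCallingHandlers(
      suppressMessages(
        lme4::glmer(form, data = d, family = stats::binomial(), nAGQ = 1L,
                    control = ctrl)),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warned = warned)
  }
  out <- tryCatch({
    full <- fit_quiet(cbind(y, n - y) ~ condition + (1 | batch) + (1 | sample))
    null <- fit_quiet(cbind(y, n - y) ~ 1 + (1 | batch) + (1 | sample))
    lrt <- max(0, 2 * (as.numeric(logLik(full$fit)) - as.numeric(logLik(null$fit))))
    conv <- !(full$warned || null$warned)
    list(lrt = lrt, p = pchisq(lrt, df = 1, lower.tail = FALSE),
         converged = conv, note = if (conv) NA_character_ else "convergence warning")
  }, error = function(e) {
    list(lrt = NA_real_, p = NA_real_, converged = FALSE,
         note = paste0("fit failed: ", conditionMessage(e)))
  })
  out
}

#' Per-cluster fixed-effects differential-abundance test
#'
#' The simple alternative to MASC: for each cluster, an ordinary linear
#' regression predicting a sample's case-control status (0/1) from the
#' cluster's frequency in that sample; the reported p-value is that of the
#' frequency coefficient. Takes per-cell data and aggregates to per-sample
#' frequencies internally.
#'
#' @inheritParams masc_test
#' @return Tibble per cluster: `cluster`, `estimate` (slope), `p_value`,
#'   `note` (flags degenerate frequency vectors, for which p = 1).
#' @export
fixed_effects_test <- function(data, cluster = "new_cluster",
                               condition = "condition", sample = "sample") {
  data <- as_tibble(data)
  freqs <- tibble(sample = as.character(data[[sample]]),
                  condition = as.character(data[[condition]]),
                  cl = as.character(data[[cluster]])) |>
    dplyr::add_count(.data$sample, name = "n_total") |>
    dplyr::count(.data$sample, .data$condition, .data$n_total, .data$cl) |>
    dplyr::mutate(freq = .data$n / .data$n_total)
  conds <- sort(unique(freqs$condition))
  if (length(conds) > 2) abort("`condition` must be binary.")
  clusters <- sort(unique(freqs$cl))
  wide <- tidyr::pivot_wider(freqs, id_cols = c("sample", "condition"),
                             names_from = "cl", values_from = "freq",
                             values_fill = 0)
  status <- as.numeric(wide$condition == conds[[1]])
  purrr::map_dfr(clusters, function(K) {
    x <- wide[[K]]
    if (sd(x) == 0 || sd(status) == 0) {
      return(tibble(cluster = K, estimate = NA_real_, p_value = 1,
                    note = "degenerate predictor or response"))
    }
    # perfectly separating frequencies trip lm's perfect-fit warning; the
    # tiny p-value is the correct answer here
    fit <- suppressWarnings(summary(lm(status ~ x)))
    tibble(cluster = K, estimate = fit$coefficients["x", "Estimate"],
           p_value = fit$coefficients["x", "Pr(>|t|)"], note = NA_character_)
  })
}

#' Bonferroni detection rule
#'
#' A simulated study is a successful detection when at least one cluster's
#' p-value falls below the Bonferroni-corrected threshold `alpha / k`, with
#' `k` the number of clusters tested in that simulation.
#'
#' @param p_values Numeric vector of per-cluster p-values (NAs ignored).
#' @param k Number of tests; defaults to `length(p_values)`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Logical scalar.
#' @export
detect_da <- function(p_values, k = length(p_values), alpha = 0.05) {
  if (k < 1) abort("`k` must be >= 1.")
  p <- p_values[!is.na(p_values)]
  length(p) > 0 && min(p) < alpha / k
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Aggregate detection outcomes into a power estimate
#'
#' Power is the fraction of simulations with successful detection; the
#' attached 95% interval is the Wilson score interval for a binomial
#' proportion.
#'
#' @param detections Logical vector, one entry per simulation.
#' @param conf Confidence level for the interval.
#' @return One-row tibble: `n_sims`, `n_detected`, `power`, `ci_low`,
#'   `ci_high`.
#' @export
estimate_power <- function(detections, conf = 0.95) {
  if (!length(detections)) abort("No detection outcomes supplied.")
  n <- length(detections)
  x <- sum(detections)
  ci <- wilson_ci(x, n, conf)
  tibble(n_sims = n, n_detected = x, power = x / n,
         ci_low = ci[["low"]], ci_high = ci[["high"]])
}

#' Interpretability of a detection
#'
#' Quantifies whether a detected differential-abundance signal points back at
#' the cluster the effect was induced in: the Pearson correlation between the
#' per-cell indicator of originating from the causal cluster and the per-cell
#' indicator of membership in any significant (detected) cluster. If nothing
#' is significant the score is 0 by definition; if either indicator is
#' constant while detections exist, the correlation is undefined and the
#' score is 0 with a `flagged` attribute.
#'
#' @param origin_cluster Character vector: each cell's generative cluster.
#' @param causal_cluster The cluster the fold change was induced in.
#' @param new_cluster Character vector: each cell's post-hoc cluster label.
#' @param significant_clusters Labels of clusters passing the detection
#'   threshold (may be empty).
#' @return Numeric scalar in [-1, 1].
#' @export
interpretability_score <- function(origin_cluster, causal_cluster,
                                   new_cluster, significant_clusters) {
  if (length(significant_clusters) == 0) return(0)
  a <- as.numeric(origin_cluster == causal_cluster)
  b <- as.numeric(new_cluster %in% significant_clusters)
  if (sd(a) == 0 || sd(b) == 0) {
    out <- 0
    attr(out, "flagged") <- "constant indicator"
    return(out)
  }
  cor(a, b)
}
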