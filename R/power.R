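#' Run a Monte-Carlo power study
#'
#' Loops simulate -> re-cluster -> test -> detect for `n_sims` independent
#' studies under one design, and aggregates the detection rate (power) with
#' a 95% Wilson interval plus a per-simulation interpretability score.
#' Per-simulation seeds are `seed + i`, so the study is reproducible and any
#' subset of simulations can be re-run independently.
#'
#' @param params An [est_params] object.
#' @param design A [study_design()].
#' @param n_sims Number of simulations (>= 1).
#' @param test `"masc"` (logistic mixed model, default) or `"fixed"`
#'   (per-sample linear regression).
#' @param knn_k SNN neighborhood size for re-clustering (default 30).
#' @param alpha Family-wise significance level for the Bonferroni rule.
#' @param seed Base integer seed; defaults to `design$seed` or 1.
#' @param recluster Set `FALSE` to skip re-clustering and test the
#'   generative (origin) cluster labels instead. Mainly for calibration
#'   studies and tests.
#' @param progress Print one line per simulation.
#' @return A `power_report`: list with `summary` (one-row tibble from
#'   [estimate_power()] plus mean interpretability), `per_sim` (tibble:
#'   seed, target cluster, clusters found, min p, detected,
#'   interpretability), `p_values` (per simulation x cluster), `design`,
#'   `test`, `alpha`.
#' @export
run_power_study <- function(params, design, n_sims, test = c("masc", "fixed"),
                            knn_k = 30, alpha = 0.05, seed = NULL,
                            recluster = TRUE, progress = FALSE) {
  test <- match.arg(test)
  if (n_sims < 1) abort("`n_sims` must be >= 1.")
  base_seed <- seed %||% design$seed %||% 1L

  per_sim <- vector("list", n_sims)
  pvals <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim_seed <- base_seed + i
    design_i <- design
    design_i$seed <- sim_seed
    ds <- simulate_dataset(params, design_i)
    if (recluster) {
      ds <- cluster_cells(ds, k = knn_k, resolution = design$resolution)
    } else {
      ds$meta$new_cluster <- ds$meta$origin_cluster
    }
    label_col <- "new_cluster"
    res <- if (test == "masc") {
      masc_test(ds$meta, cluster = label_col)
    } else {
      dplyr::mutate(
        fixed_effects_test(ds$meta, cluster = label_col),
        lrt_statistic = NA_real_, converged = TRUE)
    }
    k_found <- nrow(res)
    detected <- detect_da(res$p_value, k = k_found, alpha = alpha)
    sig <- res$cluster[!is.na(res$p_value) & res$p_value < alpha / k_found]
    interp <- interpretability_score(ds$meta$origin_cluster, ds$target_cluster,
                                     ds$meta$new_cluster, sig)
    per_sim[[i]] <- tibble(
      sim = i, seed = sim_seed, target_cluster = ds$target_cluster,
      k_found = k_found, min_p = suppressWarnings(min(res$p_value, na.rm = TRUE)),
      detected = detected, interpretability = as.numeric(interp))
    pvals[[i]] <- dplyr::mutate(res[c("cluster", "p_value")], sim = i,
                                .before = 1)
    if (progress) {
      cat(sprintf("sim %d/%d: k=%d min_p=%.3g detected=%s\n",
                  i, n_sims, k_found, per_sim[[i]]$min_p, detected))
    }
  }
  per_sim <- dplyr::bind_rows(per_sim)
  summary <- estimate_power(per_sim$detected) |>
    dplyr::mutate(mean_interpretability = mean(per_sim$interpretability))
  structure(
    list(summary = summary, per_sim = per_sim,
         p_values = dplyr::bind_rows(pvals), design = design, test = test,
         alpha = alpha, base_seed = base_seed),
    class = "power_report")
}

#' @exportS3Method base::print
print.power_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<power_report> %s: power %.1f%% [%.1f%%, %.1f%%] from %d simulations (fc = %g)\n",
    x$test, 100 * s$power, 100 * s$ci_low, 100 * s$ci_high, s$n_sims,
    x$design$fold_change))
  invisible(x)
}

#' Tidy per-simulation outcomes of a power study
#'
#' @param x A `power_report`.
#' @param ... Unused.
#' @return The per-simulation tibble (seed, target, clusters found, min
#'   p-value, detection, interpretability).
#' @export
tidy.power_report <- function(x, ...) x$per_sim

#' One-row summary of a power study
#'
#' @param x A `power_report`.
#' @param ... Unused.
#' @return Tibble: power, Wilson CI, simulation count, mean
#'   interpretability, fold change and design scales.
#' @export
glance.power_report <- function(x, ...) {
  dplyr::mutate(x$summary,
                fold_change = x$design$fold_change,
                n_case = x$design$n_case, n_control = x$design$n_control,
                cells_per_sample = x$design$cells_per_sample[[1]],
                test = x$test)
}

#' Plot a power report
#'
#' Single-design report: bar of power with its Wilson interval.
#'
#' @param object A `power_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_report <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold_change), y = .data$power)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.15) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "Induced fold change", y = "Power",
                  title = sprintf("Detection power (%s test, %d simulations)",
                                  object$test, df$n_sims)) +
    ggplot2::theme_minimal()
}

#' Power curves across a design grid
#'
#' @param grid_summary Tibble as returned by [run_pipeline()]'s summary (one
#'   row per grid point with `fold_change`, `power`, `ci_low`, `ci_high`,
#'   and optionally `n_case`/`n_control`).
#' @return A ggplot object: power vs fold change, one line per sample-size
#'   combination.
#' @export
plot_power_curve <- function(grid_summary) {
  df <- dplyr::mutate(grid_summary,
                      samples = paste0(.data$n_case, "+", .data$n_control))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change, y = .data$power,
                                   color = .data$samples, group = .data$samples)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.02) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "Induced fold change", y = "Power",
                  color = "Samples (case+control)") +
    ggplot2::theme_minimal()
}
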