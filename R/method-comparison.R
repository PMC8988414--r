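# Paired comparison of flow estimates: Pearson product-moment correlation
# and Bland-Altman limits of agreement, plus the summary tables of a
# multi-patient study (per-state input flows, per-site three-method flows,
# per-model correlations).

METHOD_PAIRS <- list(
  c("Benchtop/Invasive",   "I_benchtop_cc_s",   "I_invasive_cc_s"),
  c("Electrical/Invasive", "I_windkessel_cc_s", "I_invasive_cc_s"),
  c("Benchtop/Electrical", "I_benchtop_cc_s",   "I_windkessel_cc_s")
)

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) value_error("inputs must be numeric vectors")
  if (length(x) != length(y)) value_error("paired vectors must have equal length")
  if (length(x) < 2L) value_error("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) value_error("paired vectors must not contain NA")
  invisible(NULL)
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors (equal length >= 2, both with non-zero
#'   variance).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  check_paired(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    value_error("correlation undefined: an input has zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; reports `mean(d)` and the 95% limits of
#' agreement `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard
#' deviation.
#'
#' @param x,y paired numeric vectors (equal length >= 2).
#' @return List of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `n`.
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         lower = m - 1.96 * s, upper = m + 1.96 * s, n = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d mean diff %.4f, limits [%.4f, %.4f]\n",
              x$n, x$mean_diff, x$lower, x$upper))
  invisible(x)
}

comparison_row <- function(label, x, y) {
  ba <- bland_altman(x, y)
  data.frame(
    pair = label, n = ba$n, pearson_r = pearson(x, y),
    ba_mean_diff_cc_s = ba$mean_diff,
    ba_lower_cc_s = ba$lower, ba_upper_cc_s = ba$upper,
    stringsAsFactors = FALSE
  )
}

#' Compare the three flow methods over a study report
#'
#' Computes, for each method pair (benchtop/invasive, electrical/invasive,
#' benchtop/electrical), the Pearson correlation and Bland-Altman summary of
#' the paired site-by-state flows. `grouping = "pooled"` uses all complete
#' rows at once; `grouping = "per_model"` computes one result per model (the
#' report then needs a `model` column) plus an `Average` row per pair.
#'
#' @param report a `site_flow_report` (or row-bound reports with a `model`
#'   column) containing the three flow columns.
#' @param grouping `"pooled"` or `"per_model"`.
#' @return Data frame, one row per pair (and per model when grouped).
#' @export
compare_methods <- function(report, grouping = c("pooled", "per_model")) {
  grouping <- match.arg(grouping)
  need <- c("I_invasive_cc_s", "I_benchtop_cc_s", "I_windkessel_cc_s")
  if (!all(need %in% names(report))) {
    value_error("report lacks the three method flow columns")
  }
  complete <- report[stats::complete.cases(report[need]), , drop = FALSE]
  if (nrow(complete) < 2L) value_error("need >= 2 complete paired observations")
  if (grouping == "pooled") {
    out <- do.call(rbind, lapply(METHOD_PAIRS, function(p) {
      comparison_row(p[1], complete[[p[2]]], complete[[p[3]]])
    }))
    return(out)
  }
  if (!"model" %in% names(report)) {
    value_error("per-model grouping needs a `model` column")
  }
  rows <- list()
  for (m in unique(complete$model)) {
    sub <- complete[complete$model == m, , drop = FALSE]
    for (p in METHOD_PAIRS) {
      r <- comparison_row(p[1], sub[[p[2]]], sub[[p[3]]])
      rows[[length(rows) + 1L]] <- cbind(model = m, r)
    }
  }
  out <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(METHOD_PAIRS, function(p) {
    sub <- out[out$pair == p[1], , drop = FALSE]
    data.frame(model = "Average", pair = p[1], n = sum(sub$n),
               pearson_r = mean(sub$pearson_r),
               ba_mean_diff_cc_s = mean(sub$ba_mean_diff_cc_s),
               ba_lower_cc_s = mean(sub$ba_lower_cc_s),
               ba_upper_cc_s = mean(sub$ba_upper_cc_s),
               stringsAsFactors = FALSE)
  }))
  rbind(out, avg)
}

#' Study summary tables
#'
#' Shapes a multi-model study into the three standard summaries:
#' `input_flows` (per model and state: coronary inflow, aortic outflow and
#' their sum, which equals the configured total input flow), `site_flows`
#' (per state and artery: the three method flows averaged across models) and
#' `correlations` (per model: Pearson r of the three method pairs over its
#' site-by-state flows, plus an `Average` row).
#'
#' @param report row-bound `site_flow_report`s with a `model` column; the
#'   per-model totals (attribute `"totals"` of each sweep) must be row-bound
#'   with a `model` column and attached as attribute `"totals"`, as done by
#'   [run_study()].
#' @return List with data frames `input_flows`, `site_flows`, `correlations`.
#' @export
flow_summary_tables <- function(report) {
  if (!is.data.frame(report) || nrow(report) == 0L) value_error("empty report")
  if (!"model" %in% names(report)) report$model <- "model_1"
  totals <- attr(report, "totals")
  if (is.null(totals)) value_error("report lacks the per-state totals attribute")

  input_flows <- totals[order(totals$model, match(totals$activity, ACTIVITY_LEVELS)), ]
  rownames(input_flows) <- NULL

  agg <- stats::aggregate(
    report[c("I_invasive_cc_s", "I_benchtop_cc_s", "I_windkessel_cc_s")],
    by = list(activity = report$activity, artery = report$artery),
    FUN = function(v) mean(v)
  )
  agg <- agg[order(match(agg$activity, ACTIVITY_LEVELS), agg$artery), ]
  rownames(agg) <- NULL

  correlations <- NULL
  if (all(stats::complete.cases(
    report[c("I_invasive_cc_s", "I_benchtop_cc_s", "I_windkessel_cc_s")]
  ))) {
    cm <- compare_methods(report, grouping = "per_model")
    correlations <- stats::reshape(
      cm[c("model", "pair", "pearson_r")],
      idvar = "model", timevar = "pair", direction = "wide"
    )
    names(correlations) <- sub("^pearson_r\\.", "", names(correlations))
    rownames(correlations) <- NULL
  }

  list(input_flows = input_flows, site_flows = agg, correlations = correlations)
}

#' Mean per-model pairwise Pearson correlation
#'
#' The mean of the per-model Pearson correlations over the three method
#' pairs: a single scalar summary of how strongly the three flow methods
#' agree across a study.
#'
#' @param report row-bound `site_flow_report`s with `model` column and all
#'   three flow columns complete.
#' @return Scalar in \[-1, 1\].
#' @export
mean_pairwise_pearson <- function(report) {
  cm <- compare_methods(report, grouping = "per_model")
  mean(cm$pearson_r[cm$model != "Average"])
}

#' Bland-Altman plot for two flow methods
#'
#' @param x,y paired flow vectors (cc/s); `x - y` is plotted against the
#'   pair means with the mean difference and 95% limits of agreement.
#' @param labels length-2 character vector naming the methods.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, labels = c("method 1", "method 2")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    state_error("ggplot2 is required for plotting")
  }
  ba <- bland_altman(x, y)
  df <- data.frame(mean = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (cc/s)", labels[1], labels[2]),
      y = sprintf("%s - %s (cc/s)", labels[1], labels[2]),
      title = "Bland-Altman agreement"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two flow methods with the identity line
#'
#' @param x,y paired flow vectors (cc/s).
#' @param labels length-2 character vector naming the methods.
#' @return A ggplot object.
#' @export
plot_method_scatter <- function(x, y, labels = c("method 1", "method 2")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    state_error("ggplot2 is required for plotting")
  }
  df <- data.frame(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("%s flow (cc/s)", labels[1]),
                  y = sprintf("%s flow (cc/s)", labels[2]),
                  subtitle = sprintf("Pearson r = %.3f", pearson(x, y))) +
    ggplot2::theme_minimal()
}
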