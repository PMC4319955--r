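#' Compare two groups of measurements
#'
#' Welch two-sample t test (unequal variances), two-sided, with group
#' means and 95% confidence intervals. A Mann-Whitney (Wilcoxon rank-sum)
#' alternative is available for heavy-tailed metrics. When both groups
#' have zero variance and equal means, p = 1 by convention.
#'
#' @param values_a,values_b Numeric samples, n >= 2 each (NAs dropped).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return A `GroupComparison` list: `n`, `means`, `sds`, `ci95` (2x2
#'   matrix), `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  ci <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) return(c(m, m))
    half <- stats::qt(0.975, length(x) - 1) * s / sqrt(length(x))
    c(m - half, m + half)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stat <- NA_real_
    p <- if (mean(a) == mean(b)) 1 else 0
  } else if (test == "welch") {
    tt <- stats::t.test(a, b)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(n = c(a = length(a), b = length(b)),
                 means = c(a = mean(a), b = mean(b)),
                 sds = c(a = stats::sd(a), b = stats::sd(b)),
                 ci95 = rbind(a = ci(a), b = ci(b)),
                 statistic = stat, p_value = p, test = test),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "GroupComparison (%s): mean a = %.4g (n=%d), mean b = %.4g (n=%d), p = %.3g\n",
    x$test, x$means["a"], x$n["a"], x$means["b"], x$n["b"], x$p_value))
  invisible(x)
}

#' Summarize analysis tables per condition and metric
#'
#' Long summary of every numeric metric in the events/geometry/kinetics
#' tables: one row per (condition, metric) with n, mean, SD, 95% CI, and
#' the count of oocytes excluded because the metric was undetected (NA).
#'
#' @param events,geometry,kinetics Result tables from [analyze_dir()]
#'   (any may be NULL).
#' @param grouping Named vector or 2-column data.frame mapping oocyte_id
#'   to condition; oocyte ids present in the tables but absent here are an
#'   integrity error.
#' @return A `data.table` summary.
#' @export
cohort_summary <- function(events = NULL, geometry = NULL, kinetics = NULL,
                           grouping) {
  if (is.data.frame(grouping)) {
    grp <- stats::setNames(as.character(grouping[[2]]),
                           as.character(grouping[[1]]))
  } else {
    grp <- grouping
  }
  pieces <- list()
  add_table <- function(tab, label) {
    if (is.null(tab) || !nrow(tab)) return()
    tab <- as.data.frame(tab)
    orphans <- setdiff(unique(tab$oocyte_id), names(grp))
    if (length(orphans)) {
      stop("oocyte id(s) missing from grouping: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
    nums <- names(tab)[vapply(tab, is.numeric, logical(1))]
    for (m in nums) {
      df <- data.frame(condition = unname(grp[as.character(tab$oocyte_id)]),
                       metric = paste0(label, ".", m),
                       value = tab[[m]])
      pieces[[length(pieces) + 1]] <<- df
    }
  }
  add_table(events, "events")
  add_table(geometry, "geometry")
  add_table(kinetics, "kinetics")
  long <- data.table::rbindlist(pieces)
  long[, {
    v <- value[!is.na(value)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n > 1) stats::sd(v) else NA_real_
    half <- if (n > 1 && s > 0) stats::qt(0.975, n - 1) * s / sqrt(n)
            else 0
    list(n = n, mean = m, sd = s,
         ci_lo = if (n) m - half else NA_real_,
         ci_hi = if (n) m + half else NA_real_,
         n_excluded = sum(is.na(value)),
         sd_undefined = n < 2)
  }, by = c("condition", "metric")]
}

#' Write the cohort report: summary table and per-metric plots
#'
#' @param results List from [analyze_dir()].
#' @param grouping Mapping oocyte_id -> condition (see
#'   [cohort_summary()]).
#' @param out_dir Output directory; writes `group_stats.csv` and one SVG
#'   scatter (mean +/- 95% CI) per metric.
#' @return The summary table, invisibly.
#' @export
write_report <- function(results, grouping, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- cohort_summary(results$events, results$geometry,
                         results$kinetics, grouping)
  data.table::fwrite(summ, file.path(out_dir, "group_stats.csv"))
  if (is.data.frame(grouping)) {
    grp <- stats::setNames(as.character(grouping[[2]]),
                           as.character(grouping[[1]]))
  } else grp <- grouping
  for (tab_name in c("events", "geometry", "kinetics")) {
    tab <- results[[tab_name]]
    if (is.null(tab) || !nrow(tab)) next
    tab <- as.data.frame(tab)
    nums <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                    "oocyte_id")
    for (m in nums) {
      vals <- tab[[m]]
      conds <- factor(grp[as.character(tab$oocyte_id)])
      if (all(is.na(vals))) next
      f <- file.path(out_dir, paste0(tab_name, "_", m, ".svg"))
      grDevices::svg(f, width = 5, height = 4)
      graphics::plot(jitter(as.integer(conds), 0.15), vals,
                     xaxt = "n", xlab = "", ylab = m,
                     main = paste(tab_name, m), pch = 19,
                     col = grDevices::adjustcolor("steelblue", 0.6))
      graphics::axis(1, at = seq_along(levels(conds)),
                     labels = levels(conds), las = 2, cex.axis = 0.8)
      for (li in seq_along(levels(conds))) {
        v <- vals[as.integer(conds) == li]
        v <- v[!is.na(v)]
        if (!length(v)) next
        mu <- mean(v)
        graphics::segments(li - 0.2, mu, li + 0.2, mu, lwd = 2)
        if (length(v) > 1 && stats::sd(v) > 0) {
          half <- stats::qt(0.975, length(v) - 1) *
            stats::sd(v) / sqrt(length(v))
          graphics::arrows(li, mu - half, li, mu + half, angle = 90,
                           code = 3, length = 0.05)
        }
      }
      grDevices::dev.off()
    }
  }
  invisible(summ)
}
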