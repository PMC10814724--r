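#' Group x day summaries of a measurement
#'
#' Per dose-group and day: n (non-missing), mean, SEM (`sd / sqrt(n)`,
#' missing when n = 1), and — when the cohort has been scored for this
#' measurement (see [score_cohort()]) — the percentage of Z-scores above
#' the cutoff. Cells with no data are absent from the output, never
#' reported as zero.
#'
#' @param records Cohort records (optionally scored).
#' @param measurement Measurement column to summarize.
#' @param cutoff CAL cutoff used for the percent column, default 3.
#' @return Tibble with columns `group`, `day`, `measurement`, `n`, `mean`,
#'   `sem` and (if Z-scores are present) `percent_z_gt_cutoff`.
#' @export
summarize_cohort <- function(records, measurement, cutoff = 3.0) {
  if (!measurement %in% names(records)) {
    stop("measurement '", measurement, "' not found", call. = FALSE)
  }
  zcol <- paste0("z_", measurement)
  out <- records |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      measurement = measurement,
      n = sum(!is.na(.data[[measurement]])),
      mean = mean(.data[[measurement]], na.rm = TRUE),
      sem = if (sum(!is.na(.data[[measurement]])) > 1) {
        sd(.data[[measurement]], na.rm = TRUE) /
          sqrt(sum(!is.na(.data[[measurement]])))
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n > 0)
  if (zcol %in% names(records)) {
    pz <- records |>
      dplyr::group_by(.data$group, .data$day) |>
      dplyr::summarise(
        percent_z_gt_cutoff = if (any(!is.na(.data[[zcol]]))) {
          percent_above(.data[[zcol]], cutoff)
        } else {
          NA_real_
        },
        .groups = "drop"
      )
    out <- dplyr::left_join(pz, out, by = c("group", "day")) |>
      dplyr::select("group", "day", "measurement", "n", "mean", "sem",
                    "percent_z_gt_cutoff") |>
      dplyr::filter(!is.na(.data$n))
  }
  out
}

#' Two-sample Student's t-test between dose groups
#'
#' Classical pooled-variance two-tailed Student's t-test of a measurement
#' between two groups at one study day (`df = n_a + n_b - 2`); Welch's
#' unequal-variance form is available behind `welch = TRUE`. Significance
#' is called at p <= 0.05.
#'
#' @param records Cohort records.
#' @param group_a,group_b Group labels to compare (a minus b).
#' @param measurement Measurement column.
#' @param day Study day.
#' @param welch Use Welch's t instead of the pooled form. Default `FALSE`.
#' @param alpha Significance threshold, default 0.05.
#' @return One-row tibble: `group_a`, `group_b`, `measurement`, `day`,
#'   `n_a`, `n_b`, `t`, `df`, `p`, `significant`.
#' @export
two_sample_t <- function(records, group_a, group_b, measurement, day,
                         welch = FALSE, alpha = 0.05) {
  pick <- function(g) {
    v <- records[[measurement]][records$group == g & records$day == day]
    v[!is.na(v)]
  }
  a <- pick(group_a); b <- pick(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("two_sample_t needs >= 2 values per group (have ", length(a),
         " and ", length(b), ")", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = !welch)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    measurement = measurement, day = day,
    n_a = length(a), n_b = length(b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, significant = ht$p.value <= alpha
  )
}

#' Pearson correlation between two measurements
#'
#' Product-moment correlation over complete pairs at one study day, with a
#' two-tailed p-value from the t-transform on n - 2 degrees of freedom.
#' Pairs with a missing value in either variable are dropped, never
#' imputed.
#'
#' @param records Cohort records.
#' @param x_name,y_name Measurement columns to correlate.
#' @param day Study day; `NULL` uses all rows.
#' @return One-row tibble: `x_name`, `y_name`, `day`, `n`, `r`, `p`.
#' @export
pearson_corr <- function(records, x_name, y_name, day = NULL) {
  rows <- if (is.null(day)) records else records[records$day == day, ]
  x <- rows[[x_name]]; y <- rows[[y_name]]
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("pearson_corr needs >= 3 complete pairs (have ", n, ")",
         call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("pearson_corr: zero variance in ",
         if (var(x) == 0) x_name else y_name, call. = FALSE)
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    x_name = x_name, y_name = y_name,
    day = if (is.null(day)) NA_integer_ else day,
    n = n, r = unname(ht$estimate), p = ht$p.value
  )
}

#' Dose-response table with monotonicity flag
#'
#' Group means of a measurement per day, ordered by dose rank, with a flag
#' per day that is `TRUE` iff the means are non-decreasing in dose rank
#' (the direction expected of LCWE-induced dilation/thickening). A single
#' available group makes the flag vacuously `TRUE`.
#'
#' @param records Cohort records.
#' @param measurement Measurement column.
#' @param group_order Group labels in increasing dose rank; default
#'   control < low < medium < high.
#' @return List of class `dose_response` with `summaries` (the ordered
#'   group x day table) and `monotonicity` (tibble of `day`,
#'   `non_decreasing`, `n_groups`).
#' @export
dose_response_table <- function(records, measurement,
                                group_order = c("control", "low",
                                                "medium", "high")) {
  present <- intersect(group_order, unique(records$group))
  if (length(present) == 0) {
    stop("none of the groups in group_order are present", call. = FALSE)
  }
  summaries <- summarize_cohort(records, measurement) |>
    dplyr::filter(.data$group %in% present) |>
    dplyr::arrange(.data$day, match(.data$group, group_order))
  mono <- summaries |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      non_decreasing = !is.unsorted(.data$mean),
      n_groups = dplyr::n(),
      .groups = "drop"
    )
  structure(list(summaries = summaries, monotonicity = mono),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response>", unique(x$summaries$measurement), "\n")
  print(x$summaries)
  print(x$monotonicity)
  invisible(x)
}

#' Percent-Z table by dose group and day
#'
#' Wide table of the percentage of animals with Z above the cutoff: one
#' row per dose group (in dose-rank order), one column per study day.
#'
#' @param scored Scored records (see [score_cohort()]).
#' @param measurement Scored measurement.
#' @param cutoff CAL cutoff, default 3.
#' @param group_order Dose-rank order of groups.
#' @return Tibble, rows = groups, columns `group` then `day_<d>`.
#' @export
percent_z_table <- function(scored, measurement, cutoff = 3.0,
                            group_order = c("control", "low",
                                            "medium", "high")) {
  zcol <- paste0("z_", measurement)
  if (!zcol %in% names(scored)) {
    stop("records are not scored for '", measurement,
         "'; run score_cohort() first", call. = FALSE)
  }
  long <- summarize_cohort(scored, measurement, cutoff) |>
    dplyr::filter(.data$group %in% group_order)
  long |>
    dplyr::mutate(day = paste0("day_", .data$day)) |>
    dplyr::select("group", "day", "percent_z_gt_cutoff") |>
    tidyr::pivot_wider(names_from = "day",
                       values_from = "percent_z_gt_cutoff") |>
    dplyr::arrange(match(.data$group, group_order))
}

#' Full cohort-level analysis
#'
#' Runs the standard report on a scored cohort: group x day summaries of
#' the key measurements, each treated group versus control by pooled
#' t-test at every post-baseline day, the day-28 carotid-coronary Pearson
#' correlations on weight-adjusted values (carotid outer diameter and
#' carotid mean wall thickness against coronary inner diameter), and the
#' percent-Z table. No multiple-testing correction is applied; the number
#' of tests run is reported alongside.
#'
#' @param scored Scored, derived cohort records.
#' @param measurement Scored measurement for the percent-Z table.
#' @param cutoff CAL cutoff, default 3.
#' @param group_order Dose-rank order of groups.
#' @param summary_measurements Measurements to summarize and t-test.
#' @param corr_day Day of the carotid-coronary correlation, default 28.
#' @param corr_weight_adjusted Correlate weight-adjusted values (default)
#'   or raw mm.
#' @return List of class `kdz_report`: `summaries`, `ttests`,
#'   `correlations`, `percent_z`, `n_tests`.
#' @export
analyze_cohort <- function(scored,
                           measurement = "coronary_inner_d_mm",
                           cutoff = 3.0,
                           group_order = c("control", "low",
                                           "medium", "high"),
                           summary_measurements = c(
                             "coronary_inner_d_mm", "carotid_outer_d_mm",
                             "carotid_wall_mean_mm", "aorta_outer_d_mm",
                             "ejection_fraction_pct"
                           ),
                           corr_day = 28,
                           corr_weight_adjusted = TRUE) {
  summary_measurements <- intersect(summary_measurements, names(scored))
  summaries <- dplyr::bind_rows(lapply(
    summary_measurements, function(m) summarize_cohort(scored, m, cutoff)
  ))
  ctl <- group_order[1]
  treated <- setdiff(intersect(group_order, unique(scored$group)), ctl)
  days <- sort(setdiff(unique(scored$day), 0))
  ttests <- list()
  for (m in summary_measurements) {
    for (g in treated) {
      for (d in days) {
        n_ok <- function(gr) {
          sum(!is.na(scored[[m]][scored$group == gr & scored$day == d]))
        }
        if (n_ok(g) >= 2 && n_ok(ctl) >= 2) {
          ttests[[length(ttests) + 1]] <- two_sample_t(scored, g, ctl, m, d)
        }
      }
    }
  }
  ttests <- dplyr::bind_rows(ttests)
  suffix <- if (corr_weight_adjusted) "_wadj" else "_mm"
  cor_pairs <- list(
    c(paste0("carotid_outer_d", suffix), paste0("coronary_inner_d", suffix)),
    c(paste0("carotid_wall_mean", suffix), paste0("coronary_inner_d", suffix))
  )
  correlations <- dplyr::bind_rows(lapply(cor_pairs, function(p) {
    if (all(p %in% names(scored))) {
      pearson_corr(scored, p[1], p[2], day = corr_day)
    }
  }))
  pz <- if (paste0("z_", measurement) %in% names(scored)) {
    percent_z_table(scored, measurement, cutoff, group_order)
  } else {
    NULL
  }
  structure(
    list(
      summaries = summaries,
      ttests = ttests,
      correlations = correlations,
      percent_z = pz,
      n_tests = nrow(ttests) + nrow(correlations)
    ),
    class = "kdz_report"
  )
}

#' @export
print.kdz_report <- function(x, ...) {
  cat("<kdz_report>\n")
  cat(sprintf("  %d summaries, %d t-tests + %d correlations (uncorrected)\n",
              nrow(x$summaries), nrow(x$ttests), nrow(x$correlations)))
  if (!is.null(x$percent_z)) {
    cat("  percent Z > cutoff by dose group and day:\n")
    print(x$percent_z)
  }
  invisible(x)
}
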