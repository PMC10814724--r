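#' Construct a normative model object
#'
#' Low-level constructor for a day-0 normative reference model of one echo
#' measurement. In `regression` mode the model is
#' `predicted = intercept + slope * sqrt(BSA)` with a residual SD; in
#' `mean_sd` mode the slope is 0 and intercept/residual_sd are the plain
#' day-0 mean and SD. Usually built by [fit_normative()]; the constructor
#' is exported so analytically known reference models can be used directly
#' (e.g. in calibration studies).
#'
#' @param measurement Measurement name.
#' @param intercept Intercept in native units.
#' @param slope Slope in native units per cm of sqrt(BSA).
#' @param residual_sd Residual SD in native units, > 0.
#' @param n Number of baseline observations.
#' @param mode `"regression"` or `"mean_sd"`.
#' @return Object of class `normative_model` with fields `measurement`,
#'   `intercept`, `slope`, `residual_sd`, `n`, `dof`, `mode`.
#' @export
normative_model <- function(measurement, intercept, slope, residual_sd, n,
                            mode = c("regression", "mean_sd")) {
  mode <- match.arg(mode)
  if (!is.finite(residual_sd) || residual_sd <= 0) {
    stop("residual_sd must be > 0", call. = FALSE)
  }
  min_n <- if (mode == "regression") 3L else 2L
  if (n < min_n) {
    stop("normative model needs n >= ", min_n, " in ", mode, " mode",
         call. = FALSE)
  }
  structure(
    list(
      measurement = measurement,
      intercept = intercept,
      slope = slope,
      residual_sd = residual_sd,
      n = as.integer(n),
      dof = as.integer(n) - if (mode == "regression") 2L else 1L,
      mode = mode
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model>", x$measurement, sprintf("[%s mode]\n", x$mode))
  cat(sprintf("  predicted = %.6g %+.6g * sqrt(BSA) [cm]\n",
              x$intercept, x$slope))
  cat(sprintf("  residual SD = %.6g (n = %d, dof = %d)\n",
              x$residual_sd, x$n, x$dof))
  invisible(x)
}

#' Fit the day-0 normative model
#'
#' Fits the pre-treatment reference model of a measurement used for
#' Z-scoring. `regression` mode (default) regresses the observed day-0
#' values on sqrt(BSA) by ordinary least squares, with
#' `residual_sd = sqrt(SSE / (n - 2))`; `mean_sd` mode is the degenerate
#' body-size-free model: intercept = day-0 sample mean, slope = 0,
#' residual_sd = day-0 sample SD (n - 1 denominator). The degenerate mode
#' matches reference ranges reported as plain mean +/- SD.
#'
#' @param baseline Derived day-0 records (see [derive_measures()]); all
#'   rows must have `day == 0`.
#' @param measurement Measurement column to model.
#' @param mode `"regression"` (default) or `"mean_sd"`.
#' @return A [normative_model()].
#' @export
fit_normative <- function(baseline, measurement,
                          mode = c("regression", "mean_sd")) {
  mode <- match.arg(mode)
  if (!measurement %in% names(baseline)) {
    stop("measurement '", measurement, "' not found in baseline",
         call. = FALSE)
  }
  if (!"day" %in% names(baseline) || any(baseline$day != 0)) {
    stop("baseline must contain day-0 records only", call. = FALSE)
  }
  y <- baseline[[measurement]]
  if (mode == "regression") {
    if (!"sqrt_bsa_cm" %in% names(baseline)) {
      stop("baseline lacks sqrt_bsa_cm; run derive_measures() first",
           call. = FALSE)
    }
    x <- baseline$sqrt_bsa_cm
    keep <- !is.na(y) & !is.na(x)
    y <- y[keep]; x <- x[keep]
    n <- length(y)
    if (n < 3) {
      stop("need >= 3 baseline values in regression mode (have ", n,
           "); use mode = 'mean_sd' for smaller baselines", call. = FALSE)
    }
    if (var(x) == 0) {
      stop("sqrt(BSA) has zero variance in the baseline; ",
           "fall back to mode = 'mean_sd'", call. = FALSE)
    }
    fit <- lm(y ~ x)
    sse <- sum(residuals(fit)^2)
    normative_model(
      measurement = measurement,
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      residual_sd = sqrt(sse / (n - 2)),
      n = n,
      mode = "regression"
    )
  } else {
    y <- y[!is.na(y)]
    n <- length(y)
    if (n < 2) {
      stop("need >= 2 baseline values in mean_sd mode (have ", n, ")",
           call. = FALSE)
    }
    s <- sd(y)
    if (s == 0) {
      stop("baseline values are constant: zero SD, no normative model",
           call. = FALSE)
    }
    normative_model(
      measurement = measurement,
      intercept = mean(y),
      slope = 0,
      residual_sd = s,
      n = n,
      mode = "mean_sd"
    )
  }
}

#' Z-score an observation against a normative model
#'
#' `z = (observed - predicted) / residual_sd` with
#' `predicted = intercept + slope * sqrt_bsa`. Missing observations yield
#' missing Z-scores, never silent zeros.
#'
#' @param model A [normative_model()].
#' @param observed Observed values in native units (vectorized).
#' @param sqrt_bsa sqrt(BSA) in cm for each observation; may be omitted for
#'   a zero-slope model.
#' @return Numeric Z-scores (dimensionless).
#' @export
z_score <- function(model, observed, sqrt_bsa = NULL) {
  stopifnot(inherits(model, "normative_model"))
  if (is.null(sqrt_bsa)) {
    if (model$slope != 0) {
      stop("model has a sqrt(BSA) slope; supply sqrt_bsa", call. = FALSE)
    }
    sqrt_bsa <- 0
  }
  predicted <- model$intercept + model$slope * sqrt_bsa
  (observed - predicted) / model$residual_sd
}

#' Classify a coronary artery lesion from a Z-score
#'
#' Strict threshold rule: abnormal iff `z > cutoff` (a Z exactly at the
#' cutoff is normal). Missing Z gives missing flag.
#'
#' @param z Z-scores.
#' @param cutoff Dimensionless cutoff, default 3.
#' @return Logical CAL flags.
#' @export
classify_cal <- function(z, cutoff = 3.0) {
  z > cutoff
}

#' Percentage of Z-scores above the cutoff
#'
#' `100 * (# z > cutoff) / (# non-missing z)`, the per-cell abnormality
#' rate reported by dose group and day.
#'
#' @param z Z-scores; at least one non-missing.
#' @param cutoff Dimensionless cutoff, default 3.
#' @return Percentage in `[0, 100]`.
#' @export
percent_above <- function(z, cutoff = 3.0) {
  z <- z[!is.na(z)]
  if (length(z) == 0) {
    stop("percent_above: all Z-scores are missing", call. = FALSE)
  }
  100 * sum(z > cutoff) / length(z)
}

#' Score a cohort against a normative model
#'
#' Appends `z_<measurement>` and `cal_<measurement>` columns computed from
#' the model; rows with a missing observation get missing Z and flag.
#'
#' @param records Derived records (need `sqrt_bsa_cm` for a sloped model).
#' @param model A [normative_model()].
#' @param cutoff CAL cutoff, default 3.
#' @return The records with Z and CAL columns appended.
#' @export
score_cohort <- function(records, model, cutoff = 3.0) {
  stopifnot(inherits(model, "normative_model"))
  m <- model$measurement
  if (!m %in% names(records)) {
    stop("records lack measurement '", m, "'", call. = FALSE)
  }
  sb <- if (model$slope != 0 || model$mode == "regression") {
    if (!"sqrt_bsa_cm" %in% names(records)) {
      stop("records lack sqrt_bsa_cm; run derive_measures() first",
           call. = FALSE)
    }
    records$sqrt_bsa_cm
  } else {
    NULL
  }
  z <- z_score(model, records[[m]], sb)
  records[[paste0("z_", m)]] <- z
  records[[paste0("cal_", m)]] <- classify_cal(z, cutoff)
  records
}

#' Write a normative model to JSON
#'
#' Full-precision JSON serialization; [read_normative_model()] restores a
#' bit-identical model.
#'
#' @param model A [normative_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  # 17 significant digits round-trip IEEE doubles exactly
  num <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(sprintf(
    paste0('{"measurement":"%s","intercept":%s,"slope":%s,',
           '"residual_sd":%s,"n":%d,"dof":%d,"mode":"%s"}'),
    model$measurement, num(model$intercept), num(model$slope),
    num(model$residual_sd), model$n, model$dof, model$mode
  ), path)
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path Path written by [write_normative_model()].
#' @return A [normative_model()].
#' @export
read_normative_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  normative_model(
    measurement = raw$measurement,
    intercept = raw$intercept,
    slope = raw$slope,
    residual_sd = raw$residual_sd,
    n = raw$n,
    mode = raw$mode
  )
}
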