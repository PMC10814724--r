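#' Echo measurement column names
#'
#' Canonical names (and order) of the per-animal echocardiographic
#' measurement columns used throughout the package. All lengths are in mm;
#' ejection fraction is in percent.
#'
#' @return Character vector of measurement column names.
#' @export
echo_measurements <- function() {
  c(
    "coronary_inner_d_mm", "coronary_outer_d_mm",
    "carotid_inner_d_mm", "carotid_outer_d_mm",
    "carotid_upper_wall_mm", "carotid_lower_wall_mm",
    "aorta_inner_d_mm", "aorta_outer_d_mm",
    "aorta_upper_wall_mm", "aorta_lower_wall_mm",
    "ejection_fraction_pct"
  )
}

# full cohort CSV schema, in column order
cohort_columns <- function() {
  c("animal_id", "group", "day", "body_weight_g", echo_measurements())
}

#' Default day-0 normative ranges
#'
#' Per-measurement day-0 (pre-treatment) mean and SD in native units. The
#' coronary artery values are the published murine norms (inner diameter
#' 0.217 +/- 0.028 mm, outer 0.472 +/- 0.056 mm); the carotid, aortic, wall
#' and ejection-fraction entries are plausible defaults for healthy young
#' C57BL/6 mice and are freely configurable.
#'
#' @return Tibble with columns `measurement`, `mean`, `sd`.
#' @export
default_norms <- function() {
  tibble::tribble(
    ~measurement,            ~mean,  ~sd,
    "coronary_inner_d_mm",   0.217,  0.028,
    "coronary_outer_d_mm",   0.472,  0.056,
    "carotid_inner_d_mm",    0.45,   0.04,
    "carotid_outer_d_mm",    0.60,   0.05,
    "carotid_upper_wall_mm", 0.075,  0.010,
    "carotid_lower_wall_mm", 0.075,  0.010,
    "aorta_inner_d_mm",      1.05,   0.09,
    "aorta_outer_d_mm",      1.20,   0.10,
    "aorta_upper_wall_mm",   0.075,  0.010,
    "aorta_lower_wall_mm",   0.075,  0.010,
    "ejection_fraction_pct", 65,     5
  )
}

#' Default dose-group effect sizes
#'
#' Additive mean shifts, in units of each measurement's normative SD, for
#' every (group, day > 0, measurement) cell; cells not listed default to 0,
#' and the control group is identically 0. Coronary inner diameter carries
#' the central dilation signal (high dose +2 SD at day 7 rising to +5 SD at
#' days 21-28; medium +1 to +3; low +0.5 to +1.5) and ejection fraction
#' drops 1.5 SD in the high-dose group at day 21. Carotid and aortic
#' diameters and walls carry dose- and time-monotone dilation/thickening
#' shifts of the same directionality; coronary outer shifts mirror the
#' inner ones on the outer-SD scale so the inner-outer gap is preserved.
#'
#' @return Tibble with columns `group`, `day`, `measurement`, `shift_sd`.
#' @export
default_effects <- function() {
  grid <- function(group, measurement, shifts) {
    tibble::tibble(
      group = group, day = c(7L, 14L, 21L, 28L),
      measurement = measurement, shift_sd = shifts
    )
  }
  dplyr::bind_rows(
    # coronary inner: the CAL signal
    grid("low", "coronary_inner_d_mm", c(0.5, 1.0, 1.5, 1.5)),
    grid("medium", "coronary_inner_d_mm", c(1.0, 2.0, 3.0, 3.0)),
    grid("high", "coronary_inner_d_mm", c(2.0, 3.5, 5.0, 5.0)),
    # coronary outer mirrors inner on its own SD scale
    grid("low", "coronary_outer_d_mm", c(0.25, 0.5, 0.75, 0.75)),
    grid("medium", "coronary_outer_d_mm", c(0.5, 1.0, 1.5, 1.5)),
    grid("high", "coronary_outer_d_mm", c(1.0, 1.75, 2.5, 2.5)),
    # carotid dilation and wall thickening
    grid("low", "carotid_outer_d_mm", c(0.25, 0.5, 0.75, 1.0)),
    grid("medium", "carotid_outer_d_mm", c(0.5, 1.0, 1.5, 2.0)),
    grid("high", "carotid_outer_d_mm", c(1.0, 2.0, 2.5, 3.0)),
    grid("low", "carotid_inner_d_mm", c(-0.25, -0.25, -0.25, -0.25)),
    grid("medium", "carotid_inner_d_mm", c(-0.5, -0.5, -0.5, -0.5)),
    grid("high", "carotid_inner_d_mm", c(-1.0, -1.0, -1.0, -1.0)),
    grid("low", "carotid_upper_wall_mm", c(0.5, 0.5, 0.75, 1.0)),
    grid("medium", "carotid_upper_wall_mm", c(1.0, 1.25, 1.5, 2.0)),
    grid("high", "carotid_upper_wall_mm", c(2.0, 2.0, 2.5, 3.0)),
    grid("low", "carotid_lower_wall_mm", c(0.5, 0.5, 0.75, 1.0)),
    grid("medium", "carotid_lower_wall_mm", c(1.0, 1.25, 1.5, 2.0)),
    grid("high", "carotid_lower_wall_mm", c(2.0, 2.0, 2.5, 3.0)),
    # aorta
    grid("low", "aorta_outer_d_mm", c(0.0, 0.25, 0.5, 0.75)),
    grid("medium", "aorta_outer_d_mm", c(0.25, 0.5, 1.0, 1.5)),
    grid("high", "aorta_outer_d_mm", c(0.5, 1.0, 1.5, 2.0)),
    grid("low", "aorta_upper_wall_mm", c(0.5, 0.5, 0.5, 0.75)),
    grid("medium", "aorta_upper_wall_mm", c(1.0, 1.0, 1.0, 1.5)),
    grid("high", "aorta_upper_wall_mm", c(2.0, 1.5, 1.5, 2.5)),
    grid("low", "aorta_lower_wall_mm", c(0.5, 0.5, 0.5, 0.75)),
    grid("medium", "aorta_lower_wall_mm", c(1.0, 1.0, 1.0, 1.5)),
    grid("high", "aorta_lower_wall_mm", c(2.0, 1.5, 1.5, 2.5)),
    # cardiac function dips in the high-dose group at day 21
    tibble::tibble(
      group = "high", day = 21L,
      measurement = "ejection_fraction_pct", shift_sd = -1.5
    )
  )
}

#' Default measurement-noise overrides
#'
#' Post-baseline measurement noise defaults to `noise_sd_scale` times the
#' normative SD. These rows override that with an absolute SD for specific
#' (group, measurement) cells at days > 0; the default gives the dilated
#' coronary inner diameter in the medium- and high-dose groups a wider
#' absolute noise SD of 0.04 mm, reflecting the larger caliper variability
#' of a dilated vessel.
#'
#' @return Tibble with columns `group`, `measurement`, `sd_abs`.
#' @export
default_noise_overrides <- function() {
  tibble::tibble(
    group = c("medium", "high"),
    measurement = "coronary_inner_d_mm",
    sd_abs = 0.04
  )
}

#' Synthetic cohort generator configuration
#'
#' Full parameterization of the synthetic longitudinal echo cohort. The
#' defaults reproduce the study design: dose groups control/low/medium/high
#' (nominal doses 0/1/2/4 mg/kg, labels only -- effects are configured
#' explicitly, never computed from dose), n = 9 animals per group measured
#' at days 0, 7, 14, 21 and 28, a day-0 normative cohort of 38 animals, and
#' the day-0 normative ranges of [default_norms()].
#'
#' @param n_per_group_per_day Animals per dose group (each measured at every
#'   study day). Default 9.
#' @param n_baseline Total day-0 animals for the normative cohort. If the
#'   longitudinal animals supply fewer day-0 records, baseline-only control
#'   animals are added to reach this count. Default 38.
#' @param days Integer study days, sorted ascending, unique; default
#'   `c(0, 7, 14, 21, 28)`.
#' @param groups Named numeric vector of nominal doses in mg/kg; names give
#'   the ordered dose-group labels. Default
#'   `c(control = 0, low = 1, medium = 2, high = 4)`.
#' @param weight_mean_g,weight_sd_g Baseline body weight distribution in g
#'   (default 20 +/- 1.5).
#' @param growth_g_per_day Linear body-weight growth in g/day (default 0.15).
#' @param weight_noise_sd_g Per-visit weight measurement noise SD in g
#'   (default 0.3).
#' @param norms Tibble of per-measurement day-0 mean/SD; see
#'   [default_norms()].
#' @param slope_per_sqrt_bsa Named numeric vector of per-measurement slopes
#'   of the mean on sqrt(BSA) (native units per cm), centred at the
#'   reference weight so the mean at `bsa_ref_weight_g` equals the norm
#'   mean. Unnamed measurements get slope 0. Default: all 0 (pure mean/SD
#'   model).
#' @param effects Tibble of additive mean shifts in normative-SD units; see
#'   [default_effects()]. Cells not listed are 0; control must be 0.
#' @param noise_sd_scale Multiplier on the normative SD for measurement
#'   noise (default 1).
#' @param noise_overrides Tibble of absolute noise SDs for (group,
#'   measurement) cells at days > 0; see [default_noise_overrides()].
#' @param rho Loading of the latent per-animal severity factor shared by
#'   carotid outer diameter, carotid walls and coronary inner diameter in
#'   treated groups at days > 0 (default 0.6, giving a population
#'   carotid-coronary correlation of rho^2 = 0.36 in affected groups).
#' @param coupled_measurements Measurements sharing the severity factor.
#' @param inner_outer_corr Within-row correlation between the inner and
#'   outer diameter of the same vessel (default 0.95): anatomically the two
#'   calipers track the same vessel, and independent draws would put inner >
#'   outer with non-negligible probability.
#' @param missingness Per-measurement probability that a value is missing
#'   (default 0).
#' @param published_ns If `TRUE`, emulate the published baseline Ns by
#'   masking day-0 coronary inner diameter down to `baseline_n_inner`
#'   observed values and coronary outer down to `baseline_n_outer`.
#' @param baseline_n_inner,baseline_n_outer Observed day-0 Ns used in
#'   published-Ns mode (defaults 18 and 37).
#' @param meeh_k Meeh coefficient for BSA = k * W^(2/3), in
#'   cm^2 g^(-2/3) (default 9.8, the murine convention).
#' @param bsa_ref_weight_g Reference weight (g) at which the sqrt(BSA) slope
#'   term is centred (default 20).
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   cohort.
#'
#' @return A validated list of class `kdz_config`.
#' @seealso [generate_cohort()], [read_config()]
#' @export
kdz_config <- function(n_per_group_per_day = 9L,
                       n_baseline = 38L,
                       days = c(0L, 7L, 14L, 21L, 28L),
                       groups = c(control = 0, low = 1, medium = 2, high = 4),
                       weight_mean_g = 20,
                       weight_sd_g = 1.5,
                       growth_g_per_day = 0.15,
                       weight_noise_sd_g = 0.3,
                       norms = default_norms(),
                       slope_per_sqrt_bsa = NULL,
                       effects = default_effects(),
                       noise_sd_scale = 1,
                       noise_overrides = default_noise_overrides(),
                       rho = 0.6,
                       coupled_measurements = c(
                         "carotid_outer_d_mm", "carotid_upper_wall_mm",
                         "carotid_lower_wall_mm", "coronary_inner_d_mm"
                       ),
                       inner_outer_corr = 0.95,
                       missingness = 0,
                       published_ns = FALSE,
                       baseline_n_inner = 18L,
                       baseline_n_outer = 37L,
                       meeh_k = 9.8,
                       bsa_ref_weight_g = 20,
                       seed = 1L) {
  slopes <- setNames(rep(0, length(echo_measurements())), echo_measurements())
  if (!is.null(slope_per_sqrt_bsa)) {
    bad <- setdiff(names(slope_per_sqrt_bsa), echo_measurements())
    if (length(bad) > 0) {
      stop("slope_per_sqrt_bsa: unknown measurement(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    slopes[names(slope_per_sqrt_bsa)] <- slope_per_sqrt_bsa
  }
  # effect rows for groups outside the design are irrelevant; drop them so
  # reduced designs (e.g. day-0-only control cohorts) can keep the default
  # effects table
  if (nrow(effects) > 0) {
    effects <- effects[effects$group %in% names(groups), , drop = FALSE]
  }
  if (nrow(noise_overrides) > 0) {
    noise_overrides <-
      noise_overrides[noise_overrides$group %in% names(groups), , drop = FALSE]
  }
  cfg <- structure(
    list(
      n_per_group_per_day = as.integer(n_per_group_per_day),
      n_baseline = as.integer(n_baseline),
      days = as.integer(days),
      groups = groups,
      weight_mean_g = weight_mean_g,
      weight_sd_g = weight_sd_g,
      growth_g_per_day = growth_g_per_day,
      weight_noise_sd_g = weight_noise_sd_g,
      norms = norms,
      slope_per_sqrt_bsa = slopes,
      effects = effects,
      noise_sd_scale = noise_sd_scale,
      noise_overrides = noise_overrides,
      rho = rho,
      coupled_measurements = coupled_measurements,
      inner_outer_corr = inner_outer_corr,
      missingness = missingness,
      published_ns = isTRUE(published_ns),
      baseline_n_inner = as.integer(baseline_n_inner),
      baseline_n_outer = as.integer(baseline_n_outer),
      meeh_k = meeh_k,
      bsa_ref_weight_g = bsa_ref_weight_g,
      seed = as.integer(seed)
    ),
    class = "kdz_config"
  )
  validate_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks every structural invariant of a [kdz_config()] and fails with an
#' error naming the offending field.
#'
#' @param config A `kdz_config` list.
#' @return The config, invisibly unchanged, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) {
    stop("invalid config: field '", field, "': ", msg, call. = FALSE)
  }
  if (!inherits(config, "kdz_config")) {
    stop("config must be a 'kdz_config' object (see kdz_config())",
         call. = FALSE)
  }
  n <- config$n_per_group_per_day
  if (!is.finite(n) || n < 2) fail("n_per_group_per_day", "must be >= 2")
  if (!is.finite(config$n_baseline) || config$n_baseline < 2) {
    fail("n_baseline", "must be >= 2")
  }
  d <- config$days
  if (length(d) < 1 || anyNA(d)) fail("days", "must be non-empty, no NA")
  if (is.unsorted(d, strictly = TRUE)) {
    fail("days", "must be sorted ascending and unique")
  }
  if (any(d < 0)) fail("days", "must be non-negative")
  if (is.null(names(config$groups)) || any(names(config$groups) == "")) {
    fail("groups", "must be a named vector (labels = group names)")
  }
  if (anyDuplicated(names(config$groups))) fail("groups", "duplicate labels")
  nr <- config$norms
  if (!all(c("measurement", "mean", "sd") %in% names(nr))) {
    fail("norms", "needs columns measurement, mean, sd")
  }
  missing_m <- setdiff(echo_measurements(), nr$measurement)
  if (length(missing_m) > 0) {
    fail("norms", paste("missing measurement(s):",
                        paste(missing_m, collapse = ", ")))
  }
  if (any(!is.finite(nr$sd) | nr$sd < 0)) fail("norms", "all SDs must be >= 0")
  if (any(!is.finite(nr$mean))) fail("norms", "all means must be finite")
  ef <- config$effects
  if (nrow(ef) > 0) {
    if (!all(c("group", "day", "measurement", "shift_sd") %in% names(ef))) {
      fail("effects", "needs columns group, day, measurement, shift_sd")
    }
    bad_g <- setdiff(unique(ef$group), names(config$groups))
    if (length(bad_g) > 0) {
      fail("effects", paste("unknown group(s):", paste(bad_g, collapse = ", ")))
    }
    ctl <- names(config$groups)[1]
    if (any(ef$group == ctl & ef$shift_sd != 0)) {
      fail("effects", paste0("effects for the control group ('", ctl,
                             "') must be identically 0"))
    }
    if (any(ef$day == 0 & ef$shift_sd != 0)) {
      fail("effects", "day-0 effects must be 0 (baseline is pre-treatment)")
    }
    if (anyDuplicated(ef[c("group", "day", "measurement")])) {
      fail("effects", "duplicate (group, day, measurement) rows")
    }
  }
  if (!is.finite(config$weight_sd_g) || config$weight_sd_g < 0) {
    fail("weight_sd_g", "must be >= 0")
  }
  if (config$weight_mean_g <= 0) fail("weight_mean_g", "must be > 0")
  if (config$weight_noise_sd_g < 0) fail("weight_noise_sd_g", "must be >= 0")
  if (config$noise_sd_scale < 0) fail("noise_sd_scale", "must be >= 0")
  if (config$rho < 0 || config$rho >= 1) fail("rho", "must be in [0, 1)")
  if (abs(config$inner_outer_corr) >= 1) {
    fail("inner_outer_corr", "must be in (-1, 1)")
  }
  if (config$missingness < 0 || config$missingness >= 1) {
    fail("missingness", "must be in [0, 1)")
  }
  if (config$meeh_k <= 0) fail("meeh_k", "must be > 0")
  if (config$bsa_ref_weight_g <= 0) fail("bsa_ref_weight_g", "must be > 0")
  if (is.na(config$seed)) fail("seed", "must be an integer")
  invisible(config)
}

#' @export
print.kdz_config <- function(x, ...) {
  cat("<kdz_config>\n")
  cat("  groups:", paste(names(x$groups), collapse = ", "),
      sprintf("(n = %d per group per day)\n", x$n_per_group_per_day))
  cat("  days:", paste(x$days, collapse = ", "),
      sprintf("| baseline N = %d\n", x$n_baseline))
  cat(sprintf("  weight: %.1f +/- %.1f g, growth %.2f g/day\n",
              x$weight_mean_g, x$weight_sd_g, x$growth_g_per_day))
  cat(sprintf("  severity coupling rho = %.2f; seed = %d\n", x$rho, x$seed))
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' Every field of [kdz_config()] is addressable; scalar fields use their
#' argument names, `groups` is a label -> dose mapping, and `norms`,
#' `effects` and `noise_overrides` are lists of records. Fields absent from
#' the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `kdz_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  args <- list()
  scalars <- c(
    "n_per_group_per_day", "n_baseline", "weight_mean_g", "weight_sd_g",
    "growth_g_per_day", "weight_noise_sd_g", "noise_sd_scale", "rho",
    "inner_outer_corr", "missingness", "published_ns", "baseline_n_inner",
    "baseline_n_outer", "meeh_k", "bsa_ref_weight_g", "seed"
  )
  for (s in intersect(scalars, names(raw))) args[[s]] <- raw[[s]]
  if (!is.null(raw$days)) args$days <- as.integer(unlist(raw$days))
  if (!is.null(raw$groups)) args$groups <- unlist(raw$groups)
  if (!is.null(raw$slope_per_sqrt_bsa)) {
    args$slope_per_sqrt_bsa <- unlist(raw$slope_per_sqrt_bsa)
  }
  if (!is.null(raw$coupled_measurements)) {
    args$coupled_measurements <- unlist(raw$coupled_measurements)
  }
  rec_tbl <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  if (!is.null(raw$norms)) args$norms <- rec_tbl(raw$norms)
  if (!is.null(raw$effects)) {
    args$effects <- rec_tbl(raw$effects)
    args$effects$day <- as.integer(args$effects$day)
  }
  if (!is.null(raw$noise_overrides)) {
    args$noise_overrides <- rec_tbl(raw$noise_overrides)
  }
  do.call(kdz_config, args)
}

#' Write a generator configuration to YAML
#'
#' Inverse of [read_config()]: `read_config(write_config(cfg, f))` restores
#' an equivalent configuration.
#'
#' @param config A `kdz_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  as_recs <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  out <- list(
    n_per_group_per_day = config$n_per_group_per_day,
    n_baseline = config$n_baseline,
    days = as.list(config$days),
    groups = as.list(config$groups),
    weight_mean_g = config$weight_mean_g,
    weight_sd_g = config$weight_sd_g,
    growth_g_per_day = config$growth_g_per_day,
    weight_noise_sd_g = config$weight_noise_sd_g,
    norms = as_recs(config$norms),
    slope_per_sqrt_bsa = as.list(config$slope_per_sqrt_bsa),
    effects = as_recs(config$effects),
    noise_sd_scale = config$noise_sd_scale,
    noise_overrides = as_recs(config$noise_overrides),
    rho = config$rho,
    coupled_measurements = as.list(config$coupled_measurements),
    inner_outer_corr = config$inner_outer_corr,
    missingness = config$missingness,
    published_ns = config$published_ns,
    baseline_n_inner = config$baseline_n_inner,
    baseline_n_outer = config$baseline_n_outer,
    meeh_k = config$meeh_k,
    bsa_ref_weight_g = config$bsa_ref_weight_g,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
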