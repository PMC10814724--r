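#' Generate a synthetic longitudinal echo cohort
#'
#' Draws one record per animal x study day with the statistical structure
#' the downstream analysis assumes. Each dose group contributes
#' `n_per_group_per_day` animals measured at every day; if day 0 is in the
#' design and the longitudinal animals supply fewer than `n_baseline` day-0
#' records, baseline-only control animals are appended so the normative
#' cohort reaches `n_baseline`.
#'
#' Each measurement is drawn as
#' `norm_mean + slope * (sqrt(BSA) - sqrt(BSA_ref)) + shift_sd * norm_SD`
#' plus noise, where the noise SD is `noise_sd_scale * norm_SD` unless a
#' (group, measurement) override applies at days > 0. Treated groups at
#' days > 0 share a latent per-animal severity factor (loading `rho`)
#' across the coupled measurements, and the inner/outer calipers of the
#' same vessel are correlated at `inner_outer_corr` so that outer >= inner
#' holds with overwhelming probability. Control records at all days, and
#' all records at day 0, are marginally pure normative draws.
#'
#' @param config A validated [kdz_config()].
#' @return Tibble with columns `animal_id`, `group`, `day`,
#'   `body_weight_g` and the columns of [echo_measurements()]. Identical
#'   config + seed gives an identical table.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)

  group_labels <- names(config$groups)
  n <- config$n_per_group_per_day
  animals <- tibble::tibble(
    animal_id = unlist(lapply(group_labels, function(g) {
      sprintf("%s_%02d", g, seq_len(n))
    })),
    group = rep(group_labels, each = n),
    baseline_only = FALSE
  )
  has_day0 <- 0L %in% config$days
  if (has_day0) {
    extra <- config$n_baseline - nrow(animals)
    if (extra > 0) {
      animals <- dplyr::bind_rows(
        animals,
        tibble::tibble(
          animal_id = sprintf("baseline_%02d", seq_len(extra)),
          group = group_labels[1],
          baseline_only = TRUE
        )
      )
    }
  }
  n_animals <- nrow(animals)
  animals$w0 <- rnorm(n_animals, config$weight_mean_g, config$weight_sd_g)
  animals$u <- rnorm(n_animals)  # latent severity factor

  rows <- tidyr::crossing(animals, day = config$days)
  rows <- rows[!(rows$baseline_only & rows$day != 0L), ]
  rows <- dplyr::arrange(rows, match(.data$group, group_labels),
                         .data$animal_id, .data$day)
  n_rows <- nrow(rows)
  rows$body_weight_g <- rows$w0 + config$growth_g_per_day * rows$day +
    rnorm(n_rows, 0, config$weight_noise_sd_g)
  if (any(rows$body_weight_g <= 0)) {
    stop("generated non-positive body weight; check the weight model fields",
         call. = FALSE)
  }
  sqrt_bsa <- sqrt(config$meeh_k * rows$body_weight_g^(2 / 3))
  sqrt_bsa_ref <- sqrt(config$meeh_k * config$bsa_ref_weight_g^(2 / 3))

  norms <- config$norms
  norm_mean <- setNames(norms$mean, norms$measurement)
  norm_sd <- setNames(norms$sd, norms$measurement)
  ctl <- group_labels[1]
  affected <- rows$group != ctl & rows$day > 0L

  # effect shift per row x measurement (normative-SD units)
  shift_for <- function(m) {
    out <- numeric(n_rows)
    ef <- config$effects
    if (nrow(ef) == 0) return(out)
    ef <- ef[ef$measurement == m, , drop = FALSE]
    if (nrow(ef) == 0) return(out)
    key <- paste(rows$group, rows$day)
    idx <- match(key, paste(ef$group, ef$day))
    hit <- !is.na(idx)
    out[hit] <- ef$shift_sd[idx[hit]]
    out
  }
  noise_sd_for <- function(m) {
    out <- rep(config$noise_sd_scale * norm_sd[[m]], n_rows)
    ov <- config$noise_overrides
    if (nrow(ov) > 0) {
      ov <- ov[ov$measurement == m, , drop = FALSE]
      if (nrow(ov) > 0) {
        idx <- match(rows$group, ov$group)
        hit <- !is.na(idx) & rows$day > 0L
        out[hit] <- ov$sd_abs[idx[hit]]
      }
    }
    out
  }

  meas <- echo_measurements()
  # standardized noise: eps drawn per measurement in canonical order for
  # reproducibility, severity coupling applied in affected rows only
  eps <- lapply(setNames(meas, meas), function(m) rnorm(n_rows))
  z <- eps
  rho <- config$rho
  for (m in intersect(config$coupled_measurements, meas)) {
    z[[m]] <- ifelse(affected,
                     rho * rows$u + sqrt(1 - rho^2) * eps[[m]],
                     eps[[m]])
  }
  # inner/outer calipers of one vessel track each other
  c_io <- config$inner_outer_corr
  vessel_pairs <- list(
    c(primary = "coronary_inner_d_mm", secondary = "coronary_outer_d_mm"),
    c(primary = "carotid_outer_d_mm", secondary = "carotid_inner_d_mm"),
    c(primary = "aorta_outer_d_mm", secondary = "aorta_inner_d_mm")
  )
  for (p in vessel_pairs) {
    z[[p[["secondary"]]]] <- c_io * z[[p[["primary"]]]] +
      sqrt(1 - c_io^2) * eps[[p[["secondary"]]]]
  }

  for (m in meas) {
    rows[[m]] <- norm_mean[[m]] +
      config$slope_per_sqrt_bsa[[m]] * (sqrt_bsa - sqrt_bsa_ref) +
      shift_for(m) * norm_sd[[m]] +
      noise_sd_for(m) * z[[m]]
  }

  if (config$missingness > 0) {
    for (m in meas) {
      rows[[m]][runif(n_rows) < config$missingness] <- NA_real_
    }
  }
  if (config$published_ns && has_day0) {
    day0 <- which(rows$day == 0L)
    mask_to <- function(m, keep_n) {
      if (length(day0) > keep_n) {
        drop <- sample(day0, length(day0) - keep_n)
        rows[[m]][drop] <<- NA_real_
      }
    }
    mask_to("coronary_inner_d_mm", config$baseline_n_inner)
    mask_to("coronary_outer_d_mm", config$baseline_n_outer)
  }

  rows$day <- as.integer(rows$day)
  rows[, cohort_columns()]
}

#' Validate cohort records
#'
#' Checks the per-record invariants: positive body weight, positive lengths
#' where present, outer >= inner diameter per vessel, and ejection fraction
#' in (0, 100]. Fails naming the first offending row and invariant.
#'
#' @param records Cohort tibble with the [cohort_columns()] schema.
#' @return The records, invisibly, if valid.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fail_row <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      stop("invalid record at row ", bad[1], ": ", what, call. = FALSE)
    }
  }
  fail_row(!is.na(records$body_weight_g) & records$body_weight_g > 0,
           "body_weight_g must be > 0")
  lengths_mm <- setdiff(echo_measurements(), "ejection_fraction_pct")
  for (m in lengths_mm) {
    v <- records[[m]]
    fail_row(is.na(v) | v > 0, paste(m, "must be > 0 where present"))
  }
  pair_ok <- function(outer, inner) {
    o <- records[[outer]]; i <- records[[inner]]
    fail_row(is.na(o) | is.na(i) | o >= i,
             paste0(outer, " must be >= ", inner))
  }
  pair_ok("coronary_outer_d_mm", "coronary_inner_d_mm")
  pair_ok("carotid_outer_d_mm", "carotid_inner_d_mm")
  pair_ok("aorta_outer_d_mm", "aorta_inner_d_mm")
  ef <- records$ejection_fraction_pct
  fail_row(is.na(ef) | (ef > 0 & ef <= 100),
           "ejection_fraction_pct must be in (0, 100]")
  invisible(records)
}

#' Write a cohort to CSV
#'
#' UTF-8 CSV with the exact [cohort_columns()] header; missing values are
#' empty cells. Doubles are written at round-trip precision, so
#' `read_cohort(write_cohort(x, f))` restores `x` exactly.
#'
#' @param records Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, cohort_columns()]
  # 17 significant digits round-trip IEEE doubles exactly
  for (m in c("body_weight_g", echo_measurements())) {
    v <- out[[m]]
    out[[m]] <- ifelse(is.na(v), NA_character_,
                       formatC(v, digits = 17, format = "g"))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads a [write_cohort()]-format CSV (empty cells = missing) and
#' validates every record, failing with the row number and violated
#' invariant on malformed input.
#'
#' @param path CSV path.
#' @return Validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  classes <- c(
    animal_id = "character", group = "character", day = "integer",
    setNames(rep("numeric", length(echo_measurements()) + 1),
             c("body_weight_g", echo_measurements()))
  )
  # base strtod parses decimals correctly rounded, so the 17-digit CSV
  # written by write_cohort() round-trips doubles bit-exactly
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  records <- tibble::as_tibble(utils::read.csv(
    path, colClasses = classes[intersect(cohort_columns(), header)],
    na.strings = "", check.names = FALSE
  ))
  header_problems <- setdiff(cohort_columns(), names(records))
  if (length(header_problems) > 0) {
    stop("malformed cohort CSV, missing column(s): ",
         paste(header_problems, collapse = ", "), call. = FALSE)
  }
  records <- records[, cohort_columns()]
  if (nrow(records) > 0) validate_records(records)
  records
}
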