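# day-0-only normative cohort of n control animals
baseline_config <- function(n, seed = 1L, ...) {
  kdz_config(
    days = 0L, groups = c(control = 0),
    n_per_group_per_day = n, n_baseline = n,
    seed = seed, ...
  )
}

# no treatment effects anywhere
no_effects <- function() default_effects()[0, ]

# hand-built records table for the stats operations; cells are named
# "group@day" -> numeric values
records_of <- function(values_by_cell, measurement = "m") {
  dplyr::bind_rows(lapply(names(values_by_cell), function(key) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    v <- values_by_cell[[key]]
    tb <- tibble::tibble(
      animal_id = paste0(parts[1], "_", seq_along(v)),
      group = parts[1],
      day = as.integer(parts[2])
    )
    tb[[measurement]] <- v
    tb
  }))
}
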