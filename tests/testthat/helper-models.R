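# Shared fixtures: bundled models and a per-session cache of simulations
# reused across test files (the trajectories are deterministic).

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(population, dose, dt_h = 0.5) {
  key <- paste(population, dose, dt_h, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_pbk(pbk_model(population), dose, dt_h = dt_h)
  }
  .sim_cache[[key]]
}

fits_to_kinetics <- function(fits) {
  data.frame(
    pathway = vapply(fits, `[[`, character(1), "pathway"),
    km_uM = vapply(fits, `[[`, numeric(1), "km_uM"),
    vmax_invitro = vapply(fits, `[[`, numeric(1), "vmax_invitro"),
    stringsAsFactors = FALSE
  )
}

# tolerance of "+/- 1 unit in the last printed digit" for a rounded
# table value such as 15.6 or 0.01
last_digit_unit <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  dec <- ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0)
  10^(-dec)
}

expect_within_printed <- function(computed, printed) {
  expect_true(
    all(abs(computed - printed) <= last_digit_unit(printed) + 1e-9),
    label = paste0(
      "computed (", paste(signif(computed, 4), collapse = ", "),
      ") within one last-printed-digit of (",
      paste(printed, collapse = ", "), ")"
    )
  )
}
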