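# Bundled literature parameter sets for the Chinese and Caucasian
# populations: physiology, tissue:blood partition coefficients, and the
# Michaelis-Menten constants measured in pooled liver microsomal and S9
# incubations. These are the single source of truth used by the default
# models, the bundled config files and the test suite.

.reference_kinetics <- list(
  chinese = data.frame(
    pathway = c("AP", "EE", "HE", "HA", "M5", "HEG", "OE", "HES"),
    km_uM = c(115, 161, 49, 450, 618, 4656, 403, 694),
    km_sem = c(24, 17, 8, 219, 164, 1247, 137, 321),
    vmax_invitro = c(0.15, 0.42, 0.35, 0.32, 0.18, 1.63, 1.82, 0.0014),
    vmax_sem = c(0.01, 0.01, 0.01, 0.07, 0.02, 0.33, 0.28, 0.0002),
    efficiency_printed = c(1.3, 2.6, 7.9, 0.71, 0.29, 0.35, 4.5, 0.002),
    stringsAsFactors = FALSE
  ),
  caucasian = data.frame(
    pathway = c("AP", "EE", "HE", "HA", "M5", "HEG", "OE", "HES"),
    km_uM = c(308, 146, 62, 429, 1451, 4607, 521, 423),
    km_sem = c(71, 15, 9, 80, 615, 878, 265, 159),
    vmax_invitro = c(0.74, 1.85, 1.19, 0.99, 1.18, 4.29, 2.8, 0.004),
    vmax_sem = c(0.07, 0.06, 0.04, 0.08, 0.34, 0.61, 0.70, 0.0005),
    efficiency_printed = c(2.4, 12.7, 19.3, 2.3, 0.82, 0.93, 5.4, 0.01),
    stringsAsFactors = FALSE
  )
)

# Scaled whole-liver constants as printed (rounded) in the source tables,
# kept for regeneration checks; the models themselves use unrounded values
# recomputed from the in vitro constants.
.reference_scaled_printed <- list(
  chinese = data.frame(
    pathway = c("AP", "EE", "HE", "HA", "M5", "HEG", "OE", "HES"),
    vmax_scaled = c(0.3, 0.9, 0.7, 0.7, 0.4, 3.4, 15.6, 0.01),
    efficiency_scaled = c(2.7, 5.5, 15.0, 1.5, 0.6, 0.7, 38.7, 0.02),
    stringsAsFactors = FALSE
  ),
  caucasian = data.frame(
    pathway = c("AP", "EE", "HE", "HA", "M5", "HEG", "OE", "HES"),
    vmax_scaled = c(1.6, 3.9, 2.5, 2.1, 2.5, 9.0, 24.0, 0.03),
    efficiency_scaled = c(5.0, 26.6, 40.3, 4.8, 1.7, 2.0, 46.1, 0.08),
    stringsAsFactors = FALSE
  )
)

.reference_physiology <- list(
  chinese = list(
    body_weight_kg = 60,
    tissue_fraction_pct = c(
      liver = 2.3, fat = 18.7, rapidly_perfused = 5.3,
      slowly_perfused = 54.3, blood = 7.9
    ),
    cardiac_output_constant = 15,
    flow_fraction_pct = c(
      liver = 26.3, fat = 6.75, rapidly_perfused = 43.8,
      slowly_perfused = 23.3
    )
  ),
  caucasian = list(
    body_weight_kg = 70,
    tissue_fraction_pct = c(
      liver = 2.6, fat = 21.4, rapidly_perfused = 5,
      slowly_perfused = 51.7, blood = 7.9
    ),
    cardiac_output_constant = 15,
    flow_fraction_pct = c(
      liver = 22.7, fat = 5.2, rapidly_perfused = 47.3,
      slowly_perfused = 24.8
    )
  )
)

.reference_partitions <- list(
  estragole = c(
    liver = 6.5, fat = 105, rapidly_perfused = 6.5, slowly_perfused = 4.1
  ),
  hydroxyestragole = c(liver = 1.6)
)

.check_population <- function(population) {
  population <- tolower(population)
  if (!population %in% c("chinese", "caucasian")) {
    stop("population must be 'chinese' or 'caucasian'", call. = FALSE)
  }
  population
}

#' Bundled in vitro kinetic constants
#'
#' Michaelis-Menten constants (mean +/- SEM) for the eight hepatic pathways,
#' as measured in pooled Chinese or Caucasian liver microsomal/S9
#' incubations, together with the catalytic efficiency as printed in the
#' source table. Note two printed-efficiency cells differ slightly from
#' `Vmax/Km x 1000` recomputed at the printed precision (Chinese `HE`: 7.9
#' printed vs 7.1 recomputed; Caucasian `HE`: 19.3 vs 19.2), presumably
#' because the original table used unrounded fit values; this package always
#' recomputes.
#'
#' @param population `"chinese"` or `"caucasian"`.
#' @return A data frame merged with [pathway_registry()]: one row per
#'   pathway with `km_uM`, `km_sem`, `vmax_invitro`, `vmax_sem`,
#'   `efficiency_printed`.
#' @export
reference_kinetics <- function(population) {
  population <- .check_population(population)
  out <- merge(.pathways, .reference_kinetics[[population]],
               by = "pathway", sort = FALSE)
  out[match(.pathways$pathway, out$pathway), , drop = FALSE]
}

#' Bundled scaled kinetic constants as printed
#'
#' The whole-liver scaled `Vmax` (umol/h/g liver) and scaled catalytic
#' efficiency (uL/h/g liver) at the rounding of the source table. Used to
#' check that [build_scaled_table()] regenerates the table from the in vitro
#' constants; the simulation itself uses unrounded values.
#'
#' @inheritParams reference_kinetics
#' @return A data frame with `pathway`, `vmax_scaled`, `efficiency_scaled`.
#' @export
reference_scaled_printed <- function(population) {
  .reference_scaled_printed[[.check_population(population)]]
}

#' Bundled population physiology
#'
#' Body weight, tissue volumes as percent of body weight, the cardiac output
#' allometric constant (L/h/kg bw^0.74) and tissue blood flows as percent of
#' cardiac output. The Chinese flow fractions sum to 100.15% as printed.
#'
#' @inheritParams reference_kinetics
#' @return A list with `body_weight_kg`, `tissue_fraction_pct`,
#'   `cardiac_output_constant`, `flow_fraction_pct`.
#' @export
reference_physiology <- function(population) {
  .reference_physiology[[.check_population(population)]]
}

#' Bundled tissue:blood partition coefficients
#'
#' @return A list with components `estragole` (liver, fat, rapidly and
#'   slowly perfused) and `hydroxyestragole` (liver only: the model keeps
#'   1'-hydroxyestragole disposition hepatic).
#' @export
reference_partitions <- function() .reference_partitions

#' Look up a single bundled reference value
#'
#' Convenience accessor over the bundled tables: kinetic constants per
#' pathway, physiology, or partition coefficients.
#'
#' @inheritParams reference_kinetics
#' @param what A pathway id (returns its kinetic constants), `"physiology"`,
#'   or `"partitions"`.
#' @return A one-row data frame or list, depending on `what`.
#' @examples
#' reference_values("chinese", "HE")$km_uM  # 49
#' @export
reference_values <- function(population, what) {
  population <- .check_population(population)
  if (identical(what, "physiology")) return(reference_physiology(population))
  if (identical(what, "partitions")) return(reference_partitions())
  .check_pathway(what)
  kin <- reference_kinetics(population)
  kin[kin$pathway == what, , drop = FALSE]
}
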