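# Seeded generator of synthetic incubation datasets. Emulates the design of
# the in vitro experiments behind the bundled constants: replicate
# incubations over a fixed substrate grid with multiplicative Gaussian
# noise (assay scatter scales with signal).

#' Default substrate concentration grids
#'
#' The estragole microsomal assays span 25-1000 uM; conjugation assays of
#' 1'-hydroxyestragole need the grid extended into the mM range so that the
#' glucuronidation Km (~4.7 mM) is spanned.
#'
#' @param parent `"estragole"` or `"hydroxyestragole"`.
#' @return Numeric vector of substrate concentrations, uM.
#' @export
default_concentration_grid <- function(parent = c("estragole",
                                                  "hydroxyestragole")) {
  parent <- match.arg(parent)
  if (parent == "estragole") c(25, 50, 100, 250, 500, 1000)
  else c(25, 50, 100, 250, 500, 1000, 2000, 4000, 8000)
}

#' Generate a synthetic in vitro incubation dataset
#'
#' Draws `n_replicates` rates per concentration as
#' `rate = mm_rate(Km, Vmax, S) x (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)` truncated below at -0.99 (rates stay
#' positive), then reduces to per-concentration means and SEMs, which is
#' what the fitter consumes. Bit-reproducible under a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param true_km_uM,true_vmax True kinetic constants.
#' @param concentrations Substrate grid, uM.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 gives rates exactly on the curve).
#' @param n_replicates Replicates per concentration (default 3, the assay
#'   design).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param pathway,protein_source Labels for the resulting dataset.
#' @return An [invitro_dataset()]; the replicate matrix is attached as
#'   attribute `"replicates"` (concentrations x replicates).
#' @export
generate_invitro_dataset <- function(true_km_uM, true_vmax,
                                     concentrations = default_concentration_grid(),
                                     noise_cv = 0.1, n_replicates = 3,
                                     seed = NULL,
                                     pathway = "HE",
                                     protein_source = "microsomes") {
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be at least 1", call. = FALSE)
  truth <- mm_rate(true_km_uM, true_vmax, concentrations)
  reps <- .with_seed(seed, {
    eps <- matrix(
      rnorm(length(concentrations) * n_replicates, 0, noise_cv),
      nrow = length(concentrations)
    )
    eps[eps < -0.99] <- -0.99
    truth * (1 + eps)
  })
  means <- rowMeans(reps)
  sems <- if (n_replicates > 1) {
    apply(reps, 1, sd) / sqrt(n_replicates)
  } else {
    rep(NA_real_, length(concentrations))
  }
  ds <- invitro_dataset(
    pathway = pathway, protein_source = protein_source,
    concentrations = concentrations, rates = means,
    rate_sems = if (all(is.na(sems))) NULL else sems,
    n_replicates = n_replicates
  )
  attr(ds, "replicates") <- reps
  attr(ds, "truth") <- c(km_uM = true_km_uM, vmax = true_vmax)
  ds
}

#' Generate synthetic datasets for all eight pathways of a population
#'
#' Uses the bundled kinetic constants as truths, the parent-appropriate
#' substrate grid, and one sub-seed per pathway derived from `seed`.
#'
#' @param population `"chinese"` or `"caucasian"`.
#' @param noise_cv,n_replicates As in [generate_invitro_dataset()].
#' @param seed Integer master seed.
#' @return Named list of [invitro_dataset()] objects, one per pathway.
#' @export
generate_population_datasets <- function(population, noise_cv = 0.1,
                                         n_replicates = 3, seed = 1) {
  kin <- reference_kinetics(population)
  out <- lapply(seq_len(nrow(kin)), function(i) {
    generate_invitro_dataset(
      true_km_uM = kin$km_uM[i], true_vmax = kin$vmax_invitro[i],
      concentrations = default_concentration_grid(kin$parent[i]),
      noise_cv = noise_cv, n_replicates = n_replicates,
      seed = if (is.null(seed)) NULL else seed + i,
      pathway = kin$pathway[i], protein_source = kin$protein_source[i]
    )
  })
  setNames(out, kin$pathway)
}
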