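#' Assemble a PBK model specification
#'
#' Builds the six-compartment flow-limited physiologically based kinetic
#' model for oral estragole: GI tract (first-order absorption straight into
#' the liver via the portal vein), liver, fat, rapidly perfused tissue,
#' slowly perfused tissue and blood, plus a hepatic 1'-hydroxyestragole
#' sub-model whose liver pool exchanges with blood and is cleared by
#' glucuronidation, oxidation and sulfation. All metabolism is hepatic and
#' saturable (Michaelis-Menten in the venous-equilibrium liver
#' concentration).
#'
#' The model stores the *in vitro* kinetic constants together with the
#' protein yields and physiology; scaled whole-liver rates, compartment
#' volumes and blood flows are re-derived at simulation time, so that any
#' scalar parameter (including the yields) can be perturbed for sensitivity
#' analysis with derived quantities following.
#'
#' @param population `"chinese"` or `"caucasian"` to use the bundled
#'   parameter set; or `NULL` to supply every piece explicitly.
#' @param physiology A list as [reference_physiology()] returns.
#' @param partitions A list as [reference_partitions()] returns.
#' @param kinetics A data frame of in vitro constants with columns
#'   `pathway`, `km_uM`, `vmax_invitro` covering the five estragole and
#'   three 1'-hydroxyestragole pathways exactly once.
#' @param yields Protein yields, mg/(g liver); see [protein_yields()].
#' @param ka_per_h First-order oral absorption rate constant, 1/h.
#' @param mw_estragole Molecular weight used for the mg to umol dose
#'   conversion, g/mol.
#' @param name Label used in printing and comparison tables.
#'
#' @return An object of class `pbk_model`.
#' @examples
#' mod <- pbk_model("chinese")
#' sim <- simulate_pbk(mod, dose_mg_per_kg = 0.01)
#' percent_of_dose(sim, "HE")
#' @export
pbk_model <- function(population = NULL,
                      physiology = NULL, partitions = NULL, kinetics = NULL,
                      yields = protein_yields(), ka_per_h = 1.0,
                      mw_estragole = 148.20, name = NULL) {
  if (!is.null(population)) {
    population <- .check_population(population)
    if (is.null(physiology)) physiology <- reference_physiology(population)
    if (is.null(partitions)) partitions <- reference_partitions()
    if (is.null(kinetics)) kinetics <- reference_kinetics(population)
    if (is.null(name)) name <- population
  }
  if (is.null(name)) name <- "custom"
  if (is.null(physiology) || is.null(partitions) || is.null(kinetics)) {
    stop("supply a population or physiology, partitions and kinetics",
         call. = FALSE)
  }
  kinetics <- as.data.frame(kinetics)[, c("pathway", "km_uM", "vmax_invitro")]
  model <- structure(
    list(
      name = name, physiology = physiology, partitions = partitions,
      kinetics = kinetics, yields = yields,
      ka_per_h = ka_per_h, mw_estragole = mw_estragole
    ),
    class = "pbk_model"
  )
  validate_pbk_model(model)
  model
}

#' Validate a PBK model specification
#'
#' Checks the structural invariants: exactly the five estragole and three
#' 1'-hydroxyestragole pathways present once each with positive `Km` and
#' non-negative `Vmax`; positive fractions; tissue fractions summing to at
#' most 100% of body weight; flow fractions summing to 100 +/- 0.5%;
#' positive partition coefficients, absorption rate and molecular weight.
#'
#' @param model A `pbk_model`.
#' @return `model`, invisibly; errors describe the first violated invariant.
#' @export
validate_pbk_model <- function(model) {
  stopifnot(inherits(model, "pbk_model"))
  ph <- model$physiology
  tiss <- c("liver", "fat", "rapidly_perfused", "slowly_perfused", "blood")
  flow <- c("liver", "fat", "rapidly_perfused", "slowly_perfused")
  if (!is.numeric(ph$body_weight_kg) || ph$body_weight_kg <= 0) {
    stop("body weight must be positive", call. = FALSE)
  }
  if (!all(tiss %in% names(ph$tissue_fraction_pct))) {
    stop("tissue_fraction_pct must name ", paste(tiss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(flow %in% names(ph$flow_fraction_pct))) {
    stop("flow_fraction_pct must name ", paste(flow, collapse = ", "),
         call. = FALSE)
  }
  if (any(ph$tissue_fraction_pct <= 0) || any(ph$flow_fraction_pct <= 0)) {
    stop("all physiology fractions must be positive", call. = FALSE)
  }
  if (sum(ph$tissue_fraction_pct[tiss]) > 100) {
    stop("tissue fractions exceed 100% of body weight", call. = FALSE)
  }
  fsum <- sum(ph$flow_fraction_pct[flow])
  if (abs(fsum - 100) > 0.5) {
    stop(sprintf("flow fractions sum to %.2f%%; expected 100 +/- 0.5", fsum),
         call. = FALSE)
  }
  if (!is.numeric(ph$cardiac_output_constant) || ph$cardiac_output_constant <= 0) {
    stop("cardiac_output_constant must be positive", call. = FALSE)
  }
  pa <- model$partitions
  if (any(unlist(pa) <= 0)) stop("partition coefficients must be positive", call. = FALSE)
  if (!"liver" %in% names(pa$hydroxyestragole)) {
    stop("a liver partition coefficient for 1'-hydroxyestragole is required",
         call. = FALSE)
  }
  kin <- model$kinetics
  expect_e <- .pathways$pathway[.pathways$parent == "estragole"]
  expect_h <- .pathways$pathway[.pathways$parent == "hydroxyestragole"]
  if (!setequal(kin$pathway, c(expect_e, expect_h)) ||
      anyDuplicated(kin$pathway)) {
    stop("kinetics must contain exactly the pathways ",
         paste(c(expect_e, expect_h), collapse = ", "), call. = FALSE)
  }
  if (any(kin$km_uM <= 0) || any(kin$vmax_invitro < 0)) {
    stop("kinetics need positive Km and non-negative Vmax", call. = FALSE)
  }
  if (model$ka_per_h < 0) stop("ka_per_h must be non-negative", call. = FALSE)
  if (model$mw_estragole <= 0) stop("mw_estragole must be positive", call. = FALSE)
  invisible(model)
}

#' @export
print.pbk_model <- function(x, ...) {
  ph <- x$physiology
  cat(sprintf("<pbk_model> %s: %g kg bw, Ka = %g /h\n",
              x$name, ph$body_weight_kg, x$ka_per_h))
  dv <- derive_flows_volumes(x)
  cat(sprintf("  liver %.3g L, cardiac output %.4g L/h (tissue flows sum %.4g L/h)\n",
              dv$volumes_L[["liver"]], dv$cardiac_output_L_per_h,
              dv$total_flow_L_per_h))
  cat("  scaled pathways (umol/h/g liver):\n")
  st <- scaled_pathways(x)
  cat(sprintf("    %-4s Km %8.4g uM  Vmax %8.4g  eff %8.4g uL/h/g\n",
              st$pathway, st$km_uM, st$vmax_scaled, st$efficiency_scaled),
      sep = "")
  invisible(x)
}

#' Scaled pathway table of a model
#'
#' @param model A `pbk_model`.
#' @return The [build_scaled_table()] of the model's in vitro kinetics under
#'   its protein yields.
#' @export
scaled_pathways <- function(model) {
  stopifnot(inherits(model, "pbk_model"))
  build_scaled_table(model$kinetics, model$yields)
}

#' Derive compartment volumes and blood flows
#'
#' Volumes are tissue fractions of body weight at density 1 kg/L; each
#' tissue blood flow is its flow fraction of the allometric cardiac output
#' `constant x BW^0.74`. The total flow used in the blood mass balance is
#' the sum of the tissue flows (the printed flow fractions do not sum to
#' exactly 100% for the Chinese set; using their sum conserves mass
#' exactly).
#'
#' @param x A `pbk_model` or a physiology list.
#' @return A list with `volumes_L`, `flows_L_per_h`,
#'   `cardiac_output_L_per_h`, `total_flow_L_per_h` and `liver_mass_g`.
#' @export
derive_flows_volumes <- function(x) {
  ph <- if (inherits(x, "pbk_model")) x$physiology else x
  bw <- ph$body_weight_kg
  vols <- ph$tissue_fraction_pct / 100 * bw
  qc <- ph$cardiac_output_constant * bw^0.74
  flows <- ph$flow_fraction_pct / 100 * qc
  list(
    volumes_L = vols,
    flows_L_per_h = flows,
    cardiac_output_L_per_h = qc,
    total_flow_L_per_h = sum(flows),
    liver_mass_g = vols[["liver"]] * 1000
  )
}

# State vector layout shared by the RHS, the simulator and the summaries.
.state_names <- c(
  "AGI_E", "AL_E", "AF_E", "AR_E", "AS_E", "AB_E", "AL_HE", "AB_HE",
  "AM_AP", "AM_EE", "AM_HE", "AM_HA", "AM_M5", "AM_HEG", "AM_OE", "AM_HES"
)

# Flatten a model into the numeric environment the RHS needs; done once per
# simulate() call.
.compile_pars <- function(model) {
  dv <- derive_flows_volumes(model)
  st <- scaled_pathways(model)
  vm <- setNames(st$vmax_scaled, st$pathway) * dv$liver_mass_g  # umol/h whole liver
  km <- setNames(st$km_uM, st$pathway)
  pa <- model$partitions
  list(
    ka = model$ka_per_h,
    VL = dv$volumes_L[["liver"]], VF = dv$volumes_L[["fat"]],
    VR = dv$volumes_L[["rapidly_perfused"]],
    VS = dv$volumes_L[["slowly_perfused"]], VB = dv$volumes_L[["blood"]],
    QL = dv$flows_L_per_h[["liver"]], QF = dv$flows_L_per_h[["fat"]],
    QR = dv$flows_L_per_h[["rapidly_perfused"]],
    QS = dv$flows_L_per_h[["slowly_perfused"]],
    QT = dv$total_flow_L_per_h,
    PL = pa$estragole[["liver"]], PF = pa$estragole[["fat"]],
    PR = pa$estragole[["rapidly_perfused"]],
    PS = pa$estragole[["slowly_perfused"]],
    PLHE = pa$hydroxyestragole[["liver"]],
    vm = vm, km = km,
    liver_mass_g = dv$liver_mass_g
  )
}

.pbk_rhs <- function(t, y, p) {
  ca <- y[[6]] / p$VB                 # arterial estragole, uM
  cvl <- y[[2]] / p$VL / p$PL         # venous-equilibrium liver estragole
  cvf <- y[[3]] / p$VF / p$PF
  cvr <- y[[4]] / p$VR / p$PR
  cvs <- y[[5]] / p$VS / p$PS
  v <- p$vm * cvl / (p$km + cvl)      # all 8 pathways; HE-substrate ones fixed below
  cahe <- y[[8]] / p$VB
  cvlhe <- y[[7]] / p$VL / p$PLHE
  v[["HEG"]] <- p$vm[["HEG"]] * cvlhe / (p$km[["HEG"]] + cvlhe)
  v[["OE"]] <- p$vm[["OE"]] * cvlhe / (p$km[["OE"]] + cvlhe)
  v[["HES"]] <- p$vm[["HES"]] * cvlhe / (p$km[["HES"]] + cvlhe)
  uptake <- p$ka * y[[1]]
  list(c(
    -uptake,
    uptake + p$QL * (ca - cvl) -
      v[["AP"]] - v[["EE"]] - v[["HE"]] - v[["HA"]] - v[["M5"]],
    p$QF * (ca - cvf),
    p$QR * (ca - cvr),
    p$QS * (ca - cvs),
    p$QL * cvl + p$QF * cvf + p$QR * cvr + p$QS * cvs - p$QT * ca,
    v[["HE"]] + p$QL * (cahe - cvlhe) - v[["HEG"]] - v[["OE"]] - v[["HES"]],
    p$QL * (cvlhe - cahe),
    v[["AP"]], v[["EE"]], v[["HE"]], v[["HA"]], v[["M5"]],
    v[["HEG"]], v[["OE"]], v[["HES"]]
  ))
}

#' Evaluate the model's time derivatives at a state
#'
#' The mass-balance right-hand side: first-order GI absorption into the
#' liver, flow-limited exchange of estragole between blood and the liver,
#' fat, rapidly and slowly perfused compartments, the five saturable
#' hepatic estragole conversions driven by the venous-equilibrium
#' concentration `CL_E/PL_E`, the hepatic 1'-hydroxyestragole balance
#' (formation, blood exchange, and its three saturable conversions), and
#' cumulative formation trackers equal to the pathway rates.
#'
#' Exposed mainly for inspection and testing; [simulate_pbk()] integrates
#' it.
#'
#' @param state Named numeric vector over the states `AGI_E`, `AL_E`,
#'   `AF_E`, `AR_E`, `AS_E`, `AB_E`, `AL_HE`, `AB_HE` and the cumulative
#'   trackers `AM_AP`, `AM_EE`, `AM_HE`, `AM_HA`, `AM_M5`, `AM_HEG`,
#'   `AM_OE`, `AM_HES` (amounts, umol). Missing entries default to 0.
#' @param model A `pbk_model`.
#' @return Named numeric vector of time derivatives, umol/h.
#' @export
pbk_derivatives <- function(state, model) {
  stopifnot(inherits(model, "pbk_model"))
  y <- setNames(numeric(length(.state_names)), .state_names)
  if (is.null(names(state))) {
    if (length(state) != length(y)) {
      stop("unnamed state must have length ", length(y), call. = FALSE)
    }
    y[] <- state
  } else {
    bad <- setdiff(names(state), .state_names)
    if (length(bad)) stop("unknown state entries: ", paste(bad, collapse = ", "), call. = FALSE)
    y[names(state)] <- state
  }
  if (any(y < 0)) stop("state amounts must be non-negative", call. = FALSE)
  setNames(.pbk_rhs(0, y, .compile_pars(model))[[1]], .state_names)
}

#' Simulate an oral bolus dose
#'
#' Integrates the model with a stiff solver for `duration_h` hours after a
#' single oral bolus. The dose enters as
#' `AGI_E(0) = dose_mg_per_kg x BW / MW x 1000` umol with all other states
#' zero.
#'
#' @param model A `pbk_model`.
#' @param dose_mg_per_kg Oral dose, mg/kg bw (0 gives an all-zero result).
#' @param duration_h Simulated time span, h.
#' @param dt_h Output grid resolution, h. The default 0.01 h keeps the
#'   liver-concentration maximum and AUC accurate; coarser grids do not
#'   affect solver accuracy, only the stored trajectory.
#' @param rtol,atol Solver relative/absolute tolerances (atol in umol).
#' @param method A [deSolve::ode()] stiff-capable method.
#'
#' @return An object of class `pbk_simulation`: list with `time` (h),
#'   `states` (matrix, umol), `dose_umol`, `dose_mg_per_kg`, `model`, and
#'   `summary`, a data frame per metabolite of cumulative umol, percent of
#'   dose and nmol/(g liver), plus `he_liver_cmax_uM` and
#'   `he_liver_auc_uM_h` for the liver 1'-hydroxyestragole concentration.
#' @export
simulate_pbk <- function(model, dose_mg_per_kg, duration_h = 24,
                         dt_h = 0.01, rtol = 1e-8, atol = 1e-12,
                         method = "lsoda") {
  stopifnot(inherits(model, "pbk_model"))
  if (!is.numeric(dose_mg_per_kg) || length(dose_mg_per_kg) != 1 ||
      !is.finite(dose_mg_per_kg) || dose_mg_per_kg < 0) {
    stop("dose_mg_per_kg must be a single non-negative number", call. = FALSE)
  }
  p <- .compile_pars(model)
  dose_umol <- dose_mg_per_kg * model$physiology$body_weight_kg /
    model$mw_estragole * 1000
  y0 <- setNames(numeric(length(.state_names)), .state_names)
  y0[["AGI_E"]] <- dose_umol
  times <- seq(0, duration_h, by = dt_h)
  if (times[length(times)] < duration_h) times <- c(times, duration_h)
  out <- deSolve::ode(
    y = y0, times = times, func = .pbk_rhs, parms = p,
    method = method, rtol = rtol, atol = atol
  )
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate ", attr(out, "istate")[1], "); ",
         "see deSolve diagnostics", call. = FALSE)
  }
  states <- out[, .state_names, drop = FALSE]
  res <- structure(
    list(
      time = out[, "time"], states = states,
      dose_umol = dose_umol, dose_mg_per_kg = dose_mg_per_kg,
      duration_h = duration_h, model = model,
      liver_mass_g = p$liver_mass_g, liver_volume_L = p$VL,
      he_partition = p$PLHE
    ),
    class = "pbk_simulation"
  )
  res$summary <- .summarize_simulation(res)
  res
}

.summarize_simulation <- function(res) {
  final <- res$states[nrow(res$states), ]
  mets <- .pathways$pathway
  cum <- final[paste0("AM_", mets)]
  pct <- if (res$dose_umol > 0) cum / res$dose_umol * 100 else cum * 0
  cl_he <- res$states[, "AL_HE"] / res$liver_volume_L  # uM in liver tissue
  auc <- sum(diff(res$time) * (cl_he[-1] + cl_he[-length(cl_he)]) / 2)
  structure(
    data.frame(
      pathway = mets,
      metabolite = .pathways$metabolite,
      cumulative_umol = unname(cum),
      percent_of_dose = unname(pct),
      nmol_per_g_liver = unname(cum) * 1000 / res$liver_mass_g,
      stringsAsFactors = FALSE
    ),
    he_liver_cmax_uM = max(cl_he),
    he_liver_auc_uM_h = auc
  )
}

#' @export
print.pbk_simulation <- function(x, ...) {
  cat(sprintf(
    "<pbk_simulation> %s, %g mg/kg bw oral, %g h (dose %.4g umol)\n",
    x$model$name, x$dose_mg_per_kg, x$duration_h, x$dose_umol
  ))
  s <- x$summary
  cat(sprintf("  %-4s %12.5g umol %10.4g %% of dose %12.5g nmol/g liver\n",
              s$pathway, s$cumulative_umol, s$percent_of_dose,
              s$nmol_per_g_liver), sep = "")
  cat(sprintf("  liver 1'-hydroxyestragole: Cmax %.4g uM, AUC(0-%g h) %.4g uM h\n",
              attr(s, "he_liver_cmax_uM"), x$duration_h,
              attr(s, "he_liver_auc_uM_h")))
  invisible(x)
}

.lookup_metabolite <- function(result, metabolite) {
  s <- result$summary
  i <- match(metabolite, s$pathway)
  if (is.na(i)) {
    stop("metabolite '", metabolite, "' not tracked; available: ",
         paste(s$pathway, collapse = ", "), call. = FALSE)
  }
  s[i, ]
}

#' Cumulative metabolite formation as percent of dose
#'
#' @param result A `pbk_simulation`.
#' @param metabolite A pathway id (`"HE"`, `"HES"`, ...).
#' @return Percent of the administered dose (0 for a zero dose).
#' @export
percent_of_dose <- function(result, metabolite) {
  stopifnot(inherits(result, "pbk_simulation"))
  .lookup_metabolite(result, metabolite)$percent_of_dose
}

#' Cumulative metabolite formation per gram of liver
#'
#' @inheritParams percent_of_dose
#' @return nmol formed per gram of liver over the simulated period.
#' @export
amount_per_g_liver <- function(result, metabolite) {
  stopifnot(inherits(result, "pbk_simulation"))
  .lookup_metabolite(result, metabolite)$nmol_per_g_liver
}

#' Cumulative metabolite formation in umol
#'
#' @inheritParams percent_of_dose
#' @return Cumulative amount formed, umol.
#' @export
cumulative_amount <- function(result, metabolite) {
  stopifnot(inherits(result, "pbk_simulation"))
  .lookup_metabolite(result, metabolite)$cumulative_umol
}

#' Worst-case relative mass-balance error of a simulation
#'
#' Total mass at each output time is the GI amount plus all estragole
#' compartment amounts, the four terminal estragole metabolites, and the
#' 1'-hydroxyestragole branch (its liver and blood pools plus its three
#' products). For a conservative model this equals the dose to within
#' solver tolerance at every time.
#'
#' @param result A `pbk_simulation`.
#' @return Maximum over time of `|total - dose| / dose` (0 for a zero
#'   dose).
#' @export
mass_balance_error <- function(result) {
  stopifnot(inherits(result, "pbk_simulation"))
  if (result$dose_umol == 0) return(0)
  pools <- c("AGI_E", "AL_E", "AF_E", "AR_E", "AS_E", "AB_E",
             "AM_AP", "AM_EE", "AM_HA", "AM_M5",
             "AL_HE", "AB_HE", "AM_HEG", "AM_OE", "AM_HES")
  total <- rowSums(result$states[, pools, drop = FALSE])
  max(abs(total - result$dose_umol)) / result$dose_umol
}
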