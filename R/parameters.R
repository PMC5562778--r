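# Flat, dot-separated addressing of every scalar parameter of a pbk_model,
# used by the sensitivity sweep. Derived quantities (volumes, flows, scaled
# Vmax) are not addressable: they are recomputed from the perturbed scalars
# at simulation time.

#' Names of all scalar model parameters
#'
#' The perturbable parameter universe: body weight, the cardiac-output
#' constant, tissue and flow fractions, partition coefficients, protein
#' yields, the absorption rate constant, and every pathway's `Km` and in
#' vitro `Vmax`.
#'
#' @param model A `pbk_model`.
#' @return Character vector of dot-separated parameter paths, e.g.
#'   `"tissue_fraction.liver"`, `"partition.estragole.fat"`, `"vmax.HES"`.
#' @export
pbk_parameter_names <- function(model) {
  stopifnot(inherits(model, "pbk_model"))
  ph <- model$physiology
  c(
    "body_weight", "cardiac_output_constant",
    paste0("tissue_fraction.", names(ph$tissue_fraction_pct)),
    paste0("flow_fraction.", names(ph$flow_fraction_pct)),
    paste0("partition.estragole.", names(model$partitions$estragole)),
    paste0("partition.hydroxyestragole.",
           names(model$partitions$hydroxyestragole)),
    paste0("yield.", names(model$yields)),
    "ka",
    paste0("km.", model$kinetics$pathway),
    paste0("vmax.", model$kinetics$pathway)
  )
}

.split_path <- function(parameter) strsplit(parameter, ".", fixed = TRUE)[[1]]

#' Read a scalar model parameter by path
#'
#' @param model A `pbk_model`.
#' @param parameter A path from [pbk_parameter_names()].
#' @return The parameter's numeric value.
#' @export
pbk_get_parameter <- function(model, parameter) {
  stopifnot(inherits(model, "pbk_model"))
  p <- .split_path(parameter)
  out <- switch(p[1],
    body_weight = model$physiology$body_weight_kg,
    cardiac_output_constant = model$physiology$cardiac_output_constant,
    tissue_fraction = model$physiology$tissue_fraction_pct[[p[2]]],
    flow_fraction = model$physiology$flow_fraction_pct[[p[2]]],
    partition = model$partitions[[p[2]]][[p[3]]],
    yield = model$yields[[p[2]]],
    ka = model$ka_per_h,
    km = model$kinetics$km_uM[match(p[2], model$kinetics$pathway)],
    vmax = model$kinetics$vmax_invitro[match(p[2], model$kinetics$pathway)],
    stop("unknown parameter path: ", parameter, call. = FALSE)
  )
  if (length(out) != 1 || is.na(out)) {
    stop("unknown parameter path: ", parameter, call. = FALSE)
  }
  out
}

#' Set a scalar model parameter by path
#'
#' @inheritParams pbk_get_parameter
#' @param value New numeric value.
#' @return A modified copy of the model (revalidated only for structural
#'   errors that would break simulation; sensitivity perturbations of a few
#'   percent keep all invariants).
#' @export
pbk_set_parameter <- function(model, parameter, value) {
  pbk_get_parameter(model, parameter)  # path check
  p <- .split_path(parameter)
  value <- as.numeric(value)
  switch(p[1],
    body_weight = model$physiology$body_weight_kg <- value,
    cardiac_output_constant = model$physiology$cardiac_output_constant <- value,
    tissue_fraction = model$physiology$tissue_fraction_pct[[p[2]]] <- value,
    flow_fraction = model$physiology$flow_fraction_pct[[p[2]]] <- value,
    partition = model$partitions[[p[2]]][[p[3]]] <- value,
    yield = model$yields[[p[2]]] <- value,
    ka = model$ka_per_h <- value,
    km = model$kinetics$km_uM[match(p[2], model$kinetics$pathway)] <- value,
    vmax = model$kinetics$vmax_invitro[match(p[2], model$kinetics$pathway)] <- value
  )
  model
}
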