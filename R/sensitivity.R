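# Normalized local sensitivity by finite perturbation:
#   SC = (C' - C) / (P' - P) x (P / C)
# with a one-sided +5% perturbation of one parameter at a time, all others
# held at baseline. SC is dimensionless and invariant to the units of the
# perturbed parameter.

#' Normalized sensitivity coefficient of an arbitrary scalar function
#'
#' Low-level building block: perturbs one entry of a named parameter list
#' and evaluates `SC = (C' - C)/(P' - P) x (P/C)`.
#'
#' @param fun Function taking the parameter list and returning a scalar
#'   output `C`.
#' @param params Named list (or vector) of numeric parameters.
#' @param parameter Name of the entry to perturb. Its baseline value must be
#'   non-zero.
#' @param delta Relative perturbation size (default 0.05, i.e. +5%).
#' @param side `"forward"` (one-sided, the default) or `"central"`.
#' @return The dimensionless sensitivity coefficient.
#' @examples
#' # one-compartment linear clearance: AUC = D/CL, so SC of CL is exactly -1
#' finite_sc(function(p) p$dose / p$cl, list(dose = 1, cl = 2), "cl")
#' @export
finite_sc <- function(fun, params, parameter, delta = 0.05,
                      side = c("forward", "central")) {
  side <- match.arg(side)
  p0 <- params[[parameter]]
  if (is.null(p0) || !is.finite(p0) || p0 == 0) {
    stop("parameter '", parameter, "' must exist and be non-zero", call. = FALSE)
  }
  set <- function(val) {
    params[[parameter]] <- val
    params
  }
  c0 <- fun(params)
  if (!is.finite(c0) || c0 == 0) {
    stop("baseline output is zero or non-finite; SC undefined", call. = FALSE)
  }
  if (side == "forward") {
    p1 <- p0 * (1 + delta)
    (fun(set(p1)) - c0) / (p1 - p0) * (p0 / c0)
  } else {
    ph <- p0 * (1 + delta)
    pl <- p0 * (1 - delta)
    (fun(set(ph)) - fun(set(pl))) / (ph - pl) * (p0 / c0)
  }
}

.sens_output <- function(model, dose, output, dt_h) {
  sim <- simulate_pbk(model, dose, dt_h = dt_h)
  cumulative_amount(sim, output)
}

#' Sensitivity coefficient of a PBK model output to one parameter
#'
#' Perturbs a single scalar parameter (see [pbk_parameter_names()]),
#' re-derives all dependent quantities (volumes, flows, scaled rates),
#' re-simulates, and evaluates the normalized coefficient on the 24-h
#' cumulative amount of the chosen metabolite.
#'
#' @param model A `pbk_model`.
#' @param parameter Parameter path, e.g. `"vmax.HE"`.
#' @param output Metabolite whose 24-h cumulative formation is the model
#'   output, e.g. `"HE"` or `"HES"`.
#' @param dose Oral dose, mg/kg bw.
#' @param delta Relative perturbation (default +5%).
#' @param side `"forward"` or `"central"`.
#' @param dt_h Output grid used for the underlying simulations (the final
#'   cumulative amount does not depend on it).
#' @return The dimensionless sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(model, parameter, output, dose,
                                    delta = 0.05,
                                    side = c("forward", "central"),
                                    dt_h = 0.5) {
  stopifnot(inherits(model, "pbk_model"))
  side <- match.arg(side)
  p0 <- pbk_get_parameter(model, parameter)
  if (p0 == 0) stop("parameter '", parameter, "' is zero; SC undefined", call. = FALSE)
  c0 <- .sens_output(model, dose, output, dt_h)
  if (c0 == 0) stop("baseline output is zero; SC undefined", call. = FALSE)
  eval_at <- function(val) {
    .sens_output(pbk_set_parameter(model, parameter, val), dose, output, dt_h)
  }
  if (side == "forward") {
    p1 <- p0 * (1 + delta)
    (eval_at(p1) - c0) / (p1 - p0) * (p0 / c0)
  } else {
    ph <- p0 * (1 + delta)
    pl <- p0 * (1 - delta)
    (eval_at(ph) - eval_at(pl)) / (ph - pl) * (p0 / c0)
  }
}

#' Full sensitivity sweep over parameters, outputs and doses
#'
#' Computes the normalized sensitivity coefficient of every scalar model
#' parameter for each output metabolite at each dose, and filters to the
#' reporting threshold `|SC| >= threshold` (default 0.1) while retaining
#' the unfiltered table.
#'
#' @param model A `pbk_model`.
#' @param doses Doses, mg/kg bw.
#' @param outputs Metabolites used as outputs (24-h cumulative amounts).
#' @param delta,side,dt_h Passed to [sensitivity_coefficient()].
#' @param threshold Reporting threshold on `|SC|`; must be positive.
#' @param parameters Parameter paths to sweep; defaults to all of
#'   [pbk_parameter_names()].
#' @return An object of class `sensitivity_report`: list with `all` (data
#'   frame parameter/output/dose/sc) and `influential` (rows with
#'   `|sc| >= threshold`).
#' @export
sensitivity_sweep <- function(model, doses = c(0.01, 5, 150),
                              outputs = c("HE", "HES"),
                              delta = 0.05, side = "forward",
                              threshold = 0.1, dt_h = 0.5,
                              parameters = pbk_parameter_names(model)) {
  stopifnot(inherits(model, "pbk_model"), threshold > 0)
  rows <- list()
  for (dose in doses) {
    base <- simulate_pbk(model, dose, dt_h = dt_h)
    c0 <- vapply(outputs, function(o) cumulative_amount(base, o), numeric(1))
    for (par in parameters) {
      p0 <- pbk_get_parameter(model, par)
      p1 <- p0 * (1 + delta)
      pert <- simulate_pbk(pbk_set_parameter(model, par, p1), dose, dt_h = dt_h)
      c1 <- vapply(outputs, function(o) cumulative_amount(pert, o), numeric(1))
      sc <- (c1 - c0) / (p1 - p0) * (p0 / c0)
      if (side == "central") {
        pl <- p0 * (1 - delta)
        pertl <- simulate_pbk(pbk_set_parameter(model, par, pl), dose, dt_h = dt_h)
        cl <- vapply(outputs, function(o) cumulative_amount(pertl, o), numeric(1))
        sc <- (c1 - cl) / (p1 - pl) * (p0 / c0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, output = outputs, dose = dose, sc = unname(sc),
        stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  structure(
    list(
      all = all,
      influential = all[abs(all$sc) >= threshold, , drop = FALSE],
      threshold = threshold, delta = delta, side = side,
      model = model$name
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> %s: %d coefficients, %d with |SC| >= %g (+%g%% %s)\n",
    x$model, nrow(x$all), nrow(x$influential), x$threshold, x$delta * 100,
    x$side
  ))
  if (nrow(x$influential)) {
    inf <- x$influential
    inf <- inf[order(inf$dose, inf$output, -abs(inf$sc)), ]
    print(inf, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
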