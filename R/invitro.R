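#' In vitro incubation dataset
#'
#' Container for one concentration-rate series from a liver microsomal or S9
#' incubation: substrate concentration versus mean metabolite formation rate,
#' optionally with per-concentration standard errors over replicates.
#'
#' @param pathway Pathway id, one of [pathway_registry()]`$pathway`.
#' @param protein_source `"microsomes"` or `"S9"`.
#' @param concentrations Substrate concentrations, uM. Strictly positive;
#'   stored sorted increasing.
#' @param rates Mean formation rates, nmol/min/(mg protein). Non-negative,
#'   same length as `concentrations`.
#' @param rate_sems Optional standard errors of the mean rates, same units.
#' @param n_replicates Number of replicate incubations behind each mean.
#'
#' @return An object of class `invitro_dataset`.
#' @seealso [fit_michaelis_menten()], [generate_invitro_dataset()]
#' @export
invitro_dataset <- function(pathway, protein_source, concentrations, rates,
                            rate_sems = NULL, n_replicates = NA_integer_) {
  .check_pathway(pathway)
  .check_protein_source(protein_source)
  concentrations <- as.numeric(concentrations)
  rates <- as.numeric(rates)
  if (length(concentrations) != length(rates)) {
    stop("concentrations and rates must have the same length", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative", call. = FALSE)
  }
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  if (anyDuplicated(concentrations)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  rates <- rates[ord]
  if (!is.null(rate_sems)) {
    rate_sems <- as.numeric(rate_sems)
    if (length(rate_sems) != length(rates)) {
      stop("rate_sems must match rates in length", call. = FALSE)
    }
    rate_sems <- rate_sems[ord]
  }
  structure(
    list(
      pathway = pathway, protein_source = protein_source,
      concentrations = concentrations, rates = rates,
      rate_sems = rate_sems, n_replicates = as.integer(n_replicates)
    ),
    class = "invitro_dataset"
  )
}

#' @export
print.invitro_dataset <- function(x, ...) {
  cat(sprintf(
    "<invitro_dataset> pathway %s (%s), %d concentrations %g-%g uM\n",
    x$pathway, x$protein_source, length(x$concentrations),
    min(x$concentrations), max(x$concentrations)
  ))
  df <- data.frame(concentration_uM = x$concentrations, rate = x$rates)
  if (!is.null(x$rate_sems)) df$sem <- x$rate_sems
  print(df, row.names = FALSE)
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' Saturable formation rate `v = Vmax * S / (Km + S)`: zero at `S = 0`,
#' half-maximal at `S = Km`, approaching `Vmax` as `S` grows.
#'
#' @param km_uM Michaelis constant, uM. Must be positive.
#' @param vmax Maximum rate (any unit; the result is in the same unit).
#' @param substrate_uM Substrate concentration(s), uM, non-negative.
#'   Vectorized.
#'
#' @return Formation rate(s) in the units of `vmax`.
#' @examples
#' mm_rate(49, 0.35, 49)  # half-saturation: Vmax/2
#' @export
mm_rate <- function(km_uM, vmax, substrate_uM) {
  if (any(!is.finite(km_uM)) || any(km_uM <= 0)) {
    stop("km_uM must be positive", call. = FALSE)
  }
  if (any(substrate_uM < 0)) {
    stop("substrate_uM must be non-negative", call. = FALSE)
  }
  vmax * substrate_uM / (km_uM + substrate_uM)
}

#' Fit Michaelis-Menten constants to an incubation dataset
#'
#' Unweighted least-squares fit of (`Km`, `Vmax`) to the mean rates of an
#' [invitro_dataset()], with non-negativity bounds and a multistart over
#' initial `Km` guesses (`0.1x`, `1x`, `10x` the interpolated
#' half-maximum concentration) to avoid local minima. Replicate SEMs are
#' carried along but not used in the loss. Reported uncertainties are the
#' asymptotic standard errors of the nonlinear regression.
#'
#' A dataset whose rates are all zero is degenerate: `Vmax` is 0 and `Km`
#' unidentifiable; the returned fit is flagged in `$diagnostics`.
#'
#' @param dataset An [invitro_dataset()].
#'
#' @return An object of class `mm_fit` with elements `pathway`,
#'   `protein_source`, `km_uM`, `vmax_invitro`, `km_sem`, `vmax_sem`, `sse`
#'   and `diagnostics` (start points tried, convergence flags).
#' @export
fit_michaelis_menten <- function(dataset) {
  stopifnot(inherits(dataset, "invitro_dataset"))
  s <- dataset$concentrations
  v <- dataset$rates
  if (length(s) < 2) {
    stop("need at least as many concentrations as parameters (2)",
         call. = FALSE)
  }
  if (length(s) < 4 || max(s) / min(s) < 10) {
    warning("fewer than 4 concentrations or less than a 10-fold range; ",
            "Km and Vmax may be poorly identified", call. = FALSE)
  }
  if (all(v == 0)) {
    return(.mm_fit(dataset, km = NA_real_, vmax = 0,
                   km_sem = NA_real_, vmax_sem = NA_real_, sse = 0,
                   diagnostics = list(degenerate = "all rates zero; Km unidentifiable")))
  }

  vmax0 <- max(v)
  # interpolated concentration at half-maximal rate as the Km seed
  km0 <- tryCatch(
    approx(v, s, xout = vmax0 / 2, ties = "ordered")$y,
    error = function(e) NA_real_
  )
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s)

  fits <- list()
  for (mult in c(0.1, 1, 10)) {
    fits[[length(fits) + 1L]] <- tryCatch(
      minpack.lm::nlsLM(
        v ~ vmax * s / (km + s),
        data = data.frame(s = s, v = v),
        start = list(km = km0 * mult, vmax = vmax0),
        lower = c(km = 1e-9, vmax = 0),
        upper = c(km = 1e7, vmax = 1e3),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-10, ptol = 1e-12
        )
      ),
      error = function(e) e
    )
  }
  ok <- vapply(fits, function(f) inherits(f, "nls"), logical(1))
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    stop("Michaelis-Menten fit failed to converge from all start points: ",
         paste(unique(msgs), collapse = "; "), call. = FALSE)
  }
  sses <- vapply(fits[ok], function(f) sum(residuals(f)^2), numeric(1))
  best <- fits[ok][[which.min(sses)]]
  est <- coef(best)
  ses <- tryCatch(sqrt(diag(vcov(best))), error = function(e) c(km = NA, vmax = NA))
  .mm_fit(
    dataset,
    km = unname(est["km"]), vmax = unname(est["vmax"]),
    km_sem = unname(ses["km"]), vmax_sem = unname(ses["vmax"]),
    sse = min(sses),
    diagnostics = list(
      km_start = km0 * c(0.1, 1, 10), vmax_start = vmax0,
      converged = ok, sse_by_start = sses
    )
  )
}

.mm_fit <- function(dataset, km, vmax, km_sem, vmax_sem, sse, diagnostics) {
  structure(
    list(
      pathway = dataset$pathway, protein_source = dataset$protein_source,
      km_uM = km, vmax_invitro = vmax,
      km_sem = km_sem, vmax_sem = vmax_sem,
      sse = sse, diagnostics = diagnostics, data = dataset
    ),
    class = "mm_fit"
  )
}

#' Construct a Michaelis-Menten parameter set directly
#'
#' For kinetic constants taken from the literature rather than fitted.
#'
#' @inheritParams invitro_dataset
#' @param km_uM,vmax_invitro Kinetic constants (uM; nmol/min/mg protein).
#' @param km_sem,vmax_sem Optional standard errors.
#' @return An `mm_fit` object.
#' @export
mm_kinetics <- function(pathway, protein_source, km_uM, vmax_invitro,
                        km_sem = NA_real_, vmax_sem = NA_real_) {
  .check_pathway(pathway)
  .check_protein_source(protein_source)
  if (!is.finite(km_uM) || km_uM <= 0) stop("km_uM must be positive", call. = FALSE)
  if (!is.finite(vmax_invitro) || vmax_invitro < 0) {
    stop("vmax_invitro must be non-negative", call. = FALSE)
  }
  structure(
    list(
      pathway = pathway, protein_source = protein_source,
      km_uM = km_uM, vmax_invitro = vmax_invitro,
      km_sem = km_sem, vmax_sem = vmax_sem,
      sse = NA_real_, diagnostics = list(source = "supplied"), data = NULL
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s (%s)\n", x$pathway, x$protein_source))
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$km_uM, x$km_sem))
  cat(sprintf("  Vmax = %.4g +/- %.3g nmol/min/mg\n",
              x$vmax_invitro, x$vmax_sem))
  if (is.finite(x$km_uM)) {
    cat(sprintf("  catalytic efficiency = %.3g uL/min/mg\n",
                catalytic_efficiency(x)))
  }
  if (!is.null(x$diagnostics$degenerate)) {
    cat("  [degenerate fit: ", x$diagnostics$degenerate, "]\n", sep = "")
  }
  invisible(x)
}

#' In vitro catalytic efficiency
#'
#' `Vmax/Km x 1000`, in uL/min/(mg protein): the apparent first-order rate
#' constant of the pathway in the low-substrate limit, the quantity on which
#' the inter-ethnic comparisons of the individual conversions are based.
#'
#' @param x An `mm_fit`, or a numeric `Km` (uM) with `vmax` supplied.
#' @param vmax Maximum rate, nmol/min/(mg protein); ignored when `x` is an
#'   `mm_fit`.
#' @return Efficiency in uL/min/(mg protein).
#' @examples
#' catalytic_efficiency(115, 0.15)  # 1.3
#' @export
catalytic_efficiency <- function(x, vmax = NULL) {
  if (inherits(x, "mm_fit")) {
    km <- x$km_uM
    vmax <- x$vmax_invitro
  } else {
    km <- x
    if (is.null(vmax)) stop("vmax required when x is numeric", call. = FALSE)
  }
  if (any(!is.finite(km)) || any(km <= 0)) stop("Km must be positive", call. = FALSE)
  vmax / km * 1000
}

#' Fold-difference between two positive values
#'
#' Ratio of the larger to the smaller value with a flag saying which side is
#' lower, as used to compare catalytic efficiencies or metabolite formation
#' between populations.
#'
#' @param reference,other Positive scalars (e.g. catalytic efficiencies), or
#'   `mm_fit` objects (compared on catalytic efficiency).
#' @param labels Length-2 character labels used in the direction flag.
#' @return A list of class `fold_difference` with elements `fold` (>= 1) and
#'   `lower` (label of the smaller value, or `"neither"` on a tie).
#' @examples
#' fold_difference(12.7, 2.6)  # 4.9-fold, other lower
#' @export
fold_difference <- function(reference, other,
                            labels = c("reference", "other")) {
  val <- function(x) if (inherits(x, "mm_fit")) catalytic_efficiency(x) else as.numeric(x)
  a <- val(reference)
  b <- val(other)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("fold_difference needs two positive finite values", call. = FALSE)
  }
  structure(
    list(
      fold = max(a, b) / min(a, b),
      lower = if (a == b) "neither" else labels[[which.min(c(a, b))]],
      values = setNames(c(a, b), labels)
    ),
    class = "fold_difference"
  )
}

#' @export
print.fold_difference <- function(x, ...) {
  cat(sprintf("%.3g-fold difference (%s lower)\n", x$fold, x$lower))
  invisible(x)
}
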