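# In vitro to in vivo extrapolation: conversion of incubation Vmax values,
# nmol/min/(mg microsomal or S9 protein), to whole-liver rates in
# umol/h/(g liver) through the tissue-fraction protein yields.

#' Default liver protein yields
#'
#' Microsomal and S9 protein recovered per gram of liver, mg/g. The same
#' (Caucasian-derived) yields are applied to both populations because no
#' Chinese-specific yields are available.
#'
#' @return Named numeric vector `c(microsomes = 35, S9 = 143)`.
#' @export
protein_yields <- function() c(microsomes = 35, S9 = 143)

#' Scale an in vitro Vmax to whole liver
#'
#' `vmax_scaled = vmax_invitro x yield x 60 / 1000`, converting
#' nmol/min/(mg protein) to umol/h/(g liver). The scaling is linear in
#' `vmax_invitro`.
#'
#' @param vmax_invitro Maximum rate, nmol/min/(mg protein). Non-negative;
#'   vectorized.
#' @param protein_source `"microsomes"` or `"S9"` (recycled along
#'   `vmax_invitro`).
#' @param yields Protein yields in mg/(g liver); see [protein_yields()].
#' @return Scaled Vmax, umol/h/(g liver).
#' @examples
#' scale_vmax(1.82, "S9")          # 15.6
#' scale_vmax(0.35, "microsomes")  # 0.735
#' @export
scale_vmax <- function(vmax_invitro, protein_source, yields = protein_yields()) {
  if (any(!is.finite(vmax_invitro)) || any(vmax_invitro < 0)) {
    stop("vmax_invitro must be non-negative", call. = FALSE)
  }
  if (!all(protein_source %in% c("microsomes", "S9"))) {
    stop("protein_source must be 'microsomes' or 'S9'", call. = FALSE)
  }
  unname(vmax_invitro * yields[protein_source] * 60 / 1000)
}

#' Build the scaled whole-liver kinetic table
#'
#' Scales each pathway's in vitro Vmax with the yield of its assay fraction
#' (microsomes for `AP`, `EE`, `HE`, `HA`, `M5`, `HEG`; S9 for `OE`, `HES`)
#' and recomputes the scaled catalytic efficiency
#' `vmax_scaled / km_uM x 1000`, uL/h/(g liver).
#'
#' @param fits A list of `mm_fit` objects, or a data frame with columns
#'   `pathway`, `km_uM`, `vmax_invitro` (e.g. [reference_kinetics()]).
#'   Any subset of pathways is accepted; duplicates are an error.
#' @param yields Protein yields, mg/(g liver).
#' @return A data frame of class `scaled_pathway_table` with columns
#'   `pathway`, `parent`, `protein_source`, `km_uM`, `vmax_scaled`,
#'   `efficiency_scaled`, ordered as [pathway_registry()].
#' @export
build_scaled_table <- function(fits, yields = protein_yields()) {
  if (is.data.frame(fits)) {
    df <- fits[, intersect(c("pathway", "km_uM", "vmax_invitro"), names(fits))]
    if (!all(c("pathway", "km_uM", "vmax_invitro") %in% names(df))) {
      stop("fits data frame needs columns pathway, km_uM, vmax_invitro",
           call. = FALSE)
    }
  } else {
    if (!all(vapply(fits, inherits, logical(1), "mm_fit"))) {
      stop("fits must be mm_fit objects or a data frame", call. = FALSE)
    }
    df <- data.frame(
      pathway = vapply(fits, `[[`, character(1), "pathway"),
      km_uM = vapply(fits, `[[`, numeric(1), "km_uM"),
      vmax_invitro = vapply(fits, `[[`, numeric(1), "vmax_invitro"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(df) == 0) {
    out <- data.frame(
      pathway = character(), parent = character(),
      protein_source = character(), km_uM = numeric(),
      vmax_scaled = numeric(), efficiency_scaled = numeric(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("scaled_pathway_table", "data.frame")
    return(out)
  }
  bad <- setdiff(df$pathway, .pathways$pathway)
  if (length(bad)) stop("unknown pathway: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$pathway)) {
    stop("duplicate pathway in fits: ",
         paste(unique(df$pathway[duplicated(df$pathway)]), collapse = ", "),
         call. = FALSE)
  }
  meta <- .pathways[match(df$pathway, .pathways$pathway), ]
  out <- data.frame(
    pathway = df$pathway,
    parent = meta$parent,
    protein_source = meta$protein_source,
    km_uM = df$km_uM,
    vmax_scaled = scale_vmax(df$vmax_invitro, meta$protein_source, yields),
    stringsAsFactors = FALSE
  )
  out$efficiency_scaled <- out$vmax_scaled / out$km_uM * 1000
  out <- out[order(match(out$pathway, .pathways$pathway)), ]
  rownames(out) <- NULL
  class(out) <- c("scaled_pathway_table", "data.frame")
  out
}
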