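# Readers and writers. CSV dialect: comma-separated, UTF-8, '.' decimal,
# mandatory header, '#' comment lines. Column names carry units to prevent
# silent unit errors. Configs are JSON or YAML by file extension.

.rate_table_cols <- c("concentration_uM", "rate_mean", "rate_sem",
                      "pathway", "protein_source")

#' Read incubation rate tables from CSV/TSV
#'
#' Expects the header `concentration_uM, rate_mean, rate_sem, pathway,
#' protein_source` (rate_sem may be empty). Lines starting with `#` are
#' comments. Rows are split by pathway into [invitro_dataset()] objects.
#'
#' @param path File path; tab-separated when the extension is `.tsv`.
#' @return Named list of `invitro_dataset` objects, one per pathway present.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, comment.char = "#",
                 stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(.rate_table_cols, "rate_sem"), names(df))
  if (length(missing)) {
    stop("rate table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "),
         "; expected header: ", paste(.rate_table_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$pathway), function(d) {
    invitro_dataset(
      pathway = d$pathway[1], protein_source = d$protein_source[1],
      concentrations = d$concentration_uM, rates = d$rate_mean,
      rate_sems = if ("rate_sem" %in% names(d) && !all(is.na(d$rate_sem)))
        d$rate_sem else NULL
    )
  })
  out[order(match(names(out), .pathways$pathway))]
}

#' Write incubation datasets to CSV
#'
#' @param datasets A single [invitro_dataset()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(datasets, path) {
  if (inherits(datasets, "invitro_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    data.frame(
      concentration_uM = d$concentrations, rate_mean = d$rates,
      rate_sem = if (is.null(d$rate_sems)) NA_real_ else d$rate_sems,
      pathway = d$pathway, protein_source = d$protein_source,
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export fitted kinetic constants as a CSV table
#'
#' One row per pathway with Km, Vmax, their standard errors and the
#' catalytic efficiency rounded to two significant figures (report-table
#' convention).
#'
#' @param fits List of `mm_fit` objects.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_kinetics_table <- function(fits, path) {
  df <- data.frame(
    pathway = vapply(fits, `[[`, character(1), "pathway"),
    protein_source = vapply(fits, `[[`, character(1), "protein_source"),
    km_uM = vapply(fits, `[[`, numeric(1), "km_uM"),
    km_sem = vapply(fits, `[[`, numeric(1), "km_sem"),
    vmax_nmol_min_mg = vapply(fits, `[[`, numeric(1), "vmax_invitro"),
    vmax_sem = vapply(fits, `[[`, numeric(1), "vmax_sem"),
    stringsAsFactors = FALSE
  )
  df$efficiency_uL_min_mg <- signif(df$vmax_nmol_min_mg / df$km_uM * 1000, 2)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

.model_to_config <- function(model) {
  ph <- model$physiology
  kin <- merge(model$kinetics, .pathways[, c("pathway", "protein_source")],
               by = "pathway", sort = FALSE)
  list(
    name = model$name,
    physiology = list(
      body_weight_kg = ph$body_weight_kg,
      tissue_fraction_pct = as.list(ph$tissue_fraction_pct),
      cardiac_output_constant = ph$cardiac_output_constant,
      flow_fraction_pct = as.list(ph$flow_fraction_pct)
    ),
    partition_coefficients = lapply(model$partitions, as.list),
    pathways = lapply(seq_len(nrow(kin)), function(i) {
      list(
        pathway = kin$pathway[i], km_uM = kin$km_uM[i],
        vmax_invitro = kin$vmax_invitro[i],
        protein_source = kin$protein_source[i]
      )
    }),
    protein_yields_mg_per_g = as.list(model$yields),
    absorption = list(ka_per_h = model$ka_per_h),
    mw_estragole = model$mw_estragole
  )
}

.config_to_model <- function(cfg) {
  need <- c("physiology", "partition_coefficients", "pathways", "absorption")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("population config is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ph <- cfg$physiology
  kin <- do.call(rbind, lapply(cfg$pathways, function(p) {
    data.frame(pathway = p$pathway, km_uM = p$km_uM,
               vmax_invitro = p$vmax_invitro, stringsAsFactors = FALSE)
  }))
  yields <- if (!is.null(cfg$protein_yields_mg_per_g)) {
    unlist(cfg$protein_yields_mg_per_g)
  } else {
    protein_yields()
  }
  pbk_model(
    physiology = list(
      body_weight_kg = ph$body_weight_kg,
      tissue_fraction_pct = unlist(ph$tissue_fraction_pct),
      cardiac_output_constant = ph$cardiac_output_constant,
      flow_fraction_pct = unlist(ph$flow_fraction_pct)
    ),
    partitions = lapply(cfg$partition_coefficients, unlist),
    kinetics = kin,
    yields = yields,
    ka_per_h = cfg$absorption$ka_per_h,
    mw_estragole = if (is.null(cfg$mw_estragole)) 148.20 else cfg$mw_estragole,
    name = if (is.null(cfg$name)) "custom" else cfg$name
  )
}

#' Read a population parameter file into a PBK model
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with sections `physiology`,
#' `partition_coefficients`, `pathways`, `absorption` and optional
#' `protein_yields_mg_per_g`, `mw_estragole`, `name`. Two bundled files
#' under `system.file("extdata", package = "estrapbk")` reproduce the
#' Chinese and Caucasian parameter sets.
#'
#' @param path Config file path.
#' @return A `pbk_model`.
#' @export
read_population_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .config_to_model(cfg)
}

#' Write a PBK model to a population parameter file
#'
#' @param model A `pbk_model`.
#' @param path Output path; format chosen by extension (`.json` default,
#'   `.yml`/`.yaml` for YAML). Round-trips losslessly through
#'   [read_population_config()].
#' @return `path`, invisibly.
#' @export
write_population_config <- function(model, path) {
  stopifnot(inherits(model, "pbk_model"))
  cfg <- .model_to_config(model)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 15)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a simulation's time series and summary to disk
#'
#' @param result A `pbk_simulation`.
#' @param csv_path CSV for the trajectory: one row per time point, one
#'   column per state (amounts in umol).
#' @param json_path Optional JSON summary (dose, per-metabolite percent of
#'   dose / nmol per g liver, liver 1'-hydroxyestragole Cmax and AUC).
#' @return `csv_path`, invisibly.
#' @export
write_simulation <- function(result, csv_path, json_path = NULL) {
  stopifnot(inherits(result, "pbk_simulation"))
  df <- data.frame(time_h = result$time, result$states, check.names = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- result$summary
    jsonlite::write_json(
      list(
        population = result$model$name,
        dose_mg_per_kg = result$dose_mg_per_kg,
        dose_umol = result$dose_umol,
        duration_h = result$duration_h,
        metabolites = s,
        he_liver_cmax_uM = attr(s, "he_liver_cmax_uM"),
        he_liver_auc_uM_h = attr(s, "he_liver_auc_uM_h")
      ),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(csv_path)
}
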