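# File formats: cohorts as CSV with a sidecar JSON schema and a provenance
# JSON; profiles as JSON (null = missing) or single-row CSV (empty field =
# missing); population models as YAML (full) or CSV (hazard columns).

spec_to_list <- function(spec) {
  list(name = spec$name, kind = spec$kind, group = spec$group,
       levels = spec$levels, transform = spec$transform,
       risk_effect = as.list(spec$risk_effect),
       center = spec$center, scale = spec$scale, margin = spec$margin)
}

list_to_spec <- function(x) {
  re <- unlist(x$risk_effect)
  margin <- lapply(x$margin, function(m) if (is.list(m)) unlist(m) else m)
  variable_spec(x$name, x$kind, x$group, re, levels = unlist(x$levels),
                transform = x$transform, center = x$center, scale = x$scale,
                margin = margin)
}

#' Write and read a risk-factor schema as JSON
#'
#' @param schema a [risk_schema()].
#' @param path file path.
#' @return `read_schema()` returns a [risk_schema()]; `write_schema()` its
#'   path, invisibly.
#' @export
write_schema <- function(schema, path) {
  obj <- list(variables = lapply(unname(schema$variables), spec_to_list),
              pv_variable = schema$pv_variable,
              pgs_variable = schema$pgs_variable)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path)
  risk_schema(lapply(obj$variables, list_to_spec),
              pv_variable = obj$pv_variable,
              pgs_variable = obj$pgs_variable)
}

cohort_col_classes <- function(schema) {
  vapply(schema$variables, function(spec) {
    switch(spec$kind,
           "binary" = "integer",
           "categorical" = ,
           "ordinal-count" = "character",
           "numeric")
  }, character(1))
}

#' Write a reference cohort to disk
#'
#' Writes `<prefix>.csv` (missing entries as empty fields),
#' `<prefix>_schema.json` and `<prefix>_provenance.json`.
#'
#' @param cohort a `reference_cohort`.
#' @param prefix path prefix for the three files.
#' @return the three paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- c(data = paste0(prefix, ".csv"),
             schema = paste0(prefix, "_schema.json"),
             provenance = paste0(prefix, "_provenance.json"))
  out <- cohort$data
  for (nm in names(out)) {
    # full-precision text so that write -> read round-trips doubles exactly
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, paths[["data"]], row.names = FALSE, na = "", quote = FALSE)
  write_schema(cohort$schema, paths[["schema"]])
  prov <- cohort$provenance
  prov$dependence <- as.data.frame(prov$dependence)
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a reference cohort written by [write_cohort()]
#'
#' @param prefix the path prefix used when writing, or a CSV path (then the
#'   sidecar schema path is derived from it).
#' @return a `reference_cohort`.
#' @export
read_cohort <- function(prefix) {
  if (grepl("\\.csv$", prefix)) prefix <- sub("\\.csv$", "", prefix)
  schema <- read_schema(paste0(prefix, "_schema.json"))
  classes <- cohort_col_classes(schema)
  data <- utils::read.csv(paste0(prefix, ".csv"), colClasses = unname(classes),
                          na.strings = "", stringsAsFactors = FALSE)
  prov_path <- paste0(prefix, "_provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  structure(list(data = data, schema = schema, provenance = prov),
            class = "reference_cohort")
}

#' Read an index-individual profile
#'
#' JSON profiles have fields `age`, `horizon` and `values` (JSON `null` =
#' missing); single-row CSV profiles have an `age` column, an optional
#' `horizon` column and one column per risk factor with empty fields =
#' missing.
#'
#' @param path file path (`.json` or `.csv`).
#' @param schema a [risk_schema()] used to type and validate the values.
#' @return an [individual_profile()].
#' @export
read_profile <- function(path, schema) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path)
    vals <- lapply(obj$values, function(v) if (is.null(v)) NA else v)
    return(individual_profile(obj$age, vals,
                              horizon = obj$horizon %||% 10, schema = schema))
  }
  classes <- cohort_col_classes(schema)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  for (nm in intersect(names(classes), names(df))) {
    df[[nm]] <- switch(classes[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       as.character(df[[nm]]))
  }
  if (nrow(df) != 1L) stop_("profile CSV must have exactly one row")
  vals <- as.list(df[1L, intersect(schema_names(schema), names(df))])
  individual_profile(df$age[1L], vals,
                     horizon = if ("horizon" %in% names(df)) df$horizon[1L] else 10,
                     schema = schema)
}

#' Write an index-individual profile as JSON
#'
#' @param profile an [individual_profile()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  vals <- lapply(profile$values, function(v) if (is.na(v)) NULL else v)
  jsonlite::write_json(list(age = profile$age, horizon = profile$horizon,
                            values = vals),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write and read a population model
#'
#' YAML round-trips the full object (hazards, PV frequencies, calibration);
#' CSV holds the `age`, `incidence`, `mortality` (and optionally
#' `calibration`) columns, with PV frequencies supplied separately on read.
#'
#' @param pop a [population_model()].
#' @param path `.yaml`/`.yml` or `.csv` path.
#' @param pv_frequencies named carrier-frequency vector, required when
#'   reading from CSV.
#' @return `read_population()` returns a [population_model()].
#' @export
write_population <- function(pop, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(age = pop$age_grid, incidence = pop$incidence,
                          mortality = pop$mortality,
                          pv_frequencies = as.list(pop$pv_frequencies),
                          calibration = pop$calibration), path)
  } else {
    utils::write.csv(data.frame(age = pop$age_grid, incidence = pop$incidence,
                                mortality = pop$mortality,
                                calibration = pop$calibration),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, pv_frequencies = NULL) {
  if (grepl("\\.ya?ml$", path)) {
    obj <- yaml::read_yaml(path)
    return(population_model(obj$age, obj$incidence, obj$mortality,
                            unlist(obj$pv_frequencies),
                            calibration = obj$calibration %||%
                              rep(1, length(obj$age))))
  }
  df <- utils::read.csv(path)
  if (is.null(pv_frequencies)) {
    stop_("reading a population model from CSV requires pv_frequencies")
  }
  population_model(df$age, df$incidence, df$mortality, pv_frequencies,
                   calibration = df$calibration %||% rep(1, nrow(df)))
}

#' Write a risk distribution (samples CSV + summary JSON)
#'
#' @param dist a `risk_distribution`.
#' @param prefix path prefix; writes `<prefix>_samples.csv` and
#'   `<prefix>_summary.json`.
#' @param extra named list merged into the summary JSON (e.g. provenance).
#' @return the two paths, invisibly.
#' @export
write_distribution <- function(dist, prefix, extra = list()) {
  paths <- c(samples = paste0(prefix, "_samples.csv"),
             summary = paste0(prefix, "_summary.json"))
  utils::write.csv(data.frame(sample = seq_along(dist$samples),
                              risk = dist$samples),
                   paths[["samples"]], row.names = FALSE)
  summary <- c(list(point_estimate = dist$point_estimate,
                    ui_lower = dist$ui[["lower"]],
                    ui_upper = dist$ui[["upper"]],
                    level = dist$level,
                    category_probs = as.list(dist$category_probs),
                    rhat = as.list(dist$rhat %||% numeric()),
                    age = dist$age, horizon = dist$horizon,
                    M = dist$M, seed = dist$seed),
               extra)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a reclassification flow (tidy CSV + summary JSON)
#'
#' @param flow a `reclassification_flow`.
#' @param prefix path prefix; writes `<prefix>_flow.csv` and
#'   `<prefix>_summary.json`.
#' @param extra named list merged into the summary JSON.
#' @return the two paths, invisibly.
#' @export
write_flow <- function(flow, prefix, extra = list()) {
  paths <- c(flow = paste0(prefix, "_flow.csv"),
             summary = paste0(prefix, "_summary.json"))
  utils::write.csv(flow_table(flow), paths[["flow"]], row.names = FALSE)
  summary <- c(list(stage_labels = flow$stage_labels,
                    membership = as.data.frame(flow$membership),
                    baseline_category = flow$baseline_category,
                    reclassification_probability =
                      reclassification_probability(flow),
                    M = flow$M, M_inner = flow$M_inner, seed = flow$seed),
               extra)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
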