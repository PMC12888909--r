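#' Declare one risk-factor variable
#'
#' A `variable_spec` describes a single covariate of the risk model: its
#' statistical type, the transform used inside imputation models, the
#' measurement group it belongs to, and its effect on risk.
#'
#' Measurement groups follow the convention used when risk factors are
#' collected in blocks: `"QRF"` (questionnaire risk factors: lifestyle,
#' hormonal, reproductive), `"MD"` (mammographic density), `"GF"` (genetic
#' factors: polygenic score and rare pathogenic variants) and `"FH"` (family
#' history).
#'
#' Risk effects are log relative risks:
#' * `continuous` / `continuous-positive`: a single per-SD log-RR applied to
#'   the standardized transform scale, `beta * (t(x) - center) / scale`;
#' * `semicontinuous-zero-inflated`: a named vector
#'   `c(positive = ..., per_sd = ...)`; zero consumption is the reference
#'   (contribution 0), any positive amount contributes
#'   `positive + per_sd * (log(x) - center) / scale`;
#' * `binary`: a scalar log-RR for the exposed (`1`) level;
#' * `categorical` / `ordinal-count`: a named vector with one entry per level,
#'   reference level's entry exactly 0.
#'
#' @param name variable name (unique within a schema).
#' @param kind one of `"continuous"`, `"continuous-positive"`,
#'   `"semicontinuous-zero-inflated"`, `"binary"`, `"categorical"`,
#'   `"ordinal-count"`.
#' @param group measurement group, one of `"QRF"`, `"MD"`, `"GF"`, `"FH"`.
#' @param risk_effect log relative risk(s), see Details.
#' @param levels character vector of levels (categorical/ordinal only); the
#'   first is the reference level.
#' @param transform `"identity"` or `"log"`; `"log"` is only allowed for
#'   positive or zero-inflated kinds.
#' @param center,scale location/scale of the transform-scale reference
#'   distribution used to standardize continuous effects (ignored for
#'   discrete kinds).
#' @param margin list of generator parameters for [simulate_cohort()]
#'   (e.g. `list(meanlog =, sdlog =)` for log-normal margins, `list(p = )`
#'   for binary, `list(probs = )` for categorical).
#' @return an object of class `variable_spec`.
#' @seealso [risk_schema()], [default_schema()]
#' @export
variable_spec <- function(name, kind, group, risk_effect,
                          levels = NULL, transform = "identity",
                          center = 0, scale = 1, margin = list()) {
  kinds <- c("continuous", "continuous-positive",
             "semicontinuous-zero-inflated", "binary",
             "categorical", "ordinal-count")
  if (!kind %in% kinds) stop_("unknown kind '%s' for variable '%s'", kind, name)
  if (!group %in% c("QRF", "MD", "GF", "FH")) {
    stop_("group must be one of QRF, MD, GF, FH (variable '%s')", name)
  }
  if (!transform %in% c("identity", "log")) {
    stop_("transform must be 'identity' or 'log' (variable '%s')", name)
  }
  if (transform == "log" &&
      !kind %in% c("continuous-positive", "semicontinuous-zero-inflated")) {
    stop_("transform='log' requires a positive or zero-inflated kind ('%s')", name)
  }
  if (kind %in% c("categorical", "ordinal-count")) {
    if (is.null(levels) || length(levels) < 2L) {
      stop_("categorical/ordinal variable '%s' needs >= 2 levels", name)
    }
    if (is.null(names(risk_effect)) || !setequal(names(risk_effect), levels)) {
      stop_("risk_effect of '%s' must be named with one entry per level", name)
    }
    risk_effect <- risk_effect[levels]
    if (risk_effect[[1L]] != 0) {
      stop_("reference level '%s' of '%s' must have risk_effect 0",
            levels[1L], name)
    }
  }
  if (kind == "semicontinuous-zero-inflated") {
    if (!all(c("positive", "per_sd") %in% names(risk_effect))) {
      stop_("zero-inflated variable '%s' needs risk_effect c(positive=, per_sd=)",
            name)
    }
  }
  if (scale <= 0) stop_("scale must be positive (variable '%s')", name)
  structure(
    list(name = name, kind = kind, group = group, levels = levels,
         transform = transform, risk_effect = risk_effect,
         center = center, scale = scale, margin = margin),
    class = "variable_spec"
  )
}

#' Assemble a risk-factor schema
#'
#' The schema is the ordered list of covariates the risk model and the
#' imputation engine operate on, together with the identity of the polygenic
#' score (PGS) variable and the rare pathogenic-variant (PV) variable.
#'
#' @param variables list of [variable_spec()] objects.
#' @param pv_variable name of the pathogenic-variant variable; must be
#'   categorical with exactly 9 levels (no-PV reference plus eight genes,
#'   at most one PV per person under the rare-disease assumption).  May be
#'   `NULL` for reduced schemas that carry no PV variable (e.g. toy systems).
#' @param pgs_variable name of the PGS variable; must be continuous and is
#'   interpreted as standard normal in the population.  May be `NULL` for
#'   reduced schemas.
#' @return an object of class `risk_schema`.
#' @export
risk_schema <- function(variables, pv_variable = NULL, pgs_variable = NULL) {
  stopifnot(all(vapply(variables, inherits, logical(1), "variable_spec")))
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_("variable names must be unique")
  names(variables) <- nms
  if (!is.null(pv_variable)) {
    if (!pv_variable %in% nms) stop_("pv_variable '%s' not in schema", pv_variable)
    pv <- variables[[pv_variable]]
    if (pv$kind != "categorical" || length(pv$levels) != 9L) {
      stop_("pv_variable must be categorical with exactly 9 levels")
    }
  }
  if (!is.null(pgs_variable)) {
    if (!pgs_variable %in% nms) stop_("pgs_variable '%s' not in schema", pgs_variable)
    if (variables[[pgs_variable]]$kind != "continuous") {
      stop_("pgs_variable must be continuous")
    }
  }
  structure(
    list(variables = variables, pv_variable = pv_variable,
         pgs_variable = pgs_variable),
    class = "risk_schema"
  )
}

#' @export
print.risk_schema <- function(x, ...) {
  cat(sprintf("risk_schema: %d variables\n", length(x$variables)))
  for (v in x$variables) {
    cat(sprintf("  %-12s %-28s group=%-3s transform=%s\n",
                v$name, v$kind, v$group, v$transform))
  }
  cat(sprintf("  PGS variable: %s;  PV variable: %s\n",
              x$pgs_variable %||% "<none>", x$pv_variable %||% "<none>"))
  invisible(x)
}

schema_names <- function(schema) names(schema$variables)

schema_groups <- function(schema) {
  vapply(schema$variables, `[[`, character(1), "group")
}

#' Default breast-cancer risk-factor schema
#'
#' A self-contained stand-in for the covariate set of multifactorial
#' breast-cancer risk models: six questionnaire risk factors (BMI, alcohol
#' intake, age at menarche, parity, HRT use, oral-contraceptive use),
#' mammographic density, a standardized polygenic score, a nine-category
#' pathogenic-variant status (no PV, or a single PV in BRCA1, BRCA2, PALB2,
#' CHEK2, ATM, BARD1, RAD51C or RAD51D), and a first-degree family-history
#' count (0 / 1 / 2+ affected relatives).
#'
#' The per-factor log relative risks are illustrative defaults in the range
#' reported for these factors in the epidemiological literature; they are
#' configuration, not estimates, and can be replaced wholesale via
#' [variable_spec()].
#'
#' @return a [risk_schema()].
#' @examples
#' sch <- default_schema()
#' sch$variables$alcohol$kind
#' @export
default_schema <- function() {
  pv_levels <- c("none", "BRCA1", "BRCA2", "PALB2", "CHEK2",
                 "ATM", "BARD1", "RAD51C", "RAD51D")
  pv_effect <- c(none = 0, BRCA1 = log(10), BRCA2 = log(6), PALB2 = log(4),
                 CHEK2 = log(2.5), ATM = log(2.1), BARD1 = log(2.0),
                 RAD51C = log(1.9), RAD51D = log(1.9))
  vars <- list(
    variable_spec("bmi", "continuous-positive", "QRF",
                  risk_effect = log(1.10), transform = "log",
                  center = 3.25, scale = 0.18,
                  margin = list(meanlog = 3.25, sdlog = 0.18)),
    variable_spec("alcohol", "semicontinuous-zero-inflated", "QRF",
                  risk_effect = c(positive = log(1.05), per_sd = log(1.08)),
                  transform = "log", center = 1.8, scale = 0.8,
                  margin = list(p_zero = 0.25, meanlog = 1.8, sdlog = 0.8)),
    variable_spec("menarche_age", "continuous", "QRF",
                  risk_effect = log(0.95), center = 13, scale = 1.5,
                  margin = list(mean = 13, sd = 1.5)),
    variable_spec("parity", "ordinal-count", "QRF",
                  levels = c("0", "1", "2", "3+"),
                  risk_effect = c("0" = 0, "1" = log(0.95), "2" = log(0.88),
                                  "3+" = log(0.85)),
                  margin = list(probs = c(0.20, 0.25, 0.40, 0.15))),
    variable_spec("hrt_use", "binary", "QRF",
                  risk_effect = log(1.3), margin = list(p = 0.25)),
    variable_spec("oc_use", "binary", "QRF",
                  risk_effect = log(1.1), margin = list(p = 0.35)),
    variable_spec("md", "continuous-positive", "MD",
                  risk_effect = log(1.30), transform = "log",
                  center = 3.0, scale = 0.5,
                  margin = list(meanlog = 3.0, sdlog = 0.5)),
    variable_spec("pgs", "continuous", "GF",
                  risk_effect = log(1.6), center = 0, scale = 1,
                  margin = list(mean = 0, sd = 1)),
    variable_spec("pv", "categorical", "GF",
                  levels = pv_levels, risk_effect = pv_effect,
                  margin = list()),  # frequencies come from the population model
    variable_spec("fh", "ordinal-count", "FH",
                  levels = c("0", "1", "2+"),
                  risk_effect = c("0" = 0, "1" = log(1.8), "2+" = log(2.9)),
                  margin = list(
                    # sequential-logistic generator: P(fh >= 1) and P(2+ | >= 1)
                    # depend on PGS and PV carrier status (positively)
                    b_any = c(intercept = stats::qlogis(0.12), pgs = 0.35,
                              carrier = 0.8),
                    b_two = c(intercept = stats::qlogis(0.15), pgs = 0.20,
                              carrier = 0.5)
                  ))
  )
  risk_schema(vars, pv_variable = "pv", pgs_variable = "pgs")
}
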