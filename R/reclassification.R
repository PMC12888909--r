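# Stepwise measurement of risk-factor groups and the resulting risk-category
# reclassification flows (Sankey bookkeeping).

# Inner marginalisation: the point-estimate risk of each row of `data`, with
# that row's remaining missing covariates averaged out over M_inner chained
# imputations (single-dataset parameter draws; see vignette).
inner_point_estimates <- function(data, models, pop, age, horizon,
                                  M_inner, n_iter) {
  if (!anyNA(data)) {
    return(cumulative_risk_rr(exp(log_rr_rows(data, models$schema)),
                              age, horizon, pop))
  }
  idx <- rep(seq_len(nrow(data)), each = M_inner)
  big <- data[idx, , drop = FALSE]
  rownames(big) <- NULL
  res <- mice_rows(models, big, n_iter, per_row = FALSE)
  risks <- cumulative_risk_rr(exp(log_rr_rows(res$data, models$schema)),
                              age, horizon, pop)
  as.numeric(rowsum(risks, idx)) / M_inner
}

#' Stepwise measurement of risk-factor groups
#'
#' Simulates successively measuring groups of missing risk factors in the
#' given order.  Each of `M` Monte Carlo trajectories draws the stage-k
#' group's variables from their conditional distribution given the observed
#' profile and all previously drawn groups, then holds them fixed.  The
#' stage-k risk of a trajectory is its point estimate with the still
#' unmeasured groups left missing, obtained by averaging over `M_inner`
#' inner imputations of those covariates; each stage-k risk is classified,
#' and per-stage category memberships plus stage-to-stage transition
#' matrices are accumulated for Sankey-style output.
#'
#' @param profile an [individual_profile()].
#' @param models fitted `imputation_models`.
#' @param pop a calibrated [population_model()].
#' @param group_order ordered subset of `c("QRF", "MD", "GF", "FH")`; groups
#'   with no missing variables are skipped with a warning.
#' @param schema a [risk_schema()].
#' @param M number of Monte Carlo trajectories.
#' @param M_inner inner imputations used to marginalise still-unmeasured
#'   groups (default 100).
#' @param n_iter chained-equations iterations per imputation pass.
#' @param seed integer seed.
#' @param scheme a [category_scheme()].
#' @return an object of class `reclassification_flow`: `stage_labels`,
#'   `membership` (stage x category proportions), `transitions` (list of
#'   category x category joint-proportion matrices for consecutive stages),
#'   `baseline_category`, the per-trajectory category matrix, `M`, `seed`.
#' @export
stepwise_measurement <- function(profile, models, pop,
                                 group_order = c("QRF", "MD", "GF"),
                                 schema = models$schema, M = 1000L,
                                 M_inner = 100L, n_iter = 10L, seed,
                                 scheme = category_scheme()) {
  stopifnot(inherits(models, "imputation_models"))
  if (!all(group_order %in% c("QRF", "MD", "GF", "FH"))) {
    stop_("group_order must be a subset of QRF, MD, GF, FH")
  }
  miss <- profile_missing(profile)
  groups <- schema_groups(schema)
  stage_vars <- lapply(group_order, function(g) {
    intersect(miss, names(groups)[groups == g])
  })
  keep <- lengths(stage_vars) > 0L
  for (g in group_order[!keep]) {
    warning(sprintf("group %s has no missing variables; stage skipped", g))
  }
  group_order <- group_order[keep]
  stage_vars <- stage_vars[keep]
  n_stage <- length(group_order) + 1L  # baseline first
  labels <- c("baseline", paste0("+", group_order, recycle0 = TRUE))
  K <- length(scheme$labels)

  row <- profile_as_row(profile, schema)
  cat_mat <- matrix(NA_integer_, nrow = M, ncol = n_stage)
  with_seed(seed, {
    base_risk <- inner_point_estimates(row, models, pop, profile$age,
                                       profile$horizon, M_inner, n_iter)
    cat_mat[, 1L] <- classify_index(base_risk, scheme)
    data <- row[rep(1L, M), , drop = FALSE]
    rownames(data) <- NULL
    for (k in seq_along(group_order)) {
      drawn <- mice_rows(models, data, n_iter, per_row = TRUE)$data
      for (v in stage_vars[[k]]) data[[v]] <- drawn[[v]]
      risk_k <- inner_point_estimates(data, models, pop, profile$age,
                                      profile$horizon, M_inner, n_iter)
      cat_mat[, k + 1L] <- classify_index(risk_k, scheme)
    }
  })
  membership <- matrix(0, n_stage, K, dimnames = list(labels, scheme$labels))
  for (s in seq_len(n_stage)) {
    membership[s, ] <- tabulate(cat_mat[, s], nbins = K) / M
  }
  transitions <- list()
  if (n_stage > 1L) {
    for (s in seq_len(n_stage - 1L)) {
      tab <- table(factor(cat_mat[, s], levels = seq_len(K)),
                   factor(cat_mat[, s + 1L], levels = seq_len(K))) / M
      tab <- matrix(as.numeric(tab), K, K,
                    dimnames = list(scheme$labels, scheme$labels))
      transitions[[paste0(labels[s], " -> ", labels[s + 1L])]] <- tab
    }
  }
  structure(
    list(stage_labels = labels, categories = scheme$labels,
         membership = membership, transitions = transitions,
         baseline_category = scheme$labels[cat_mat[1L, 1L]],
         trajectory_categories = cat_mat,
         group_order = group_order, M = M, M_inner = M_inner, seed = seed),
    class = "reclassification_flow"
  )
}

#' @export
print.reclassification_flow <- function(x, ...) {
  cat(sprintf("reclassification_flow: %s (M=%d)\n",
              paste(x$stage_labels, collapse = " -> "), x$M))
  print(round(x$membership, 4))
  cat(sprintf("  baseline category: %s;  reclassification prob %.3f\n",
              x$baseline_category, reclassification_probability(x)))
  invisible(x)
}

#' Probability of leaving the baseline risk category
#'
#' One minus the probability that a trajectory is still in the
#' `from_stage` point-estimate's category after measuring through
#' `to_stage`.
#'
#' @param flow a `reclassification_flow`.
#' @param from_stage,to_stage stage labels or indices (defaults: first and
#'   last stage).
#' @return probability in `[0, 1]`.
#' @export
reclassification_probability <- function(flow, from_stage = 1L,
                                         to_stage = length(flow$stage_labels)) {
  from <- resolve_stage(flow, from_stage)
  to <- resolve_stage(flow, to_stage)
  c0 <- which.max(flow$membership[from, ])
  1 - flow$membership[[to, c0]]
}

resolve_stage <- function(flow, stage) {
  if (is.character(stage)) {
    i <- match(stage, flow$stage_labels)
    if (is.na(i)) stop_("unknown stage '%s'", stage)
    return(i)
  }
  if (stage < 1L || stage > length(flow$stage_labels)) {
    stop_("stage index %d out of range", stage)
  }
  as.integer(stage)
}

#' Tidy transition table of a reclassification flow
#'
#' One row per (stage pair, category pair) with its trajectory proportion —
#' the long format consumed by Sankey plotting tools.
#'
#' @param flow a `reclassification_flow`.
#' @return a data.frame with columns `stage_from`, `stage_to`,
#'   `category_from`, `category_to`, `proportion`.
#' @export
flow_table <- function(flow) {
  if (!length(flow$transitions)) {
    return(data.frame(stage_from = character(), stage_to = character(),
                      category_from = character(), category_to = character(),
                      proportion = numeric()))
  }
  out <- do.call(rbind, lapply(seq_along(flow$transitions), function(s) {
    tab <- flow$transitions[[s]]
    grid <- expand.grid(category_from = rownames(tab),
                        category_to = colnames(tab),
                        stringsAsFactors = FALSE)
    data.frame(stage_from = flow$stage_labels[s],
               stage_to = flow$stage_labels[s + 1L],
               grid, proportion = as.vector(tab))
  }))
  out[out$proportion > 0, , drop = FALSE]
}
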