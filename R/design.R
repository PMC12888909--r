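# Design-matrix construction shared by model fitting and imputation draws.
#
# Encoding per predictor kind:
#   continuous            -> one column on the transform scale
#   continuous-positive   -> log(x) when transform = "log"
#   semicontinuous        -> two columns: positivity indicator and
#                            log(x) (0 at zeros) — the standard two-part
#                            predictor encoding
#   binary                -> 0/1
#   categorical/ordinal   -> reference-coded indicator per non-reference level

design_colnames <- function(spec) {
  switch(spec$kind,
    "continuous" = ,
    "continuous-positive" = ,
    "binary" = spec$name,
    "semicontinuous-zero-inflated" = paste0(spec$name, c("_pos", "_logpos")),
    paste0(spec$name, "_", gsub("[^A-Za-z0-9]", ".", spec$levels[-1L]))
  )
}

design_block <- function(spec, x) {
  switch(spec$kind,
    "continuous" = matrix(x, ncol = 1L),
    "continuous-positive" = matrix(if (spec$transform == "log") log(x) else x,
                                   ncol = 1L),
    "semicontinuous-zero-inflated" = {
      pos <- as.numeric(x > 0)
      lx <- numeric(length(x))
      lx[x > 0] <- log(x[x > 0])
      cbind(pos, lx)
    },
    "binary" = matrix(as.numeric(x), ncol = 1L),
    "categorical" = ,
    "ordinal-count" = {
      idx <- match(x, spec$levels)
      if (anyNA(idx)) stop_("undeclared level in variable '%s'", spec$name)
      k <- length(spec$levels)
      out <- matrix(0, nrow = length(x), ncol = k - 1L)
      hit <- idx > 1L
      out[cbind(which(hit), idx[hit] - 1L)] <- 1
      out
    }
  )
}

# Full design for modelling `target` from all other schema variables.
# Returns a numeric matrix with an intercept column first.
build_design <- function(data, schema, target) {
  preds <- setdiff(schema_names(schema), target)
  blocks <- vector("list", length(preds))
  nms <- vector("list", length(preds))
  for (i in seq_along(preds)) {
    spec <- schema$variables[[preds[i]]]
    blocks[[i]] <- design_block(spec, data[[preds[i]]])
    nms[[i]] <- design_colnames(spec)
  }
  X <- cbind(rep(1, nrow(data)), do.call(cbind, blocks))
  colnames(X) <- c("(Intercept)", unlist(nms))
  X
}
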