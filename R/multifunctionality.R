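# Soil multifunctionality: per-variable normalization, 0-1 scaling, and the
# averaging index over the 12 included soil variables (pH excluded by
# default because it is a log-scaled quantity).

#' Normalize a soil variable toward normality
#'
#' Shapiro-Wilk at alpha = 0.05 decides whether a transform is needed. When
#' it is, log and square-root candidates are compared (after shifting the
#' whole vector by its minimum when any value is non-positive, so the minimum
#' maps to zero) and the candidate with the larger Shapiro-Wilk p is kept;
#' ties break toward log. A candidate producing non-finite values (log of a
#' zero minimum) is discarded.
#'
#' @param values numeric vector (>= 3 finite values).
#' @return list with `values` (transformed vector) and `transform`, one of
#'   `"none"`, `"log"`, `"sqrt"`, `"shift+log"`, `"shift+sqrt"`.
#' @export
normalize_variable <- function(values) {
  if (length(values) < 3 || anyNA(values) || any(!is.finite(values)))
    stop_stage("mf", "need at least 3 finite values")
  if (stats::sd(values) == 0) {
    warning("constant vector: normality test undefined, no transform applied")
    return(list(values = values, transform = "none"))
  }
  p_raw <- stats::shapiro.test(values)$p.value
  if (p_raw >= 0.05) return(list(values = values, transform = "none"))

  shift <- if (min(values) <= 0) -min(values) else 0
  shifted <- values + shift
  prefix <- if (shift > 0) "shift+" else ""
  candidates <- list()
  log_v <- suppressWarnings(log(shifted))
  if (all(is.finite(log_v)) && stats::sd(log_v) > 0)
    candidates[[paste0(prefix, "log")]] <- log_v
  sqrt_v <- sqrt(shifted)
  if (all(is.finite(sqrt_v)) && stats::sd(sqrt_v) > 0)
    candidates[[paste0(prefix, "sqrt")]] <- sqrt_v
  if (length(candidates) == 0) {
    warning("no valid transform candidate; returning untransformed values")
    return(list(values = values, transform = "none"))
  }
  ps <- vapply(candidates, function(v) stats::shapiro.test(v)$p.value, 0)
  # stable tie-break toward log: candidates listed log first
  best <- names(candidates)[which.max(ps)]
  list(values = candidates[[best]], transform = best)
}

#' Scale a vector to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' vector maps to 0.5 everywhere (uninformative midpoint), with a warning.
#'
#' @param values numeric vector (>= 2 values).
#' @return vector in `[0, 1]`.
#' @export
scale01 <- function(values) {
  if (length(values) < 2 || anyNA(values))
    stop_stage("mf", "need at least 2 complete values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant vector scaled to 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Soil multifunctionality index
#'
#' For each included soil variable: normalize toward a Gaussian shape
#' ([normalize_variable()]), then scale to `[0, 1]` ([scale01()]). The
#' multifunctionality score of a plot is the arithmetic mean of its scaled
#' variable values. Scaling (and the normality decision) uses exactly the
#' plots passed in, so per-site scores are obtained by calling this per site.
#'
#' @param soil soil table (`data.frame` with `sample_id` and the soil
#'   variable columns).
#' @param excluded variables left out of the index (default `"pH"`).
#' @param variables variables to average; defaults to the 12 standard soil
#'   variables minus `excluded`, but any numeric columns of `soil` work.
#' @return a `data.frame` with `sample_id`, `mf`, one `score_<var>` column
#'   per included variable, and a `transforms` attribute mapping variables
#'   to the transform applied.
#' @export
#' @examples
#' soil <- data.frame(sample_id = c("a", "b", "c"),
#'                    var1 = c(0, 5, 10), var2 = c(10, 0, 5))
#' multifunctionality(soil, variables = c("var1", "var2"))$mf
multifunctionality <- function(soil, excluded = "pH",
                               variables = setdiff(SOIL_VARIABLES, excluded)) {
  if (!"sample_id" %in% names(soil))
    stop_stage("mf", "soil table must have a sample_id column")
  if (nrow(soil) < 2) stop_stage("mf", "need at least 2 plots")
  variables <- setdiff(variables, excluded)
  missing <- setdiff(variables, names(soil))
  if (length(missing) > 0)
    stop_stage("mf", "missing soil variable column(s): %s",
               paste(missing, collapse = ", "))
  transforms <- character(0)
  scores <- matrix(NA_real_, nrow(soil), length(variables),
                   dimnames = list(soil$sample_id, variables))
  for (v in variables) {
    nv <- normalize_variable(soil[[v]])
    transforms[v] <- nv$transform
    scores[, v] <- scale01(nv$values)
  }
  out <- data.frame(sample_id = soil$sample_id,
                    mf = rowMeans(scores),
                    stats::setNames(as.data.frame(scores),
                                    paste0("score_", variables)),
                    check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "transforms") <- transforms
  out
}
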