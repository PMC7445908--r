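#' Ordered series of effect estimates
#'
#' A labelled, time-ordered vector of log-rate effect estimates for one
#' model dimension (age groups, period years, or cohort birth ranges).
#'
#' @param labels ordered category labels; when their leading integers
#'   are parseable they must be strictly increasing.
#' @param values finite effect estimates, same length.
#' @param dimension name of the dimension ("age", "period", "cohort").
#' @return Object of class `effect_series`.
#' @export
effect_series <- function(labels, values, dimension = "effect") {
  labels <- as.character(labels)
  values <- as.numeric(values)
  if (length(labels) != length(values))
    abort_validation("labels and values must have the same length",
                     subclass = "apcie_dimension_error")
  if (!all(is.finite(values)))
    abort_validation("effect values must be finite")
  if (anyDuplicated(labels))
    abort_validation("labels must be unique")
  lead <- suppressWarnings(as.numeric(sub("^(-?[0-9]+).*", "\\1", labels)))
  if (!anyNA(lead) && length(lead) > 1L && any(diff(lead) <= 0))
    abort_validation("labels must be strictly ordered in time/age")
  structure(list(labels = labels, values = stats::setNames(values, labels),
                 dimension = dimension),
            class = "effect_series")
}

#' Effect series of one dimension of a fit
#'
#' @param fit an [fit_ie()] result.
#' @param dimension one of "age", "period", "cohort".
#' @return An [effect_series()].
#' @export
get_effects <- function(fit, dimension = c("age", "period", "cohort")) {
  stopifnot(inherits(fit, "apc_fit"))
  dimension <- match.arg(dimension)
  v <- switch(dimension, age = fit$age_effects,
              period = fit$period_effects, cohort = fit$cohort_effects)
  effect_series(names(v), unname(v), dimension)
}

#' @export
print.effect_series <- function(x, ...) {
  cat(sprintf("effect_series (%s), %d categories:\n", x$dimension,
              length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.data.frame.effect_series <- function(x, ...) {
  data.frame(dimension = x$dimension, label = x$labels,
             effect = unname(x$values), stringsAsFactors = FALSE)
}

#' First differences of an effect series
#'
#' Numerical differentiation of the effect curve: the estimated effect
#' at time/age t is subtracted from that at t + 1 and the difference is
#' labelled at t (the change from t to t + 1 is plotted at t).
#'
#' @param series an [effect_series()] with at least 2 categories.
#' @return An `effect_series` of length n - 1 of differences.
#' @export
numerical_diff <- function(series) {
  stopifnot(inherits(series, "effect_series"))
  n <- length(series$values)
  if (n < 2L)
    abort_validation("need at least 2 categories to difference",
                     subclass = "apcie_dimension_error")
  effect_series(series$labels[-n], diff(unname(series$values)),
                dimension = paste0("d_", series$dimension))
}

#' Relative risk implied by two log-rate effects
#'
#' @param effect_from reference effect (log-rate scale).
#' @param effect_to comparison effect.
#' @return `exp(effect_to - effect_from)`; e.g. the cohort effects
#'   0.626 and -1.752 give exp(-2.378) = 0.09 to 2 decimals.
#' @export
relative_risk <- function(effect_from, effect_to) {
  if (!is.finite(effect_from) || !is.finite(effect_to))
    abort_validation("effects must be finite")
  exp(effect_to - effect_from)
}

#' Net change between two categories of an effect series
#'
#' @param series an [effect_series()].
#' @param label_from,label_to category labels present in the series.
#' @return `value(label_to) - value(label_from)`.
#' @export
net_change <- function(series, label_from, label_to) {
  stopifnot(inherits(series, "effect_series"))
  idx <- match(c(label_from, label_to), series$labels)
  if (anyNA(idx))
    abort_validation(sprintf("unknown label '%s'",
                             c(label_from, label_to)[which(is.na(idx))[1]]),
                     subclass = "apcie_lookup_error")
  unname(series$values[idx[2]] - series$values[idx[1]])
}

#' Percent decline in risk between two effects
#'
#' @inheritParams relative_risk
#' @return `(1 - exp(effect_to - effect_from)) * 100`.
#' @export
percent_decline <- function(effect_from, effect_to) {
  (1 - relative_risk(effect_from, effect_to)) * 100
}

#' Annualized change in an effect-difference curve over two windows
#'
#' @param diff_early change in the differenced effect over the early
#'   window; `span_early` its width in years.
#' @param diff_late,span_late same for the late window.
#' @return List with `rate_early`, `rate_late` (per-year changes) and
#'   `ratio = rate_late / rate_early`.
#' @export
annualized_change <- function(diff_early, span_early, diff_late, span_late) {
  if (span_early <= 0 || span_late <= 0)
    abort_validation("window spans must be positive")
  rate_early <- diff_early / span_early
  rate_late <- diff_late / span_late
  list(rate_early = rate_early, rate_late = rate_late,
       ratio = rate_late / rate_early)
}

#' Plot an effect series with its first differences
#'
#' Line plot of the effect estimates (primary axis) with the
#' differenced curve on a secondary axis, mirroring the usual
#' effect-and-change presentation of APC results.
#'
#' @param x an [effect_series()].
#' @param show_changes draw the differenced series on a secondary axis.
#' @param annotations optional character vector of phase labels placed
#'   along the top margin (supplied by the analyst, never computed).
#' @param ... passed to [graphics::plot()].
#' @export
plot.effect_series <- function(x, show_changes = TRUE, annotations = NULL,
                               ...) {
  n <- length(x$values)
  idx <- seq_len(n)
  graphics::plot(idx, unname(x$values), type = "b", pch = 16, col = "blue",
                 xaxt = "n", xlab = x$dimension, ylab = "effect (log rate)",
                 ...)
  graphics::axis(1, at = idx, labels = x$labels, las = 2, cex.axis = 0.7)
  if (show_changes && n >= 2L) {
    d <- numerical_diff(x)
    old <- graphics::par(new = TRUE)
    on.exit(graphics::par(old), add = TRUE)
    graphics::plot(seq_len(n - 1L), unname(d$values), type = "b", pch = 1,
                   col = "darkorange", axes = FALSE, xlab = "", ylab = "",
                   xlim = c(1, n))
    graphics::axis(4, col.axis = "darkorange")
    graphics::mtext("change", side = 4, line = 2, col = "darkorange",
                    cex = 0.8)
  }
  if (!is.null(annotations))
    graphics::mtext(paste(annotations, collapse = "   "), side = 3, line = 0.5,
                    cex = 0.7)
  invisible(x)
}
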