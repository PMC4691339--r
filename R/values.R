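#' Value scale for curated items
#'
#' Bounds of the per-item value scale `[w_min, w_max]`. False positives and
#' redundant items sit at `w_min`; the most valuable conceivable item at
#' `w_max`. The binary scale \[0, 1\] recovers the plain TP/FP picture.
#'
#' @param w_min Minimum item value.
#' @param w_max Maximum item value; must exceed `w_min`.
#' @return An object of class `value_scale`.
#' @export
value_scale <- function(w_min = 0, w_max = 1) {
  stopifnot(is.numeric(w_min), is.numeric(w_max), length(w_min) == 1L,
            length(w_max) == 1L)
  if (!(w_max > w_min)) stop("w_max must exceed w_min", call. = FALSE)
  structure(list(w_min = w_min, w_max = w_max), class = "value_scale")
}

#' @export
print.value_scale <- function(x, ...) {
  cat("<value_scale> [", x$w_min, ", ", x$w_max, "]\n", sep = "")
  invisible(x)
}

check_values <- function(values, scale, what = "values") {
  stopifnot(inherits(scale, "value_scale"))
  if (length(values) == 0) stop(what, " must be non-empty", call. = FALSE)
  if (any(values < scale$w_min - 1e-12 | values > scale$w_max + 1e-12)) {
    stop(what, " must lie within the value scale [", scale$w_min, ", ",
         scale$w_max, "]", call. = FALSE)
  }
  invisible(values)
}

#' Value-weighted overhead
#'
#' Generalizes overhead from binary TP/FP counts to a continuous value
#' scale: the potential value wasted by curating items below the maximum,
#' relative to the value actually created above the minimum,
#' `sum(w_max - w_i) / sum(w_i - w_min)`. On a binary scale with TPs at
#' `w_max` and FPs at `w_min` this is exactly `fp / tp`.
#'
#' @param values Per-item values of the curated (or to-be-curated) set.
#' @param scale A [value_scale()].
#' @return A non-negative ratio; `Inf` when every item sits at `w_min`.
#' @examples
#' overhead_value_weighted(c(1, 1, 0), value_scale(0, 1))  # 0.5, i.e. fp/tp
#' @export
overhead_value_weighted <- function(values, scale = value_scale()) {
  check_values(values, scale)
  num <- sum(scale$w_max - values)
  den <- sum(values - scale$w_min)
  if (den <= 0) return(Inf)
  num / den
}

#' Value- and time-weighted overhead
#'
#' Refines [overhead_value_weighted()] for the case in which items of
#' different value take different mean curation times `T(w_i)`:
#' `sum((w_max - w_i) * T_i) / sum((w_i - w_min) * T_i)`. With equal times
#' the time factor cancels and the value-weighted form is recovered.
#'
#' @inheritParams overhead_value_weighted
#' @param times Per-item curation times, positive, same length as `values`.
#' @return A non-negative ratio; `Inf` when the denominator vanishes.
#' @export
overhead_value_time_weighted <- function(values, times,
                                         scale = value_scale()) {
  check_values(values, scale)
  if (length(times) != length(values)) {
    stop("values and times must have equal length", call. = FALSE)
  }
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  num <- sum((scale$w_max - values) * times)
  den <- sum((values - scale$w_min) * times)
  if (den <= 0) return(Inf)
  num / den
}

#' Probability-adjusted overhead
#'
#' Prospective overhead when each item has only a probability `p_i` of being
#' a true positive. An item contributes its value shortfall weighted by its
#' TP probability, plus the full value span `w_max - w_min` weighted by its
#' FP probability (an FP creates no value at all); value creation in the
#' denominator is likewise discounted by the TP probability:
#'
#' `[sum((w_max - w_i) T_i p_i) + sum((w_max - w_min) T_i (1 - p_i))] /
#'  sum((w_i - w_min) T_i p_i)`
#'
#' With all `p_i = 1` this reduces to [overhead_value_time_weighted()].
#'
#' @inheritParams overhead_value_time_weighted
#' @param probs Per-item TP probabilities in \[0, 1\].
#' @return A non-negative ratio; `Inf` when the expected value creation is 0
#'   (for example all `p_i = 0`).
#' @export
overhead_probability_adjusted <- function(values, times, probs,
                                          scale = value_scale()) {
  check_values(values, scale)
  if (length(times) != length(values) || length(probs) != length(values)) {
    stop("values, times and probs must have equal length", call. = FALSE)
  }
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (any(probs < 0 | probs > 1)) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  num <- sum((scale$w_max - values) * times * probs) +
    sum((scale$w_max - scale$w_min) * times * (1 - probs))
  den <- sum((values - scale$w_min) * times * probs)
  if (den <= 0) return(Inf)
  num / den
}
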