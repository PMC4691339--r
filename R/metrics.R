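#' Confusion counts for one applied filtering strategy
#'
#' Tallies the outcome of applying a filtering strategy to a candidate set:
#' items kept and worth curating (`tp`), items kept but wasteful (`fp`), and
#' optionally items missed (`fn`) and items correctly discarded (`tn`).
#'
#' @param tp Number of true positives (non-negative integer).
#' @param fp Number of false positives (non-negative integer).
#' @param fn Number of false negatives (optional).
#' @param tn Number of true negatives (optional).
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 11, fp = 7)
#' @export
confusion_counts <- function(tp, fp, fn = NA_integer_, tn = NA_integer_) {
  for (nm in c("tp", "fp", "fn", "tn")) {
    x <- get(nm)
    if (length(x) != 1L) stop(nm, " must be a single value", call. = FALSE)
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x != floor(x))) {
      stop(nm, " must be a non-negative integer, got ", x, call. = FALSE)
    }
  }
  if (is.na(tp) || is.na(fp)) stop("tp and fp are required", call. = FALSE)
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp =", x$tp, " fp =", x$fp,
      " fn =", x$fn, " tn =", x$tn, "\n")
  invisible(x)
}

undefined_metric <- function(metric, why) {
  stop(sprintf("metric '%s' is undefined: %s", metric, why), call. = FALSE)
}

#' Precision of a filtering strategy
#'
#' The fraction of filtered items worth curating, `tp / (tp + fp)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Precision as a fraction in \[0, 1\].
#' @examples
#' precision(confusion_counts(tp = 11, fp = 7))  # 11/18
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fp == 0) {
    undefined_metric("precision", "tp + fp = 0 (empty filtered set)")
  }
  counts$tp / (counts$tp + counts$fp)
}

#' Recall of a filtering strategy
#'
#' The fraction of curation-worthy items the strategy retains,
#' `tp / (tp + fn)`.
#'
#' @inheritParams precision
#' @return Recall as a fraction in \[0, 1\].
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (is.na(counts$fn)) {
    undefined_metric("recall", "fn is unknown for these counts")
  }
  if (counts$tp + counts$fn == 0) {
    undefined_metric("recall", "tp + fn = 0 (no positives exist)")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' F-beta measure
#'
#' Weighted harmonic mean of precision and recall,
#' `(beta^2 + 1) * p * r / (beta^2 * p + r)`. `beta = 1` (the default) gives
#' the plain F-measure; `beta < 1` favours precision, `beta > 1` favours
#' recall. When both precision and recall are zero the measure is returned as
#' 0 by convention.
#'
#' @param p Precision, a fraction in \[0, 1\]. Vectorized.
#' @param r Recall, a fraction in \[0, 1\]. Vectorized.
#' @param beta Non-negative weight on recall; defaults to 1.
#' @return The F-beta value, a fraction in \[0, 1\].
#' @examples
#' f_beta(0.9, 0.1)  # 0.18
#' f_beta(0.5, 0.5)  # 0.50
#' @export
f_beta <- function(p, r, beta = 1) {
  if (any(p < 0 | p > 1) || any(r < 0 | r > 1)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  den <- beta^2 * p + r
  out <- ifelse(den > 0, (beta^2 + 1) * p * r / den, 0)
  unname(out)
}

#' Overhead of a filtering strategy (FP-to-TP ratio)
#'
#' Overhead measures the wasted curation effort a strategy imposes: in its
#' simplest form the ratio of false positives to true positives, `fp / tp`.
#' An overhead of 0.33 means one third of the productive effort is spent
#' again on waste.
#'
#' @inheritParams precision
#' @return A non-negative ratio; `Inf` when `tp = 0` with `fp > 0`
#'   (all effort wasted).
#' @examples
#' overhead_simple(confusion_counts(tp = 100, fp = 33))  # 0.33
#' @export
overhead_simple <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp == 0) {
    if (counts$fp == 0) {
      undefined_metric("overhead", "tp = fp = 0 (nothing was filtered)")
    }
    return(Inf)
  }
  counts$fp / counts$tp
}

#' Convert precision to overhead
#'
#' Inverts the identity `precision = 1 / (1 + overhead)`:
#' `overhead = (1 - p) / p`.
#'
#' @param p Precision, a fraction in (0, 1\]. Vectorized.
#' @return Overhead as a non-negative ratio; `Inf` where `p = 0`.
#' @examples
#' overhead_from_precision(0.75)  # 1/3
#' overhead_from_precision(0.85)  # ~0.176
#' @export
overhead_from_precision <- function(p) {
  if (any(p < 0 | p > 1)) stop("precision must lie in [0, 1]", call. = FALSE)
  ifelse(p == 0, Inf, (1 - p) / p)
}

#' Convert overhead to precision
#'
#' `precision = 1 / (1 + overhead)`; the inverse of
#' [overhead_from_precision()].
#'
#' @param o Overhead, a non-negative ratio. Vectorized; `Inf` maps to 0.
#' @return Precision as a fraction in \[0, 1\].
#' @export
precision_from_overhead <- function(o) {
  if (any(o < 0)) stop("overhead must be non-negative", call. = FALSE)
  1 / (1 + o)
}

#' Mean curation times by class
#'
#' Holds the mean time to curate a true positive and a false positive, and
#' optionally the overall mean curation time whose inverse is the curation
#' speed `v`.
#'
#' @param t_tp Mean curation time per TP (> 0).
#' @param t_fp Mean curation time per FP (>= 0); defaults to `t_tp`.
#' @param t_bar Overall mean curation time (optional).
#' @return An object of class `time_model`.
#' @export
time_model <- function(t_tp, t_fp = t_tp, t_bar = NULL) {
  stopifnot(is.numeric(t_tp), length(t_tp) == 1L, t_tp > 0,
            is.numeric(t_fp), length(t_fp) == 1L, t_fp >= 0)
  if (!is.null(t_bar)) stopifnot(is.numeric(t_bar), t_bar > 0)
  structure(list(t_tp = t_tp, t_fp = t_fp, t_bar = t_bar),
            class = "time_model")
}

#' Curation speed implied by a time model
#'
#' The average curation speed `v` is the inverse of the overall mean curation
#' time; when `t_bar` is absent it falls back to the mean of the per-class
#' times.
#'
#' @param tm A [time_model()].
#' @return Items curated per time unit.
#' @export
curation_speed <- function(tm) {
  stopifnot(inherits(tm, "time_model"))
  tbar <- if (!is.null(tm$t_bar)) tm$t_bar else mean(c(tm$t_tp, tm$t_fp))
  1 / tbar
}

#' Time-weighted overhead
#'
#' When curating a false positive takes a different amount of time than
#' curating a true positive, overhead is weighted by the per-class mean
#' times. Two denominator conventions are supported:
#'
#' * `"tp"` (the definitional form): `(fp * t_fp) / (tp * t_tp)` — wasted
#'   time relative to productive time;
#' * `"filtered"`: `(fp * t_fp) / ((tp + fp) * t_tp)` — wasted time relative
#'   to the TP-equivalent time of the whole filtered set, the
#'   first-approximation form used when reporting overhead against the size
#'   of the filtered set.
#'
#' With `t_fp = t_tp` the `"tp"` convention reduces to [overhead_simple()].
#'
#' @inheritParams precision
#' @param tm A [time_model()] with the per-class mean times.
#' @param denominator `"tp"` (default) or `"filtered"`.
#' @return A non-negative ratio; `Inf` when the denominator count is 0 with
#'   `fp > 0`.
#' @examples
#' # 18 filtered abstracts, 11 relevant, TPs take twice as long as FPs:
#' overhead_time_weighted(confusion_counts(tp = 11, fp = 7),
#'                        time_model(t_tp = 2, t_fp = 1),
#'                        denominator = "filtered")  # 7/36, ~19%
#' @export
overhead_time_weighted <- function(counts, tm,
                                   denominator = c("tp", "filtered")) {
  stopifnot(inherits(counts, "confusion_counts"), inherits(tm, "time_model"))
  denominator <- match.arg(denominator)
  den_n <- if (denominator == "tp") counts$tp else counts$tp + counts$fp
  if (den_n == 0) {
    if (counts$fp == 0) {
      undefined_metric("time-weighted overhead", "tp = fp = 0")
    }
    return(Inf)
  }
  (counts$fp * tm$t_fp) / (den_n * tm$t_tp)
}

#' TP production rate
#'
#' The rate at which true positives are produced while curating a filtered
#' set with overhead `o`: `1 / (t_tp * (1 + o))` TPs per time unit. With
#' uniform curation times this equals curation speed times precision.
#'
#' @param tm A [time_model()]; only `t_tp` is used.
#' @param o Overhead, a non-negative ratio (may be `Inf`).
#' @return TPs produced per time unit.
#' @export
tp_production_rate <- function(tm, o) {
  stopifnot(inherits(tm, "time_model"))
  if (any(o < 0)) stop("overhead must be non-negative", call. = FALSE)
  1 / (tm$t_tp * (1 + o))
}

#' False positives produced alongside a target number of TPs
#'
#' A strategy of precision `p` produces `n_tp * (1 - p) / p` false positives
#' for every `n_tp` true positives.
#'
#' @param p Precision, a fraction in (0, 1\].
#' @param n_tp Target number of true positives (>= 0).
#' @param exact If `TRUE`, return the exact (possibly fractional) count;
#'   default rounds to the nearest integer for reporting.
#' @return Number of FPs; `Inf` when `p = 0`.
#' @examples
#' fp_cost_for_target_tps(0.75, 100)  # 33
#' @export
fp_cost_for_target_tps <- function(p, n_tp, exact = FALSE) {
  if (any(p < 0 | p > 1)) stop("precision must lie in [0, 1]", call. = FALSE)
  if (any(n_tp < 0)) stop("n_tp must be non-negative", call. = FALSE)
  out <- ifelse(p == 0, Inf, n_tp * (1 - p) / p)
  if (exact) out else ifelse(is.finite(out), round_half_up(out), out)
}
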