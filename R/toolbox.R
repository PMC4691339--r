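#' A fixed filtering strategy as a precision-recall operating point
#'
#' One strategy in a curation toolbox, described by its operating point in
#' precision-recall space and an optional one-off application cost (time
#' units charged against the project budget when the strategy is deployed).
#'
#' @param name Unique label.
#' @param precision Fraction in (0, 1\].
#' @param recall Fraction in \[0, 1\].
#' @param cost Application cost in time units (>= 0), default 0.
#' @return An object of class `strategy_point`.
#' @export
strategy_point <- function(name, precision, recall, cost = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(precision), length(precision) == 1L,
            is.numeric(recall), length(recall) == 1L,
            is.numeric(cost), length(cost) == 1L, cost >= 0)
  if (!(precision > 0 && precision <= 1)) {
    stop("precision must lie in (0, 1]", call. = FALSE)
  }
  if (recall < 0 || recall > 1) {
    stop("recall must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, precision = precision, recall = recall,
                 cost = cost),
            class = "strategy_point")
}

#' @export
print.strategy_point <- function(x, ...) {
  cat(sprintf("<strategy_point> %s: P = %s, R = %s, cost = %g\n",
              x$name, format_percent(x$precision), format_percent(x$recall),
              x$cost))
  invisible(x)
}

#' An adjustable filtering strategy (monotone precision-recall curve)
#'
#' A strategy whose operating point can be tuned: increasing recall grows the
#' filtered set, adding both TPs and FPs, so precision is non-increasing (and
#' overhead non-decreasing) along the curve. The curve is given as ordered
#' (recall, precision) knots and interpolated linearly between them.
#'
#' @param name Unique label.
#' @param curve Two-column matrix or data frame of (recall, precision) knots;
#'   at least 2 rows, recalls strictly increasing, precisions non-increasing.
#' @param cost Application cost in time units (>= 0), default 0.
#' @return An object of class `adjustable_strategy`.
#' @export
adjustable_strategy <- function(name, curve, cost = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(cost), length(cost) == 1L, cost >= 0)
  curve <- as.matrix(curve)
  if (ncol(curve) != 2L || nrow(curve) < 2L) {
    stop("curve must have 2 columns (recall, precision) and >= 2 knots",
         call. = FALSE)
  }
  colnames(curve) <- c("recall", "precision")
  r <- curve[, "recall"]; p <- curve[, "precision"]
  if (any(r < 0 | r > 1) || any(p <= 0 | p > 1)) {
    stop("curve knots must have recall in [0, 1] and precision in (0, 1]",
         call. = FALSE)
  }
  if (any(diff(r) <= 0)) {
    stop("curve recalls must be strictly increasing", call. = FALSE)
  }
  if (any(diff(p) > 1e-12)) {
    stop("curve precisions must be non-increasing in recall", call. = FALSE)
  }
  structure(list(name = name, curve = curve, cost = cost),
            class = "adjustable_strategy")
}

#' @export
print.adjustable_strategy <- function(x, ...) {
  cat(sprintf("<adjustable_strategy> %s: %d knots, R in [%g, %g], cost = %g\n",
              x$name, nrow(x$curve), min(x$curve[, "recall"]),
              max(x$curve[, "recall"]), x$cost))
  invisible(x)
}

#' A toolbox of filtering strategies
#'
#' The "multiple strategies" approach keeps several filters with different
#' precision-recall trade-offs — like a screwdriver set — and picks the most
#' adequate one per curation project.
#'
#' @param ... [strategy_point()] and/or [adjustable_strategy()] objects, or
#'   lists of them.
#' @return An object of class `curation_toolbox` with elements `fixed` and
#'   `adjustable`.
#' @export
toolbox <- function(...) {
  args <- list(...)
  flat <- list()
  for (a in args) {
    if (inherits(a, c("strategy_point", "adjustable_strategy"))) {
      flat[[length(flat) + 1L]] <- a
    } else if (is.list(a)) {
      flat <- c(flat, a)
    } else {
      stop("toolbox() accepts strategy objects or lists of them",
           call. = FALSE)
    }
  }
  fixed <- Filter(function(s) inherits(s, "strategy_point"), flat)
  adjustable <- Filter(function(s) inherits(s, "adjustable_strategy"), flat)
  if (length(fixed) + length(adjustable) != length(flat)) {
    stop("all toolbox members must be strategy_point or adjustable_strategy",
         call. = FALSE)
  }
  nms <- c(vapply(fixed, `[[`, "", "name"),
           vapply(adjustable, `[[`, "", "name"))
  if (anyDuplicated(nms)) {
    stop("strategy names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(list(fixed = fixed, adjustable = adjustable),
            class = "curation_toolbox")
}

#' @export
print.curation_toolbox <- function(x, ...) {
  cat(sprintf("<curation_toolbox> %d fixed, %d adjustable strategies\n",
              length(x$fixed), length(x$adjustable)))
  invisible(x)
}

n_strategies <- function(tb) length(tb$fixed) + length(tb$adjustable)

#' Does one strategy dominate another?
#'
#' Strategy `a` dominates `b` when it is at least as good on both axes
#' (precision and recall) and strictly better on at least one. A dominated
#' strategy adds no capability to a toolbox.
#'
#' @param a,b [strategy_point()] objects.
#' @return `TRUE` or `FALSE`. Equal points do not dominate each other.
#' @export
dominates <- function(a, b) {
  stopifnot(inherits(a, "strategy_point"), inherits(b, "strategy_point"))
  (a$precision >= b$precision && a$recall >= b$recall) &&
    (a$precision > b$precision || a$recall > b$recall)
}

# All operating points of a toolbox collapsed to a data frame of
# (name, recall, precision); adjustable strategies contribute their knots.
toolbox_points <- function(tb) {
  stopifnot(inherits(tb, "curation_toolbox"))
  rows <- list()
  for (s in tb$fixed) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = s$name, recall = s$recall, precision = s$precision,
                 stringsAsFactors = FALSE)
  }
  for (s in tb$adjustable) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = s$name, recall = s$curve[, "recall"],
                 precision = s$curve[, "precision"],
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(name = character(), recall = numeric(),
                      precision = numeric()))
  }
  do.call(rbind, rows)
}

#' Pareto frontier of a toolbox
#'
#' The maximal (non-dominated) operating points of a toolbox, sorted by
#' recall ascending. Adjustable strategies contribute their knot points.
#' Exact duplicates are collapsed to a single representative.
#'
#' @param tb A [toolbox()].
#' @return A data frame with columns `name`, `recall`, `precision`.
#' @export
pareto_frontier <- function(tb) {
  pts <- toolbox_points(tb)
  if (nrow(pts) == 0) stop("toolbox is empty", call. = FALSE)
  pts <- pts[!duplicated(pts[, c("recall", "precision")]), , drop = FALSE]
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$precision >= pts$precision[i] & pts$recall >= pts$recall[i] &
           (pts$precision > pts$precision[i] | pts$recall > pts$recall[i]))
  }, logical(1))
  out <- pts[keep, , drop = FALSE]
  out <- out[order(out$recall, out$precision), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Piecewise-linear segments (x0, x1, y0, y1) of the precision envelope each
# strategy traces over recall: the region a strategy weakly dominates is
# {(r, p): p <= envelope(r)}. A fixed point yields a flat segment of height
# P over [0, R]; an adjustable curve yields a flat lead-in up to its first
# knot, then its interpolated curve.
strategy_segments <- function(tb) {
  segs <- list()
  add <- function(x0, x1, y0, y1) {
    segs[[length(segs) + 1L]] <<- c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  }
  for (s in tb$fixed) {
    if (s$recall > 0) add(0, s$recall, s$precision, s$precision)
  }
  for (s in tb$adjustable) {
    r <- s$curve[, "recall"]; p <- s$curve[, "precision"]
    if (r[1] > 0) add(0, r[1], p[1], p[1])
    for (i in seq_len(length(r) - 1L)) {
      add(r[i], r[i + 1L], p[i], p[i + 1L])
    }
  }
  if (length(segs) == 0) {
    matrix(numeric(), ncol = 4,
           dimnames = list(NULL, c("x0", "x1", "y0", "y1")))
  } else {
    do.call(rbind, segs)
  }
}

# Evaluate the toolbox's upper precision envelope at recall values r
# (vectorized). Zero outside every strategy's reach.
envelope_at <- function(tb, r) {
  segs <- strategy_segments(tb)
  out <- numeric(length(r))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    inside <- r >= s["x0"] & r <= s["x1"]
    if (any(inside)) {
      yv <- if (s["x1"] > s["x0"]) {
        s["y0"] + (r[inside] - s["x0"]) / (s["x1"] - s["x0"]) *
          (s["y1"] - s["y0"])
      } else {
        pmax(s["y0"], s["y1"])
      }
      out[inside] <- pmax(out[inside], yv)
    }
  }
  out
}

#' Area covered by a toolbox
#'
#' The area of the region of the precision-recall unit square weakly
#' dominated by the toolbox: the union of origin-anchored rectangles
#' `[0, R_i] x [0, P_i]` over all fixed operating points, with adjustable
#' curves contributing the region below their interpolated precision-recall
#' curve. A candidate strategy falling inside this region is inferior to the
#' toolbox. Computed exactly by integrating the upper envelope of the
#' strategies' piecewise-linear precision profiles, splitting at all knot
#' and pairwise-intersection abscissae.
#'
#' @param tb A [toolbox()].
#' @return Area in \[0, 1\]; 0 for an empty toolbox.
#' @export
area_covered <- function(tb) {
  stopifnot(inherits(tb, "curation_toolbox"))
  segs <- strategy_segments(tb)
  if (nrow(segs) == 0) return(0)
  brk <- c(0, segs[, "x0"], segs[, "x1"])
  # pairwise intersections of non-parallel segments over overlapping spans
  n <- nrow(segs)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        a <- segs[i, ]; b <- segs[j, ]
        lo <- max(a["x0"], b["x0"]); hi <- min(a["x1"], b["x1"])
        if (hi <= lo) next
        sa <- (a["y1"] - a["y0"]) / (a["x1"] - a["x0"])
        sb <- (b["y1"] - b["y0"]) / (b["x1"] - b["x0"])
        if (abs(sa - sb) < 1e-14) next
        ia <- a["y0"] - sa * a["x0"]
        ib <- b["y0"] - sb * b["x0"]
        xc <- (ib - ia) / (sa - sb)
        if (xc > lo && xc < hi) brk <- c(brk, xc)
      }
    }
  }
  brk <- sort(unique(pmin(pmax(brk, 0), 1)))
  if (length(brk) < 2) return(0)
  area <- 0
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k]; b <- brk[k + 1L]
    if (b <= a) next
    ya <- envelope_at(tb, a + (b - a) * 1e-9)
    yb <- envelope_at(tb, b - (b - a) * 1e-9)
    area <- area + (ya + yb) / 2 * (b - a)
  }
  area
}

#' Is a candidate strategy inferior to a toolbox?
#'
#' A candidate is inferior when it falls inside the area covered by the
#' toolbox, i.e. when some existing operating point weakly dominates it
#' (precision and recall both no better). An exact duplicate of an existing
#' strategy is inferior: it adds no capability.
#'
#' @param candidate A [strategy_point()].
#' @param tb A [toolbox()].
#' @return `TRUE` or `FALSE`.
#' @export
is_inferior <- function(candidate, tb) {
  stopifnot(inherits(candidate, "strategy_point"),
            inherits(tb, "curation_toolbox"))
  if (n_strategies(tb) == 0) return(FALSE)
  if (candidate$precision <= envelope_at(tb, candidate$recall) + 1e-12) {
    return(TRUE)
  }
  # covers degenerate zero-recall points, which span no envelope segment
  pts <- toolbox_points(tb)
  any(pts$recall >= candidate$recall - 1e-12 &
        pts$precision >= candidate$precision - 1e-12)
}

#' Operating point of an adjustable strategy
#'
#' Tunes an adjustable strategy to a target recall or target precision by
#' linear interpolation between its curve knots. When precision is flat over
#' a recall range, a precision target resolves to the highest recall
#' achieving it (the larger filtered set).
#'
#' @param s An [adjustable_strategy()].
#' @param recall Target recall (give exactly one of `recall`/`precision`).
#' @param precision Target precision.
#' @return A [strategy_point()] at the implied operating point, inheriting
#'   the strategy's name and cost.
#' @export
operating_point <- function(s, recall = NULL, precision = NULL) {
  stopifnot(inherits(s, "adjustable_strategy"))
  if (is.null(recall) == is.null(precision)) {
    stop("give exactly one of recall or precision", call. = FALSE)
  }
  r <- s$curve[, "recall"]; p <- s$curve[, "precision"]
  if (!is.null(recall)) {
    if (recall < r[1] - 1e-12 || recall > r[length(r)] + 1e-12) {
      stop(sprintf("target recall %g outside achievable range [%g, %g]",
                   recall, r[1], r[length(r)]), call. = FALSE)
    }
    pr <- stats::approx(r, p, xout = recall, rule = 2)$y
    return(strategy_point(s$name, pr, min(max(recall, r[1]), r[length(r)]),
                          s$cost))
  }
  pmin_ <- p[length(p)]; pmax_ <- p[1]
  if (precision < pmin_ - 1e-12 || precision > pmax_ + 1e-12) {
    stop(sprintf("target precision %g outside achievable range [%g, %g]",
                 precision, pmin_, pmax_), call. = FALSE)
  }
  # invert the non-increasing curve; ties resolve to the largest recall
  rc <- max(r[p >= precision - 1e-12], r[1])
  idx <- which(p < precision - 1e-12)
  if (length(idx) > 0) {
    j <- idx[1]  # precision crosses the target between knots j-1 and j
    r0 <- r[j - 1L]; r1 <- r[j]; p0 <- p[j - 1L]; p1 <- p[j]
    rc <- max(rc, r0 + (p0 - precision) / (p0 - p1) * (r1 - r0))
  }
  strategy_point(s$name, precision, rc, s$cost)
}

#' Expected output size of a strategy on a project
#'
#' Connects an operating point to concrete item counts: on a candidate set
#' of `n` items of which a fraction `base_rate` is truly valuable, a
#' strategy retains `n * base_rate * recall` expected TPs, and the expected
#' filtered-set size is that count divided by precision.
#'
#' @param s A [strategy_point()].
#' @param n Candidate-set size.
#' @param base_rate Prevalence of valuable items, a fraction in (0, 1\].
#' @return A list with `tps` (expected true positives) and `m` (expected
#'   filtered-set size).
#' @export
expected_output_size <- function(s, n, base_rate) {
  stopifnot(inherits(s, "strategy_point"), n > 0)
  if (!(base_rate > 0 && base_rate <= 1)) {
    stop("base_rate must lie in (0, 1]", call. = FALSE)
  }
  tps <- n * base_rate * s$recall
  m <- if (s$recall == 0) 0 else tps / s$precision
  if (m > n + 1e-9) {
    stop(sprintf(paste0("inconsistent inputs: recall %g, precision %g and ",
                        "base rate %g imply %g filtered items out of %d"),
                 s$recall, s$precision, base_rate, m, n), call. = FALSE)
  }
  list(tps = tps, m = m)
}

# Expected curation time for a strategy's output (excludes application cost).
expected_curation_time <- function(s, n, base_rate, tm) {
  sz <- expected_output_size(s, n, base_rate)
  sz$tps * tm$t_tp + (sz$m - sz$tps) * tm$t_fp
}

#' Select the most adequate strategy for a project
#'
#' Among all strategies in a toolbox, finds the one maximizing expected
#' curated TPs subject to the resource constraint: the expected time to
#' curate its output, plus the strategy's application cost, must fit within
#' the time budget. Adjustable strategies contribute their best feasible
#' operating point (the highest feasible recall, found by root-solving the
#' time constraint along the curve). When curation resources are scarce a
#' high-precision/low-recall strategy wins despite a low F-measure, because
#' its small output is the only one that fits the budget.
#'
#' @param tb A [toolbox()].
#' @param n Candidate-set size.
#' @param base_rate Prevalence of valuable items, in (0, 1\].
#' @param tm A [time_model()] with per-class mean curation times.
#' @param t_max Time budget.
#' @return An object of class `strategy_selection`: `chosen` (a
#'   [strategy_point()], or `NULL` if nothing is feasible), `feasible`
#'   flag, and `options`, a data frame listing every option with its
#'   feasibility verdict, expected `m`, expected TPs, expected time and
#'   overhead. Infeasibility is reported via the smallest achievable option
#'   versus the budget.
#' @export
select_strategy <- function(tb, n, base_rate, tm, t_max) {
  stopifnot(inherits(tb, "curation_toolbox"), inherits(tm, "time_model"),
            t_max > 0)
  if (n_strategies(tb) == 0) stop("toolbox is empty", call. = FALSE)
  opts <- list()
  add_opt <- function(pt, adjustable = FALSE) {
    sz <- expected_output_size(pt, n, base_rate)
    time <- sz$tps * tm$t_tp + (sz$m - sz$tps) * tm$t_fp + pt$cost
    opts[[length(opts) + 1L]] <<- list(
      point = pt,
      row = data.frame(
        name = pt$name, adjustable = adjustable, recall = pt$recall,
        precision = pt$precision, m = sz$m, tps = sz$tps,
        time = time, cost = pt$cost,
        overhead = overhead_from_precision(pt$precision),
        feasible = time <= t_max + 1e-9, stringsAsFactors = FALSE))
  }
  for (s in tb$fixed) add_opt(s)
  for (s in tb$adjustable) {
    budget <- t_max - s$cost
    r <- s$curve[, "recall"]
    lo_pt <- operating_point(s, recall = r[1])
    if (budget <= 0 ||
        expected_curation_time(lo_pt, n, base_rate, tm) > budget) {
      add_opt(lo_pt, adjustable = TRUE)  # recorded as infeasible
      next
    }
    hi_pt <- operating_point(s, recall = r[length(r)])
    if (expected_curation_time(hi_pt, n, base_rate, tm) <= budget) {
      add_opt(hi_pt, adjustable = TRUE)
      next
    }
    # time is increasing in recall: solve for the budget-exhausting recall
    f <- function(rc) {
      expected_curation_time(operating_point(s, recall = rc),
                             n, base_rate, tm) - budget
    }
    rc <- stats::uniroot(f, c(r[1], r[length(r)]), tol = 1e-10)$root
    add_opt(operating_point(s, recall = rc), adjustable = TRUE)
  }
  tab <- do.call(rbind, lapply(opts, `[[`, "row"))
  rownames(tab) <- NULL
  feas <- which(tab$feasible)
  if (length(feas) == 0) {
    chosen <- NULL
    smallest <- which.min(tab$time)
    verdict <- sprintf(
      "infeasible: smallest achievable option '%s' needs %.4g time units but the budget is %.4g",
      tab$name[smallest], tab$time[smallest], t_max)
  } else {
    # maximize TPs; ties: lower overhead, then smaller m, then name
    ord <- feas[order(-tab$tps[feas], tab$overhead[feas], tab$m[feas],
                      tab$name[feas])]
    best <- ord[1]
    chosen <- opts[[best]]$point
    verdict <- sprintf("chose '%s' with %.4g expected TPs", tab$name[best],
                       tab$tps[best])
  }
  structure(list(chosen = chosen, feasible = length(feas) > 0,
                 verdict = verdict, options = tab, t_max = t_max),
            class = "strategy_selection")
}

#' @export
print.strategy_selection <- function(x, ...) {
  cat("<strategy_selection>", x$verdict, "\n")
  print(x$options)
  invisible(x)
}
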