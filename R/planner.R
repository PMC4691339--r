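#' Build an item table for a curation project
#'
#' Validates and normalizes a data frame of curable items. Each row is one
#' curable unit (an abstract, a sentence, an interaction record, ...) with an
#' estimated value on the project's value scale, an estimated curation time,
#' and optionally a TP probability, a ground-truth value and a gold label
#' for retrospective evaluation.
#'
#' @param items Data frame with columns `id`, `est_value`, `est_time` and
#'   optionally `duplicate_key` (defaults to `id`), `true_value`, `p_tp`,
#'   `gold_label` (`"TP"`/`"FP"`), `redundant`.
#' @return The validated data frame with all columns present (optional ones
#'   filled with `NA`) and a `redundant` logical column.
#' @export
item_table <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  req <- c("id", "est_value", "est_time")
  miss <- setdiff(req, names(items))
  if (length(miss) > 0) {
    stop("item table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(items) == 0) stop("item table is empty", call. = FALSE)
  items$id <- as.character(items$id)
  if (anyDuplicated(items$id)) {
    stop("duplicate item id(s): ",
         paste(unique(items$id[duplicated(items$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(items$duplicate_key)) items$duplicate_key <- items$id
  items$duplicate_key <- ifelse(is.na(items$duplicate_key), items$id,
                                as.character(items$duplicate_key))
  for (col in c("true_value", "p_tp")) {
    if (is.null(items[[col]])) items[[col]] <- NA_real_
  }
  if (is.null(items$gold_label)) items$gold_label <- NA_character_
  if (is.null(items$redundant)) items$redundant <- FALSE
  bad <- which(!is.finite(items$est_time) | items$est_time <= 0)
  if (length(bad) > 0) {
    stop("est_time must be positive; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(items$p_tp) & (items$p_tp < 0 | items$p_tp > 1))
  if (length(bad) > 0) {
    stop("p_tp must lie in [0, 1]; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(items$gold_label) &
                 !items$gold_label %in% c("TP", "FP"))
  if (length(bad) > 0) {
    stop("gold_label must be 'TP' or 'FP'; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cols <- c("id", "duplicate_key", "true_value", "est_value", "p_tp",
            "est_time", "gold_label", "redundant")
  items[, c(cols, setdiff(names(items), cols)), drop = FALSE]
}

#' A curation project
#'
#' Bundles a set of curable items with the resources available to curate
#' them: a time budget `t_max`, optionally an average curation speed `v`
#' (items per time unit; derived from the mean estimated item time when
#' absent), and the value scale the item values live on.
#'
#' @param name Project label.
#' @param items An [item_table()] (or data frame coercible to one).
#' @param t_max Time budget (> 0).
#' @param speed Average curation speed `v` in items per time unit
#'   (optional).
#' @param scale A [value_scale()]; defaults to the binary \[0, 1\] scale.
#' @return An object of class `curation_project`.
#' @export
curation_project <- function(name, items, t_max, speed = NULL,
                             scale = value_scale()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(t_max), length(t_max) == 1L, t_max > 0,
            inherits(scale, "value_scale"))
  if (!is.null(speed)) stopifnot(is.numeric(speed), speed > 0)
  items <- item_table(items)
  check_values(items$est_value, scale, "est_value")
  if (any(!is.na(items$true_value))) {
    check_values(items$true_value[!is.na(items$true_value)], scale,
                 "true_value")
  }
  structure(list(name = name, items = items, t_max = t_max, speed = speed,
                 scale = scale),
            class = "curation_project")
}

#' @export
print.curation_project <- function(x, ...) {
  cat(sprintf("<curation_project> '%s': %d items, t_max = %g%s\n",
              x$name, nrow(x$items), x$t_max,
              if (is.null(x$speed)) "" else sprintf(", v = %g", x$speed)))
  invisible(x)
}

project_speed <- function(project) {
  if (!is.null(project$speed)) project$speed
  else 1 / mean(project$items$est_time)
}

#' Are the project's resources sufficient?
#'
#' A project with `n` candidate items, curation speed `v` and time budget
#' `t_max` has sufficient resources when `v * t_max >= n` (the boundary
#' counts as sufficient): every candidate can be curated and no filtering
#' is strictly necessary. Otherwise resources are insufficient and a
#' filtering strategy must reduce the candidate set.
#'
#' @param project A [curation_project()].
#' @return A list with `verdict` (`"sufficient"`/`"insufficient"`),
#'   `slack` (`v * t_max - n`, in items), and `time_slack`
#'   (`t_max - sum(est_time)`, in time units).
#' @export
feasibility <- function(project) {
  stopifnot(inherits(project, "curation_project"))
  n <- nrow(project$items)
  v <- project_speed(project)
  slack <- v * project$t_max - n
  list(verdict = if (slack >= 0) "sufficient" else "insufficient",
       slack = slack, n = n, v = v,
       time_slack = project$t_max - sum(project$items$est_time))
}

# Deterministic curation order: highest estimated value first; ties broken
# by shorter estimated time, then id.
rank_items <- function(items) {
  items[order(-items$est_value, items$est_time, items$id), , drop = FALSE]
}

#' Rank items by value and schedule curation under the time budget
#'
#' Implements the rank-and-curate strategy: sort items by estimated value
#' descending and curate down the list while the budget lasts. This needs no
#' estimate of the curation speed `v` — curation simply stops when time runs
#' out. An item whose estimated time exceeds the remaining budget is skipped
#' and the next-ranked item is tried, which never decreases the total value
#' curated. Ties on value are broken by shorter estimated time, then by id.
#'
#' @param project A [curation_project()].
#' @return An object of class `curation_schedule`: `curated` (ordered item
#'   ids), `leftover` (uncurated ids), `total_time`, `value_sum` (sum of
#'   estimated values curated), and `metrics` — realized metrics from
#'   [curate()] when ground truth is available, else `NULL`.
#' @export
rank_and_schedule <- function(project) {
  stopifnot(inherits(project, "curation_project"))
  ranked <- rank_items(project$items)
  remaining <- project$t_max
  take <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    if (ranked$est_time[i] <= remaining + 1e-12) {
      take[i] <- TRUE
      remaining <- remaining - ranked$est_time[i]
    }
  }
  curated <- ranked$id[take]
  sched <- structure(
    list(curated = curated,
         leftover = setdiff(project$items$id, curated),
         total_time = sum(ranked$est_time[take]),
         value_sum = sum(ranked$est_value[take]),
         t_max = project$t_max,
         metrics = NULL),
    class = "curation_schedule")
  has_truth <- any(!is.na(project$items$gold_label)) ||
    any(!is.na(project$items$true_value))
  if (has_truth && length(curated) > 0) {
    sched$metrics <- tryCatch(curate(project, sched), error = function(e) NULL)
  }
  sched
}

#' @export
print.curation_schedule <- function(x, ...) {
  cat(sprintf(
    "<curation_schedule> %d curated, %d left over, time %.4g / %.4g\n",
    length(x$curated), length(x$leftover), x$total_time, x$t_max))
  invisible(x)
}

#' Drop items below a minimum estimated value
#'
#' Applies an absolute value floor: items whose estimated value falls below
#' `w_floor` are removed before any scheduling, saving their curation time
#' for other work (or other projects). The floor plays the role a
#' significance threshold like a BLAST E-value cutoff plays in sequence
#' analysis: an absolute bar, set in advance.
#'
#' @param project A [curation_project()].
#' @param w_floor Minimum acceptable estimated value; must lie within the
#'   project's value scale.
#' @return The project with sub-floor items removed; the number removed is
#'   attached as attribute `n_removed`.
#' @export
apply_value_floor <- function(project, w_floor) {
  stopifnot(inherits(project, "curation_project"))
  sc <- project$scale
  if (w_floor < sc$w_min || w_floor > sc$w_max) {
    stop(sprintf("value floor %g outside the value scale [%g, %g]",
                 w_floor, sc$w_min, sc$w_max), call. = FALSE)
  }
  keep <- project$items$est_value >= w_floor
  if (!any(keep)) {
    stop("value floor removes every item in project '", project$name, "'",
         call. = FALSE)
  }
  out <- project
  out$items <- project$items[keep, , drop = FALSE]
  rownames(out$items) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Devalue redundant items
#'
#' Items already curated elsewhere (their `duplicate_key` appears in
#' `prior_keys`) or repeated within the project (first occurrence kept)
#' carry no novelty, so they are assigned the same value as a false
#' positive — the scale minimum `w_min` — and tagged `redundant`. The
#' operation is idempotent.
#'
#' @param project A [curation_project()].
#' @param prior_keys Character vector of duplicate keys curated previously.
#' @return The project with redundant items devalued and tagged.
#' @export
mark_redundant <- function(project, prior_keys = character()) {
  stopifnot(inherits(project, "curation_project"))
  items <- project$items
  red <- items$duplicate_key %in% prior_keys |
    duplicated(items$duplicate_key)
  items$est_value[red] <- project$scale$w_min
  items$redundant <- items$redundant | red
  out <- project
  out$items <- items
  out
}

#' Rank items by expected value under TP uncertainty
#'
#' Combines the two filtering criteria available before curation — the
#' estimated value of an item and its estimated probability of being a TP —
#' into a single expected value, treating a would-be FP as worth the scale
#' minimum: `p_tp * est_value + (1 - p_tp) * w_min`. Items are returned in
#' descending order of this expected value (stable for ties).
#'
#' @param items An [item_table()] with `p_tp` present for every row.
#' @param scale A [value_scale()].
#' @return The item table, reordered, with an `expected_value` column.
#' @export
expected_value_rank <- function(items, scale = value_scale()) {
  items <- item_table(items)
  missing_p <- is.na(items$p_tp)
  if (any(missing_p)) {
    stop("p_tp missing for item(s): ",
         paste(items$id[missing_p], collapse = ", "), call. = FALSE)
  }
  items$expected_value <- items$p_tp * items$est_value +
    (1 - items$p_tp) * scale$w_min
  out <- items[order(-items$expected_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a schedule against ground truth
#'
#' Recomputes all applicable metrics on the realized outcome of a schedule:
#' confusion counts from gold labels, precision, simple and time-weighted
#' overhead (both denominator conventions, with per-class mean times taken
#' from the curated items), value-weighted overhead and value sum from true
#' values, the realized TP production rate, and the estimation error (mean
#' absolute difference between estimated and true values).
#'
#' @param project A [curation_project()] whose items carry `gold_label`
#'   and/or `true_value`.
#' @param schedule A [rank_and_schedule()] result (or any list with a
#'   `curated` vector of item ids and a `total_time`).
#' @return A list of realized metrics.
#' @export
curate <- function(project, schedule) {
  stopifnot(inherits(project, "curation_project"))
  cur <- project$items[match(schedule$curated, project$items$id), ,
                       drop = FALSE]
  if (nrow(cur) == 0) stop("schedule curates no items", call. = FALSE)
  has_gold <- all(!is.na(cur$gold_label))
  has_true <- all(!is.na(cur$true_value))
  if (!has_gold && !has_true) {
    stop("evaluation requires gold_label or true_value on every curated item",
         call. = FALSE)
  }
  out <- list(n_curated = nrow(cur), total_time = schedule$total_time)
  if (has_gold) {
    tp <- sum(cur$gold_label == "TP")
    fp <- sum(cur$gold_label == "FP")
    counts <- confusion_counts(tp, fp)
    out$counts <- counts
    out$precision <- if (tp + fp > 0) precision(counts) else NA_real_
    out$overhead <- overhead_simple(counts)
    t_tp <- if (tp > 0) mean(cur$est_time[cur$gold_label == "TP"]) else NA
    t_fp <- if (fp > 0) mean(cur$est_time[cur$gold_label == "FP"]) else 0
    if (!is.na(t_tp)) {
      tm <- time_model(t_tp, t_fp)
      out$time_model <- tm
      out$overhead_time_weighted <- overhead_time_weighted(counts, tm)
      out$overhead_time_weighted_filtered <-
        overhead_time_weighted(counts, tm, denominator = "filtered")
      out$tp_rate <- tp / schedule$total_time
    }
  }
  if (has_true) {
    out$value_sum <- sum(cur$true_value)
    out$overhead_value_weighted <-
      overhead_value_weighted(cur$true_value, project$scale)
    out$overhead_value_time_weighted <-
      overhead_value_time_weighted(cur$true_value, cur$est_time,
                                   project$scale)
    out$estimation_error <- mean(abs(cur$est_value - cur$true_value))
  }
  out
}

# Overhead contributed by one project under a given time budget: the
# value-weighted (or simple) overhead of the items rank-and-schedule curates
# within that budget, from estimated values. A budget too small to curate
# anything contributes a worst case - by default the overhead of curating
# only the project's single worst item - so the optimizer cannot "solve" a
# project by starving it.
project_overhead_at_budget <- function(project, budget,
                                       type = c("value", "simple"),
                                       worst_case = NULL) {
  type <- match.arg(type)
  ov <- function(items) {
    if (type == "value") {
      overhead_value_weighted(items$est_value, project$scale)
    } else {
      tp <- sum(items$est_value > project$scale$w_min)
      fp <- nrow(items) - tp
      if (tp == 0) Inf else fp / tp
    }
  }
  if (budget <= 0 || all(project$items$est_time > budget + 1e-12)) {
    if (!is.null(worst_case)) return(worst_case)
    worst <- project$items[which.min(project$items$est_value), , drop = FALSE]
    return(ov(worst))
  }
  p <- project
  p$t_max <- budget
  sched <- rank_and_schedule(p)
  cur <- p$items[match(sched$curated, p$items$id), , drop = FALSE]
  ov(cur)
}

#' Allocate a global time budget across curation projects
#'
#' Splits a total time budget among competing curation projects so that the
#' sum of per-project overheads is minimized, subject to the budgets summing
#' exactly to the total. Time is discretized into quanta; each candidate
#' budget for a project is scored by the value-weighted overhead of the
#' items its value-ranked schedule would curate under that budget. For small
#' instances the quanta-composition space is enumerated exhaustively;
#' otherwise a greedy marginal-improvement pass followed by pairwise
#' exchange is used (certified against the exhaustive solution at small
#' scale in the test suite).
#'
#' @param projects List of [curation_project()] objects.
#' @param t_max_total Global time budget (> 0).
#' @param quantum Time quantum; must divide `t_max_total` into at most
#'   `1e5` quanta.
#' @param overhead_type `"value"` (default) or `"simple"` — which overhead
#'   enters the objective.
#' @param exhaustive_limit Enumerate exhaustively when the number of
#'   compositions is at most this (default `1e4`).
#' @return An object of class `allocation_plan`: a data frame `allocation`
#'   with per-project budgets and overheads, and the `objective`
#'   (sum of overheads). Budgets sum exactly to `t_max_total`.
#' @export
allocate_time <- function(projects, t_max_total, quantum,
                          overhead_type = c("value", "simple"),
                          exhaustive_limit = 1e4) {
  overhead_type <- match.arg(overhead_type)
  if (length(projects) == 0) stop("no projects to allocate to", call. = FALSE)
  stopifnot(all(vapply(projects, inherits, TRUE, "curation_project")),
            t_max_total > 0, quantum > 0)
  if (quantum > t_max_total) {
    stop("quantum exceeds the total budget", call. = FALSE)
  }
  K <- t_max_total / quantum
  if (abs(K - round(K)) > 1e-9) {
    stop("quantum must divide t_max_total evenly", call. = FALSE)
  }
  K <- as.integer(round(K))
  if (K > 1e5) stop("more than 1e5 time quanta; increase the quantum",
                    call. = FALSE)
  J <- length(projects)
  # memoized objective per project and per budget in quanta (0..K)
  obj <- matrix(NA_real_, nrow = J, ncol = K + 1L)
  o_of <- function(j, b) {
    if (is.na(obj[j, b + 1L])) {
      obj[j, b + 1L] <<- project_overhead_at_budget(
        projects[[j]], b * quantum, type = overhead_type)
    }
    obj[j, b + 1L]
  }
  total <- function(bud) sum(vapply(seq_len(J), function(j) o_of(j, bud[j]),
                                    numeric(1)))
  n_comp <- choose(K + J - 1, J - 1)
  if (J == 1) {
    bud <- K
  } else if (n_comp <= exhaustive_limit) {
    compositions <- function(k, parts) {
      if (parts == 1) return(matrix(k, ncol = 1))
      out <- list()
      for (first in 0:k) {
        rest <- compositions(k - first, parts - 1)
        out[[length(out) + 1L]] <- cbind(first, rest)
      }
      do.call(rbind, out)
    }
    comps <- compositions(K, J)
    objs <- apply(comps, 1, total)
    bud <- comps[which.min(objs), ]
  } else {
    # greedy: hand out quanta one at a time to the largest marginal gain
    bud <- integer(J)
    for (step in seq_len(K)) {
      gain <- vapply(seq_len(J), function(j) {
        a <- o_of(j, bud[j]); b <- o_of(j, bud[j] + 1L)
        if (is.infinite(a) && is.infinite(b)) 0
        else if (is.infinite(a)) Inf
        else a - b
      }, numeric(1))
      j <- which.max(gain)
      bud[j] <- bud[j] + 1L
    }
    # pairwise exchange: shifting any number of quanta between any pair
    # must not improve the objective (escapes local optima the one-quantum
    # greedy can fall into when a project's overhead drops in steps)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      cur <- total(bud)
      for (from in seq_len(J)) {
        for (to in seq_len(J)) {
          if (to == from || bud[from] == 0) next
          for (q in seq_len(bud[from])) {
            cand <- bud
            cand[from] <- cand[from] - q
            cand[to] <- cand[to] + q
            if (total(cand) < cur - 1e-12) {
              bud <- cand
              cur <- total(cand)
              improved <- TRUE
              break
            }
          }
        }
      }
    }
  }
  bud <- as.integer(bud)
  alloc <- data.frame(
    project = vapply(projects, `[[`, "", "name"),
    budget = bud * quantum,
    quanta = bud,
    overhead = vapply(seq_len(J), function(j) o_of(j, bud[j]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(allocation = alloc, objective = sum(alloc$overhead),
                 t_max_total = t_max_total, quantum = quantum),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf("<allocation_plan> total budget %g, objective sum(O_j) = %.4g\n",
              x$t_max_total, x$objective))
  print(x$allocation)
  invisible(x)
}
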