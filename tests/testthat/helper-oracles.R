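# Independent oracles and random-fixture generators used across the suite.
# These re-derive results from first principles (brute force, enumeration,
# grid counting) without calling the code paths they check.

# Random toolbox of fixed points; recalls/precisions away from 0 so every
# point spans an envelope segment.
random_toolbox <- function(n_points, seed) {
  set.seed(seed)
  pts <- lapply(seq_len(n_points), function(i) {
    strategy_point(paste0("s", i),
                   precision = runif(1, 0.05, 1),
                   recall = runif(1, 0.05, 1))
  })
  do.call(toolbox, pts)
}

# Grid-counting oracle for the area covered: fraction of cell centers of a
# res x res grid weakly dominated by at least one strategy. Adjustable
# curves are evaluated with stats::approx directly from their knots.
grid_area_oracle <- function(tb, res = 1000) {
  r_mid <- (seq_len(res) - 0.5) / res
  env <- numeric(res)
  for (s in tb$fixed) {
    env <- pmax(env, ifelse(r_mid <= s$recall, s$precision, 0))
  }
  for (s in tb$adjustable) {
    r <- s$curve[, "recall"]; p <- s$curve[, "precision"]
    curve_p <- approx(r, p, xout = r_mid, rule = 2)$y
    curve_p[r_mid > r[length(r)]] <- 0  # beyond the curve's reach
    env <- pmax(env, curve_p)
  }
  # cells whose p-center (j - 0.5)/res lies at or below the envelope
  sum(pmin(floor(env * res + 0.5), res)) / res^2
}

# Brute-force pairwise-dominance frontier over a point data frame.
brute_frontier <- function(pts) {
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$precision >= pts$precision[i] & pts$recall >= pts$recall[i] &
           (pts$precision > pts$precision[i] | pts$recall > pts$recall[i]))
  }, logical(1))
  out <- unique(pts[keep, c("recall", "precision")])
  out[order(out$recall, out$precision), ]
}

# Best achievable sum of estimated value over all feasible subsets
# (exhaustive; instances must stay small).
brute_best_value <- function(values, times, t_max) {
  n <- length(values)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    if (sum(times[sel]) <= t_max + 1e-12) {
      best <- max(best, sum(values[sel]))
    }
  }
  best
}

# Exhaustive allocation oracle: minimal sum of overheads over every
# composition of k quanta among the projects, scoring each budget with the
# same per-project overhead rule as the allocator (value-weighted overhead
# of the value-ranked schedule, worst-item fallback when nothing fits).
brute_allocation_objective <- function(projects, k, quantum) {
  J <- length(projects)
  score <- function(project, budget) {
    fits <- project$items$est_time <= budget + 1e-12
    if (budget <= 0 || !any(fits)) {
      worst <- which.min(project$items$est_value)
      return(overhead_value_weighted(project$items$est_value[worst],
                                     project$scale))
    }
    p <- project
    p$t_max <- budget
    sched <- rank_and_schedule(p)
    idx <- match(sched$curated, project$items$id)
    overhead_value_weighted(project$items$est_value[idx], project$scale)
  }
  comps <- expand.grid(rep(list(0:k), J))
  comps <- comps[rowSums(comps) == k, , drop = FALSE]
  objs <- apply(comps, 1, function(bud) {
    sum(vapply(seq_len(J), function(j) score(projects[[j]],
                                             bud[j] * quantum),
               numeric(1)))
  })
  min(objs)
}

# Whole-percent value of a fraction, via the exported rendering.
pct <- function(x) as.numeric(sub("%", "", format_percent(x)))

# Small random item table with ground truth.
random_items <- function(n, seed, base_rate = 0.5) {
  set.seed(seed)
  tp <- runif(n) < base_rate
  data.frame(
    id = paste0("i", seq_len(n)),
    true_value = ifelse(tp, 1, 0),
    est_value = ifelse(tp, 1, 0),
    p_tp = round(runif(n), 6),
    est_time = round(runif(n, 0.5, 2), 6),
    gold_label = ifelse(tp, "TP", "FP"),
    stringsAsFactors = FALSE)
}
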