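make_project <- function(values, times = rep(1, length(values)), t_max,
                         labels = NULL, true_values = NULL,
                         scale = value_scale(), name = "test") {
  items <- data.frame(
    id = sprintf("x%02d", seq_along(values)),
    est_value = values, est_time = times, stringsAsFactors = FALSE)
  if (!is.null(labels)) items$gold_label <- labels
  if (!is.null(true_values)) items$true_value <- true_values
  curation_project(name, items, t_max = t_max, scale = scale)
}

test_that("resource feasibility compares v * t_max with n", {
  items <- data.frame(id = paste0("a", 1:15), est_value = 1, est_time = 0.5)
  p <- curation_project("p", items, t_max = 10, speed = 2)
  f <- feasibility(p)
  expect_equal(f$verdict, "sufficient")
  expect_equal(f$slack, 5)

  boundary <- curation_project("b", items, t_max = 7.5, speed = 2)
  expect_equal(feasibility(boundary)$verdict, "sufficient")
  expect_equal(feasibility(boundary)$slack, 0)

  items100 <- data.frame(id = paste0("a", 1:100), est_value = 1,
                         est_time = 1)
  starved <- curation_project("s", items100, t_max = 1, speed = 1)
  expect_equal(feasibility(starved)$verdict, "insufficient")
  # speed derived from mean est_time when absent
  nospeed <- curation_project("ns", items, t_max = 10)
  expect_equal(feasibility(nospeed)$v, 2)
})

test_that("rank-and-schedule curates by descending value until time runs out", {
  p <- make_project(values = c(3, 1, 2), t_max = 2,
                    scale = value_scale(0, 3))
  s <- rank_and_schedule(p)
  expect_equal(s$curated, c("x01", "x03"))
  expect_equal(s$value_sum, 5)
  expect_equal(s$leftover, "x02")

  all_fit <- make_project(values = c(3, 1, 2), t_max = 10,
                          scale = value_scale(0, 3))
  expect_length(rank_and_schedule(all_fit)$curated, 3)

  none_fit <- make_project(values = c(3, 1, 2), times = rep(5, 3), t_max = 2,
                           scale = value_scale(0, 3))
  s0 <- rank_and_schedule(none_fit)
  expect_length(s0$curated, 0)
  expect_equal(s0$total_time, 0)
})

test_that("greedy schedule is value-optimal with uniform times", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    values <- round(runif(n), 4)
    t_max <- sample(seq_len(n), 1)
    p <- make_project(values, times = rep(1, n), t_max = t_max)
    s <- rank_and_schedule(p)
    expect_equal(s$value_sum, brute_best_value(values, rep(1, n), t_max))
    expect_lte(s$total_time, t_max + 1e-12)
    expect_setequal(c(s$curated, s$leftover), p$items$id)
  }
})

test_that("an item too long for the remaining budget is skipped, not fatal", {
  p <- make_project(values = c(1.0, 0.9, 0.8), times = c(2, 5, 1), t_max = 3)
  s <- rank_and_schedule(p)
  expect_equal(s$curated, c("x01", "x03"))
})

test_that("value floor trims sub-floor items and rejects bad floors", {
  p <- make_project(values = c(0.2, 0.6, 0.9), t_max = 10)
  trimmed <- apply_value_floor(p, 0.5)
  expect_equal(nrow(trimmed$items), 2)
  expect_equal(attr(trimmed, "n_removed"), 1)
  unchanged <- apply_value_floor(p, 0)
  expect_equal(nrow(unchanged$items), 3)
  expect_error(apply_value_floor(p, 1.1), "outside the value scale")
  # floor-then-schedule equals schedule-then-drop when curated values pass
  s_floor <- rank_and_schedule(apply_value_floor(p, 0.5))
  s_plain <- rank_and_schedule(p)
  kept <- s_plain$curated[p$items$est_value[match(s_plain$curated,
                                                  p$items$id)] >= 0.5]
  expect_equal(s_floor$curated, kept)
})

test_that("redundant items are devalued to w_min, idempotently", {
  items <- data.frame(
    id = c("a", "b", "c"),
    duplicate_key = c("k1", "k1", "k2"),
    est_value = c(0.9, 0.8, 0.7), est_time = 1,
    stringsAsFactors = FALSE)
  p <- curation_project("r", items, t_max = 10)
  m1 <- mark_redundant(p)
  expect_equal(m1$items$est_value, c(0.9, 0, 0.7))
  expect_equal(m1$items$redundant, c(FALSE, TRUE, FALSE))
  expect_equal(mark_redundant(m1)$items, m1$items)  # idempotent

  prior <- mark_redundant(p, prior_keys = "k2")
  expect_equal(prior$items$est_value, c(0.9, 0, 0))
  disjoint <- mark_redundant(p, prior_keys = "unseen")
  expect_equal(disjoint$items$est_value[1], 0.9)
  expect_equal(disjoint$items$est_value[3], 0.7)
})

test_that("expected-value ranking blends value with TP probability", {
  items <- data.frame(
    id = c("risky", "safe"),
    est_value = c(1.0, 0.6), p_tp = c(0.5, 1.0), est_time = 1,
    stringsAsFactors = FALSE)
  ranked <- expected_value_rank(items)
  expect_equal(ranked$id, c("safe", "risky"))
  expect_equal(ranked$expected_value, c(0.6, 0.5))

  sure <- data.frame(id = c("a", "b"), est_value = c(0.3, 0.8),
                     p_tp = 1, est_time = 1, stringsAsFactors = FALSE)
  expect_equal(expected_value_rank(sure)$id, c("b", "a"))
  hopeless <- data.frame(id = c("a", "b"), est_value = c(0.3, 0.8),
                         p_tp = 0, est_time = 1, stringsAsFactors = FALSE)
  expect_equal(expected_value_rank(hopeless)$expected_value, c(0, 0))
  expect_equal(expected_value_rank(hopeless)$id, c("a", "b"))  # stable

  missing <- data.frame(id = c("a", "b"), est_value = 0.5,
                        p_tp = c(0.4, NA), est_time = 1,
                        stringsAsFactors = FALSE)
  expect_error(expected_value_rank(missing), "p_tp missing.*b")
})

test_that("curation evaluation recomputes realized metrics", {
  n_tp <- 11; n_fp <- 7
  p <- make_project(values = rep(1, n_tp + n_fp),
                    times = c(rep(2, n_tp), rep(1, n_fp)),
                    t_max = 100,
                    labels = c(rep("TP", n_tp), rep("FP", n_fp)),
                    true_values = c(rep(1, n_tp), rep(0, n_fp)))
  s <- rank_and_schedule(p)
  m <- curate(p, s)
  expect_equal(m$precision, 11 / 18)
  expect_equal(m$overhead, 7 / 11)
  expect_equal(m$overhead_time_weighted_filtered, 7 / 36)
  expect_equal(format_percent(m$overhead_time_weighted_filtered), "19%")
  expect_equal(m$overhead_value_weighted, 7 / 11)
  expect_equal(m$estimation_error, 7 / 18)

  all_tp <- make_project(values = c(1, 1), t_max = 10,
                         labels = c("TP", "TP"), true_values = c(1, 1))
  expect_equal(curate(all_tp, rank_and_schedule(all_tp))$overhead, 0)

  no_truth <- make_project(values = c(1, 0.5), t_max = 10)
  expect_error(curate(no_truth, rank_and_schedule(no_truth)),
               "gold_label or true_value")
})

test_that("time allocation minimizes summed overheads and conserves budget", {
  mk <- function(name, n_tp, n_fp, seed) {
    set.seed(seed)
    v <- c(rep(1, n_tp), rep(0, n_fp))[sample(n_tp + n_fp)]
    make_project(values = v, t_max = 1, name = name)
  }
  p1 <- mk("clean", 8, 1, 1)
  p2 <- mk("noisy", 3, 6, 2)

  single <- allocate_time(list(p1), t_max_total = 6, quantum = 1)
  expect_equal(single$allocation$budget, 6)

  twin <- allocate_time(list(p1, p1), t_max_total = 6, quantum = 1)
  sym_obj <- sum(vapply(c(3, 3), function(b) {
    q <- p1; q$t_max <- b
    s <- rank_and_schedule(q)
    overhead_value_weighted(
      p1$items$est_value[match(s$curated, p1$items$id)], p1$scale)
  }, numeric(1)))
  expect_lte(twin$objective, sym_obj + 1e-12)
  expect_equal(sum(twin$allocation$budget), 6)

  plan <- allocate_time(list(p1, p2), t_max_total = 8, quantum = 1)
  expect_equal(sum(plan$allocation$budget), 8)
  expect_equal(plan$objective,
               brute_allocation_objective(list(p1, p2), 8, 1))

  expect_error(allocate_time(list(), 5, 1), "no projects")
  expect_error(allocate_time(list(p1), 5, 10), "quantum exceeds")
})

test_that("greedy allocation matches exhaustive enumeration on small instances", {
  for (seed in 1:8) {
    set.seed(seed)
    projects <- lapply(1:3, function(j) {
      n <- sample(5:9, 1)
      v <- round(runif(n), 3)
      make_project(values = v, times = round(runif(n, 0.5, 1.5), 3),
                   t_max = 1, name = paste0("p", j))
    })
    k <- sample(6:12, 1)
    exh <- allocate_time(projects, t_max_total = k, quantum = 1)
    greedy <- allocate_time(projects, t_max_total = k, quantum = 1,
                            exhaustive_limit = 0)
    oracle <- brute_allocation_objective(projects, k, 1)
    expect_equal(exh$objective, oracle)
    expect_equal(greedy$objective, oracle, tolerance = 1e-9)
    expect_equal(sum(exh$allocation$budget), k)
    expect_equal(sum(greedy$allocation$budget), k)
    # never worse than the equal split
    eq_bud <- rep(floor(k / 3), 3) + c(rep(1, k %% 3), rep(0, 3 - k %% 3))
    eq_obj <- sum(vapply(1:3, function(j) {
      q <- projects[[j]]; q$t_max <- eq_bud[j]
      if (all(q$items$est_time > eq_bud[j])) {
        worst <- which.min(q$items$est_value)
        return(overhead_value_weighted(q$items$est_value[worst], q$scale))
      }
      s <- rank_and_schedule(q)
      overhead_value_weighted(
        q$items$est_value[match(s$curated, q$items$id)], q$scale)
    }, numeric(1)))
    expect_lte(greedy$objective, eq_obj + 1e-12)
  }
})

test_that("item tables are validated with row-level diagnostics", {
  expect_error(item_table(data.frame(id = "a")), "required column")
  bad_time <- data.frame(id = c("a", "b"), est_value = 1,
                         est_time = c(1, -1))
  expect_error(item_table(bad_time), "est_time.*2")
  dup <- data.frame(id = c("a", "a"), est_value = 1, est_time = 1)
  expect_error(item_table(dup), "duplicate")
  bad_p <- data.frame(id = "a", est_value = 1, est_time = 1, p_tp = 1.3)
  expect_error(item_table(bad_p), "p_tp")
})
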