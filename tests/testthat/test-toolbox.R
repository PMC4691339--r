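test_that("dominance is componentwise with one strict inequality", {
  a <- strategy_point("a", 0.9, 0.6)
  b <- strategy_point("b", 0.6, 0.3)
  expect_true(dominates(a, b))
  expect_false(dominates(b, a))
  expect_false(dominates(a, a))
  hiP <- strategy_point("hiP", 0.9, 0.1)
  hiR <- strategy_point("hiR", 0.5, 0.5)
  expect_false(dominates(hiP, hiR))
  expect_false(dominates(hiR, hiP))
})

test_that("pareto frontier drops exactly the dominated strategies", {
  # high-recall A, compromise B, high-precision C; D falls inside the AC
  tb <- toolbox(strategy_point("A", 0.5, 0.9),
                strategy_point("B", 0.7, 0.6),
                strategy_point("C", 0.9, 0.3),
                strategy_point("D", 0.65, 0.5))
  fr <- pareto_frontier(tb)
  expect_setequal(fr$name, c("A", "B", "C"))
  expect_equal(fr$recall, sort(fr$recall))

  single <- toolbox(strategy_point("only", 0.5, 0.5))
  expect_equal(pareto_frontier(single)$name, "only")

  chain <- toolbox(strategy_point("top", 0.9, 0.9),
                   strategy_point("mid", 0.7, 0.7),
                   strategy_point("low", 0.5, 0.5))
  expect_equal(pareto_frontier(chain)$name, "top")
  expect_error(pareto_frontier(toolbox()), "empty")
})

test_that("pareto frontier matches the brute-force oracle on random sets", {
  for (seed in 1:40) {
    tb <- random_toolbox(sample(2:10, 1), seed)
    fr <- pareto_frontier(tb)
    pts <- do.call(rbind, lapply(tb$fixed, function(s) {
      data.frame(recall = s$recall, precision = s$precision)
    }))
    oracle <- brute_frontier(pts)
    expect_equal(fr[, c("recall", "precision")], oracle,
                 ignore_attr = TRUE)
    # frontier members are mutually incomparable
    if (nrow(fr) > 1) {
      for (i in seq_len(nrow(fr) - 1)) {
        expect_true(fr$precision[i] > fr$precision[i + 1])
      }
    }
  }
})

test_that("area covered: exact staircase and curve integration", {
  expect_equal(area_covered(toolbox(strategy_point("ideal", 1, 1))), 1)
  two <- toolbox(strategy_point("hiP", 1, 0.5),
                 strategy_point("hiR", 0.5, 1))
  expect_equal(area_covered(two), 0.75)
  expect_equal(area_covered(two), grid_area_oracle(two, 1000),
               tolerance = 1e-3)
  # adding a dominated point leaves the area unchanged
  withD <- toolbox(strategy_point("hiP", 1, 0.5),
                   strategy_point("hiR", 0.5, 1),
                   strategy_point("D", 0.4, 0.4))
  expect_equal(area_covered(withD), 0.75)
  expect_equal(area_covered(toolbox()), 0)
})

test_that("area covered handles adjustable curves", {
  # single curve: lead-in rectangle + trapezoid under the knots
  s <- adjustable_strategy("adj", rbind(c(0.2, 0.9), c(0.6, 0.5)))
  tb <- toolbox(s)
  expect_equal(area_covered(tb), 0.2 * 0.9 + 0.4 * (0.9 + 0.5) / 2)
  expect_equal(area_covered(tb), grid_area_oracle(tb, 2000),
               tolerance = 1e-3)
  # mixed with a fixed point that pokes above the curve
  mixed <- toolbox(s, strategy_point("dot", 0.8, 0.4))
  expect_equal(area_covered(mixed), grid_area_oracle(mixed, 2000),
               tolerance = 1e-3)
})

test_that("area covered is monotone and blind to dominated additions", {
  set.seed(99)
  for (i in 1:100) {
    tb <- random_toolbox(sample(1:6, 1), seed = 1000 + i)
    base_area <- area_covered(tb)
    extra <- strategy_point("extra", runif(1, 0.05, 1), runif(1, 0.05, 1))
    grown <- do.call(toolbox, c(tb$fixed, list(extra)))
    expect_gte(area_covered(grown), base_area - 1e-12)
    if (is_inferior(extra, tb)) {
      expect_equal(area_covered(grown), base_area)
    } else {
      expect_gt(area_covered(grown), base_area + 1e-12)
    }
  }
})

test_that("inferiority is weak dominance by the covered area", {
  tb <- toolbox(strategy_point("A", 0.5, 0.9),
                strategy_point("C", 0.9, 0.3))
  expect_true(is_inferior(strategy_point("in", 0.4, 0.5), tb))
  expect_true(is_inferior(strategy_point("dup", 0.9, 0.3), tb))
  expect_false(is_inferior(strategy_point("out", 0.95, 0.2), tb))
  expect_false(is_inferior(strategy_point("wide", 0.2, 0.95), tb))
})

test_that("operating points interpolate the curve", {
  s <- adjustable_strategy("adj", rbind(c(0.2, 0.9), c(0.4, 0.7)),
                           cost = 3)
  at_knot <- operating_point(s, recall = 0.4)
  expect_equal(at_knot$precision, 0.7)
  expect_equal(at_knot$cost, 3)
  mid <- operating_point(s, recall = 0.3)
  expect_equal(mid$precision, 0.8)
  expect_equal(mid$recall, 0.3)
  by_p <- operating_point(s, precision = 0.8)
  expect_equal(by_p$recall, 0.3)
  expect_error(operating_point(s, recall = 0.5), "achievable range")
  expect_error(operating_point(s, precision = 0.95), "achievable range")
  expect_error(operating_point(s), "exactly one")
})

test_that("overhead along an adjustable curve is non-decreasing in recall", {
  set.seed(5)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    r <- sort(runif(k, 0.05, 1))
    while (any(diff(r) <= 1e-6)) r <- sort(runif(k, 0.05, 1))
    p <- sort(runif(k, 0.1, 1), decreasing = TRUE)
    s <- adjustable_strategy("rand", cbind(r, p))
    grid <- seq(r[1], r[k], length.out = 25)
    prec <- vapply(grid, function(g) operating_point(s, recall = g)$precision,
                   numeric(1))
    expect_true(all(diff(prec) <= 1e-9))
    expect_true(all(diff(overhead_from_precision(prec)) >= -1e-9))
  }
})

test_that("expected output size links operating points to item counts", {
  sz <- expected_output_size(strategy_point("s", 0.5, 0.5), 1000, 0.1)
  expect_equal(sz$tps, 50)
  expect_equal(sz$m, 100)
  expect_equal(expected_output_size(strategy_point("p1", 1, 0.4),
                                    500, 0.2)$m, 40)
  expect_equal(expected_output_size(strategy_point("r0", 0.8, 0),
                                    500, 0.2)$m, 0)
  # recall 1 at precision below the base rate would imply m > n
  expect_error(expected_output_size(strategy_point("bad", 0.1, 1), 100, 0.5),
               "inconsistent")
})

test_that("strategy selection maximizes TPs within the budget", {
  tm <- time_model(1, 1)
  one <- toolbox(strategy_point("only", 0.8, 0.4))
  sel <- select_strategy(one, n = 100, base_rate = 0.2, tm = tm,
                         t_max = 1000)
  expect_true(sel$feasible)
  expect_equal(sel$chosen$name, "only")

  # scarce budget: only the high-precision strategy's small output fits
  tb <- toolbox(strategy_point("hiP", 0.9, 0.1),
                strategy_point("bal", 0.5, 0.5))
  n <- 1000; br <- 0.2
  # hiP: m = 1000*0.2*0.1/0.9 = 22.2; bal: m = 200
  sel_scarce <- select_strategy(tb, n, br, tm, t_max = 30)
  expect_equal(sel_scarce$chosen$name, "hiP")
  # ample budget: the max-recall feasible option wins
  sel_ample <- select_strategy(tb, n, br, tm, t_max = 1e4)
  expect_equal(sel_ample$chosen$name, "bal")
  # verdicts agree with brute enumeration of the option table
  feas <- sel_ample$options[sel_ample$options$feasible, ]
  expect_equal(sel_ample$chosen$name, feas$name[which.max(feas$tps)])
  # no selected option ever exceeds the budget
  expect_true(all(sel_scarce$options$time[sel_scarce$options$feasible] <=
                    30 + 1e-9))

  infeasible <- select_strategy(tb, n, br, tm, t_max = 1)
  expect_false(infeasible$feasible)
  expect_null(infeasible$chosen)
  expect_match(infeasible$verdict, "infeasible")
})

test_that("adjustable strategies are tuned to the budget when selected", {
  tm <- time_model(1, 1)
  adj <- adjustable_strategy("adj", rbind(c(0.1, 0.9), c(0.9, 0.45)))
  tb <- toolbox(adj, strategy_point("fix", 0.95, 0.05))
  n <- 1000; br <- 0.2
  sel <- select_strategy(tb, n, br, tm, t_max = 150)
  expect_equal(sel$chosen$name, "adj")
  row <- sel$options[sel$options$name == "adj", ]
  expect_lte(row$time, 150 + 1e-6)
  expect_gt(row$time, 149)  # budget-exhausting operating point
  # application cost is charged against the budget before feasibility
  costly <- toolbox(adjustable_strategy("adj", rbind(c(0.1, 0.9),
                                                     c(0.9, 0.45)),
                                        cost = 100),
                    strategy_point("fix", 0.95, 0.05))
  sel_cost <- select_strategy(costly, n, br, tm, t_max = 150)
  row_cost <- sel_cost$options[sel_cost$options$name == "adj", ]
  expect_lt(row_cost$tps, row$tps)
})

test_that("toolbox construction rejects invalid members", {
  expect_error(toolbox(strategy_point("x", 0.5, 0.5),
                       strategy_point("x", 0.6, 0.6)), "unique")
  expect_error(strategy_point("p0", 0, 0.5), "\\(0, 1\\]")
  expect_error(adjustable_strategy("bad", rbind(c(0.4, 0.7), c(0.2, 0.9))),
               "strictly increasing")
  expect_error(adjustable_strategy("bad", rbind(c(0.2, 0.7), c(0.4, 0.9))),
               "non-increasing")
  expect_error(adjustable_strategy("bad", rbind(c(0.2, 0.7))), "2 knots")
})
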