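#' Configuration for a simulated curation project
#'
#' Describes the statistical structure of a synthetic candidate set: how
#' many items, what fraction of them are truly valuable (the base rate), how
#' item values are distributed, how long items take to curate, and how noisy
#' the pre-curation estimates are. The simulator gives every downstream
#' operation a ground truth to be validated against, with no external data.
#'
#' Defaults emulate a literature-triage candidate set: binary item values
#' (an abstract is either worth curating or not; the `beta` model instead
#' draws graded TP values from a right-skewed beta(2, 5) on the value
#' scale), per-item curation times lognormal around the class means with
#' moderate dispersion, and optionally noisy value estimates and
#' approximately calibrated TP probabilities.
#'
#' @param n Item count (> 0).
#' @param base_rate Fraction of truly valuable items, in (0, 1\].
#' @param value_model `"binary"` (TPs at `w_max`) or `"beta"` (TPs drawn
#'   from a beta distribution rescaled to the value scale); FPs always sit
#'   at `w_min`.
#' @param beta_shape Length-2 shape parameters for the `"beta"` model.
#' @param t_tp,t_fp Mean curation times per TP and per FP.
#' @param time_dispersion Lognormal `sdlog` of per-item times around the
#'   class mean; 0 gives deterministic times.
#' @param est_noise_sd Standard deviation of additive noise on estimated
#'   values (clipped to the scale); 0 makes estimates exact.
#' @param p_slope Slope of the logistic transform generating `p_tp` from
#'   the gold label; larger means sharper, better-separated probabilities.
#' @param p_noise_sd Noise on the logistic latent; 0 with a large slope
#'   gives near-degenerate probabilities.
#' @param scale A [value_scale()].
#' @param t_max Project time budget; default is the expected total curation
#'   time of the whole candidate set (ample resources).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n, base_rate,
                              value_model = c("binary", "beta"),
                              beta_shape = c(2, 5),
                              t_tp = 2, t_fp = 1, time_dispersion = 0.25,
                              est_noise_sd = 0, p_slope = 2, p_noise_sd = 1,
                              scale = value_scale(), t_max = NULL) {
  value_model <- match.arg(value_model)
  stopifnot(is.numeric(n), length(n) == 1L, n > 0, n == floor(n),
            is.numeric(base_rate), base_rate > 0, base_rate <= 1,
            t_tp > 0, t_fp > 0, time_dispersion >= 0, est_noise_sd >= 0,
            p_slope >= 0, p_noise_sd >= 0,
            inherits(scale, "value_scale"))
  if (value_model == "beta" && (length(beta_shape) != 2 ||
                                any(beta_shape <= 0))) {
    stop("beta_shape must be two positive shape parameters", call. = FALSE)
  }
  if (is.null(t_max)) {
    t_max <- n * (base_rate * t_tp + (1 - base_rate) * t_fp)
  }
  stopifnot(t_max > 0)
  structure(list(n = as.integer(n), base_rate = base_rate,
                 value_model = value_model, beta_shape = beta_shape,
                 t_tp = t_tp, t_fp = t_fp,
                 time_dispersion = time_dispersion,
                 est_noise_sd = est_noise_sd, p_slope = p_slope,
                 p_noise_sd = p_noise_sd, scale = scale, t_max = t_max),
            class = "simulation_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic curation project with ground truth
#'
#' Draws `n` items: gold labels at the configured base rate, true values
#' from the value model (FPs at `w_min`), per-item curation times lognormal
#' around the class means, estimated values as true values plus clipped
#' Gaussian noise, and TP probabilities from a logistic transform of the
#' gold label plus latent noise (approximately calibrated by construction).
#' Fully reproducible: the same config and seed give an identical project.
#' Each random component draws from an independent stream derived from the
#' root seed, so changing one component never perturbs the others.
#'
#' @param cfg A [simulation_config()].
#' @param seed Root RNG seed (integer).
#' @param name Project name.
#' @return A [curation_project()] whose items carry `true_value`,
#'   `gold_label` and `p_tp`.
#' @export
generate_project <- function(cfg, seed = 1L, name = "simulated") {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n
  sc <- cfg$scale
  labels <- with_seed(derive_seed(seed, "labels"),
                      stats::runif(n) < cfg$base_rate)
  true_value <- rep(sc$w_min, n)
  if (cfg$value_model == "binary") {
    true_value[labels] <- sc$w_max
  } else {
    draws <- with_seed(derive_seed(seed, "values"),
                       stats::rbeta(n, cfg$beta_shape[1], cfg$beta_shape[2]))
    true_value[labels] <- sc$w_min +
      (sc$w_max - sc$w_min) * draws[labels]
  }
  mean_t <- ifelse(labels, cfg$t_tp, cfg$t_fp)
  if (cfg$time_dispersion > 0) {
    # lognormal with the requested mean: meanlog = log(mean) - sdlog^2/2
    est_time <- with_seed(derive_seed(seed, "times"), {
      stats::rlnorm(n, meanlog = log(mean_t) - cfg$time_dispersion^2 / 2,
                    sdlog = cfg$time_dispersion)
    })
  } else {
    est_time <- mean_t
  }
  if (cfg$est_noise_sd > 0) {
    est_value <- with_seed(derive_seed(seed, "est_values"), {
      pmin(pmax(true_value + stats::rnorm(n, 0, cfg$est_noise_sd),
                sc$w_min), sc$w_max)
    })
  } else {
    est_value <- true_value
  }
  latent <- ifelse(labels, 1, -1)
  if (cfg$p_noise_sd > 0) {
    latent <- latent + with_seed(derive_seed(seed, "probs"),
                                 stats::rnorm(n, 0, cfg$p_noise_sd))
  }
  p_tp <- stats::plogis(cfg$p_slope * latent)
  items <- data.frame(
    id = sprintf("item%05d", seq_len(n)),
    true_value = true_value,
    est_value = est_value,
    p_tp = p_tp,
    est_time = est_time,
    gold_label = ifelse(labels, "TP", "FP"),
    stringsAsFactors = FALSE)
  curation_project(name, items, t_max = cfg$t_max, scale = sc)
}

#' Apply a stochastic filtering strategy to a simulated project
#'
#' Realizes a filtering strategy with target recall and precision on a
#' project with gold labels: each gold TP is retained with probability
#' `target_recall`, and gold FPs are retained at the rate that makes the
#' expected precision of the output equal `target_precision`. Returns the
#' realized subset and its exact confusion counts (realized counts
#' fluctuate around the targets; they converge as `n` grows).
#'
#' @param project A [curation_project()] with gold labels.
#' @param target_precision Fraction in (0, 1\].
#' @param target_recall Fraction in \[0, 1\].
#' @param seed RNG seed.
#' @return A list with `items` (the filtered subset of the item table) and
#'   `counts` (a [confusion_counts()] with `fn`/`tn` filled in).
#' @export
simulate_filter <- function(project, target_precision, target_recall,
                            seed = 1L) {
  stopifnot(inherits(project, "curation_project"))
  if (!(target_precision > 0 && target_precision <= 1)) {
    stop("target_precision must lie in (0, 1]", call. = FALSE)
  }
  if (target_recall < 0 || target_recall > 1) {
    stop("target_recall must lie in [0, 1]", call. = FALSE)
  }
  lab <- project$items$gold_label
  if (any(is.na(lab))) {
    stop("simulate_filter requires gold labels on every item", call. = FALSE)
  }
  is_tp <- lab == "TP"
  n_tp <- sum(is_tp); n_fp <- sum(!is_tp)
  exp_tp <- n_tp * target_recall
  exp_fp <- exp_tp * (1 - target_precision) / target_precision
  fp_rate <- if (n_fp == 0) 0 else exp_fp / n_fp
  if (fp_rate > 1 + 1e-9) {
    stop(sprintf(paste0(
      "targets unachievable: precision %g at recall %g needs %.1f FPs but ",
      "only %d exist; feasible precision at this recall is >= %.3f"),
      target_precision, target_recall, exp_fp, n_fp,
      exp_tp / (exp_tp + n_fp)), call. = FALSE)
  }
  keep <- with_seed(derive_seed(seed, "filter"), {
    u <- stats::runif(length(lab))
    (is_tp & u < target_recall) | (!is_tp & u < fp_rate)
  })
  tp <- sum(keep & is_tp); fp <- sum(keep & !is_tp)
  list(items = project$items[keep, , drop = FALSE],
       counts = confusion_counts(tp, fp, fn = n_tp - tp, tn = n_fp - fp))
}

#' Empirical recovery of the precision-overhead relationship
#'
#' Monte-Carlo check that overheads realized by simulated filtering match
#' the closed form `(1 - p) / p`, and that realized TP production rates
#' match `1 / (t_tp * (1 + O))`. For each target operating point the
#' filter is realized `n_reps` times on a simulated project and the
#' realized overhead and TP rate are summarized.
#'
#' @param cfg A [simulation_config()].
#' @param targets Data frame with columns `precision` and `recall`.
#' @param n_reps Replicates per target (>= 1).
#' @param seed Root RNG seed.
#' @return A data frame with one row per target: mean realized overhead,
#'   its standard error and deviation from the analytic value, and the mean
#'   realized TP rate with its analytic counterpart.
#' @export
recovery_experiment <- function(cfg, targets, n_reps = 100, seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"), n_reps >= 1,
            is.data.frame(targets),
            all(c("precision", "recall") %in% names(targets)))
  project <- generate_project(cfg, seed = derive_seed(seed, "project"))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    p <- targets$precision[i]; r <- targets$recall[i]
    o_hat <- numeric(n_reps); rate_hat <- numeric(n_reps)
    for (rep in seq_len(n_reps)) {
      res <- simulate_filter(project, p, r,
                             seed = derive_seed(seed, sprintf("f%d_%d", i, rep)))
      o_hat[rep] <- if (res$counts$tp > 0) {
        overhead_simple(res$counts)
      } else NA_real_
      time_spent <- sum(res$items$est_time)
      rate_hat[rep] <- if (time_spent > 0) res$counts$tp / time_spent else NA
    }
    o_mean <- mean(o_hat, na.rm = TRUE)
    o_analytic <- overhead_from_precision(p)
    data.frame(
      precision = p, recall = r, n_reps = n_reps,
      overhead_mean = o_mean,
      overhead_se = stats::sd(o_hat, na.rm = TRUE) / sqrt(sum(!is.na(o_hat))),
      overhead_analytic = o_analytic,
      overhead_deviation = o_mean - o_analytic,
      tp_rate_mean = mean(rate_hat, na.rm = TRUE),
      tp_rate_analytic = tp_production_rate(
        time_model(cfg$t_tp, cfg$t_fp), o_analytic * cfg$t_fp / cfg$t_tp),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
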