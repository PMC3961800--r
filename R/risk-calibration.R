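#' Risk-group thresholds
#'
#' Container for the two RFRS cutoffs separating low-, intermediate- and
#' high-risk groups. The reference analysis on the original training cohort
#' produced 0.333 and 0.606; on other cohorts they are refit from the OOB
#' score distribution with [fit_thresholds()].
#'
#' @param t_low,t_high cutoffs with `0 < t_low < t_high < 1`.
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(t_low, t_high) {
  if (!(is.numeric(t_low) && is.numeric(t_high) &&
        t_low > 0 && t_low < t_high && t_high < 1)) {
    stop("thresholds must satisfy 0 < t_low < t_high < 1", call. = FALSE)
  }
  structure(list(t_low = t_low, t_high = t_high), class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("<risk_thresholds> low < %.3f <= intermediate < %.3f <= high\n",
              x$t_low, x$t_high))
  invisible(x)
}

#' Fit risk-group thresholds from the RFRS distribution
#'
#' Fits a three-component univariate Gaussian mixture to the out-of-bag
#' scores (three components because there are three risk groups) and takes as
#' each threshold the maximum score assigned to the lower component — the
#' same boundary convention used for the ER/HER2 marker cutoffs. If the
#' mixture collapses, `fallback = "quantile"` substitutes score tertiles.
#'
#' @param scores numeric vector of RFRS values in `[0, 1]` (>= 50
#'   recommended; fewer triggers a warning).
#' @param fallback `"none"` (collapse is an error) or `"quantile"` (tertile
#'   thresholds on collapse).
#' @return A [risk_thresholds()] object with attribute `method`.
#' @export
fit_thresholds <- function(scores, fallback = c("none", "quantile")) {
  fallback <- match.arg(fallback)
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must be RFRS values in [0, 1]", call. = FALSE)
  }
  if (length(scores) < 50L) {
    warning("fewer than 50 scores; threshold fit may be unstable")
  }
  if (stats::var(scores) == 0) {
    stop("scores are identical; thresholds undefined", call. = FALSE)
  }
  fit <- tryCatch(mixture_boundaries(scores, g = 3L), error = function(e) e)
  if (!inherits(fit, "error")) {
    b <- fit$boundaries
    # with unequal variances a wide low component can reclaim the far right
    # tail, making the raw boundaries non-monotone or degenerate
    if (!(b[1] > 0 && b[1] < b[2] && b[2] < 1)) {
      fit <- simpleError("mixture boundaries are degenerate (non-monotone or outside (0, 1))")
    }
  }
  if (inherits(fit, "error")) {
    if (fallback == "quantile") {
      q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
      th <- risk_thresholds(q[1], q[2])
      attr(th, "method") <- "quantile"
      return(th)
    }
    stop(conditionMessage(fit), " (set fallback = \"quantile\" for tertiles)",
         call. = FALSE)
  }
  th <- risk_thresholds(fit$boundaries[1L], fit$boundaries[2L])
  attr(th, "method") <- "mixture"
  attr(th, "components") <- list(means = fit$means, sds = fit$sds,
                                 weights = fit$weights)
  th
}

#' Assign risk groups by threshold
#'
#' Boundary conventions: `score < t_low` is low risk, `t_low <= score <
#' t_high` intermediate, and `score >= t_high` high risk (so a score exactly
#' at a threshold falls in the upper group).
#'
#' @param scores RFRS values in `[0, 1]`.
#' @param thresholds a [risk_thresholds()].
#' @return Ordered factor (`low < intermediate < high`) parallel to `scores`.
#' @examples
#' th <- risk_thresholds(0.333, 0.606)
#' assign_risk_group(c(0.2, 0.333, 0.606), th)
#' @export
assign_risk_group <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  g <- ifelse(scores < thresholds$t_low, "low",
              ifelse(scores < thresholds$t_high, "intermediate", "high"))
  factor(g, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Assign risk groups by training proportions
#'
#' For external cohorts on other platforms, absolute thresholds do not
#' transfer; instead samples are ranked by score and split so the group
#' proportions match those observed in training. Group sizes follow
#' largest-remainder apportionment; ties in score keep stable input order.
#'
#' @param scores numeric scores (higher = higher risk).
#' @param proportions numeric length-3 vector (low, intermediate, high) or a
#'   named vector with those names; must sum to 1.
#' @return Ordered factor parallel to `scores`.
#' @export
assign_groups_by_proportion <- function(scores, proportions) {
  if (!is.null(names(proportions))) {
    proportions <- proportions[c("low", "intermediate", "high")]
  }
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3L || anyNA(proportions) ||
      abs(sum(proportions) - 1) > 1e-6) {
    stop("`proportions` must be 3 values (low, intermediate, high) summing to 1",
         call. = FALSE)
  }
  n <- length(scores)
  sizes <- largest_remainder(n * proportions, n)
  ord <- order(scores, decreasing = TRUE)  # stable: ties keep input order
  g <- character(n)
  g[ord] <- rep(c("high", "intermediate", "low"), sizes[c(3, 2, 1)])
  factor(g, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Down-sample events to a target prevalence
#'
#' Removes one uniformly chosen event sample at a time until the event
#' fraction among remaining samples reaches the target. The comparison
#' carries a small tolerance (default half of one part in a thousand), so the
#' procedure stops at the first removal count whose rate equals the target at
#' the precision targets are quoted (e.g. a 572-sample cohort with 143 events
#' and a 15% target stops at 505 samples with 76 events, 76/505 = 15.0%).
#' Already at or below the target, nothing is removed.
#'
#' @param event logical event indicator per sample.
#' @param target target event fraction in (0, 1).
#' @param tol stopping tolerance on the event fraction.
#' @param seed integer seed for the random removals.
#' @return Integer vector of retained indices (in original order), with
#'   attribute `removed` (the removed indices, in removal order).
#' @examples
#' idx <- downsample_to_prevalence(rep(c(TRUE, FALSE), c(143, 429)),
#'                                 target = 0.15, seed = 1)
#' length(idx)       # 505
#' sum(rep(c(TRUE, FALSE), c(143, 429))[idx])  # 76
#' @export
downsample_to_prevalence <- function(event, target = 0.15, tol = 5e-4,
                                     seed = NULL) {
  event <- as.logical(event)
  if (anyNA(event)) stop("`event` must be non-missing logical", call. = FALSE)
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("`target` must lie in (0, 1)", call. = FALSE)
  }
  keep <- seq_along(event)
  removed <- integer(0)
  with_seed(seed, {
    repeat {
      rate <- sum(event[keep]) / length(keep)
      if (rate <= target + tol) break
      pool <- keep[event[keep]]
      victim <- pool[sample.int(length(pool), 1L)]
      removed <- c(removed, victim)
      keep <- keep[keep != victim]
    }
  })
  structure(keep, removed = removed)
}

#' Average per-group relapse rates under a target prevalence
#'
#' Repeats the full down-sampling procedure `n_iterations` times; in each
#' iteration the retained samples are assigned to risk groups (by thresholds,
#' or by training proportions) and per-group event rates and occupancy
#' proportions computed. Reported rates and proportions are means across
#' iterations; a group empty in some iteration contributes no rate there and
#' the number of contributing iterations is reported.
#'
#' @param scores RFRS values per sample.
#' @param event logical 10-year relapse indicator per sample.
#' @param thresholds a [risk_thresholds()] (used when `proportions` is NULL).
#' @param proportions optional training group proportions for
#'   [assign_groups_by_proportion()].
#' @param target target overall event fraction (default 0.15).
#' @param n_iterations number of down-sampling repetitions (default 1,000).
#' @param seed integer seed.
#' @return Data frame (`group`, `proportion`, `relapse_rate`,
#'   `n_iterations_used`), with attributes `target` and
#'   `monotone_fraction` (fraction of iterations with rates nondecreasing
#'   from low to high).
#' @export
estimate_group_rates <- function(scores, event, thresholds = NULL,
                                 proportions = NULL, target = 0.15,
                                 n_iterations = 1000L, seed = NULL) {
  event <- as.logical(event)
  stopifnot(length(scores) == length(event))
  if (is.null(thresholds) && is.null(proportions)) {
    stop("supply `thresholds` or `proportions`", call. = FALSE)
  }
  n_iterations <- assert_count(n_iterations, "n_iterations")
  lev <- c("low", "intermediate", "high")
  rate_sum <- prop_sum <- stats::setNames(numeric(3), lev)
  rate_n <- stats::setNames(integer(3), lev)
  monotone <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      keep <- downsample_to_prevalence(event, target = target)
      s <- scores[keep]
      e <- event[keep]
      grp <- if (is.null(proportions)) {
        assign_risk_group(s, thresholds)
      } else {
        assign_groups_by_proportion(s, proportions)
      }
      tab <- table(grp)
      rates <- tapply(e, grp, mean)
      prop_sum <- prop_sum + as.numeric(tab) / length(keep)
      ok <- !is.na(rates)
      rate_sum[ok] <- rate_sum[ok] + rates[ok]
      rate_n[ok] <- rate_n[ok] + 1L
      r <- rates[!is.na(rates)]
      if (length(r) > 1L && !is.unsorted(r)) monotone <- monotone + 1L
    }
  })
  out <- data.frame(group = factor(lev, levels = lev, ordered = TRUE),
                    proportion = unname(prop_sum) / n_iterations,
                    relapse_rate = ifelse(rate_n > 0, rate_sum / rate_n, NA_real_),
                    n_iterations_used = unname(rate_n))
  attr(out, "target") <- target
  attr(out, "monotone_fraction") <- monotone / n_iterations
  out
}

#' Loess calibration curve: RFRS to 10-year relapse likelihood
#'
#' Bins scores into `n_bins` equal intervals on `[0, 1]`, computes the
#' empirical relapse fraction per occupied bin, and fits a loess of fraction
#' on bin midpoint weighted by bin occupancy. The fitted curve, with
#' pointwise 95% confidence bands (fit +/- 1.96 SE), is tabulated on a fine
#' grid so that lookups and serialization never need the loess object
#' itself. Empty bins are skipped in fitting.
#'
#' @param scores RFRS values in `[0, 1]` (>= 100 samples recommended).
#' @param outcome logical 10-year relapse indicator.
#' @param n_bins number of score intervals (default 50).
#' @param span loess span (default 0.75).
#' @param level confidence level for the bands.
#' @return An object of class `relapse_curve`: `bins` (midpoint, n, rate),
#'   `grid` (score, fit, lower, upper), and the training scores with their
#'   fitted likelihoods (for population-fraction queries).
#' @export
relapse_likelihood_curve <- function(scores, outcome, n_bins = 50L,
                                     span = 0.75, level = 0.95) {
  outcome <- as.logical(outcome)
  stopifnot(length(scores) == length(outcome))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (length(scores) < 100L) {
    warning("fewer than 100 samples; the calibration curve will be noisy")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(scores, breaks, include.lowest = TRUE, labels = FALSE)
  mid <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  occupied <- sort(unique(bin))
  bins <- data.frame(
    midpoint = mid[occupied],
    n = as.integer(table(factor(bin, levels = occupied))),
    rate = as.numeric(tapply(outcome, factor(bin, levels = occupied), mean)))
  if (nrow(bins) < 4L) {
    stop("too few occupied score bins to fit a calibration curve", call. = FALSE)
  }
  fit <- stats::loess(rate ~ midpoint, data = bins, weights = bins$n,
                      span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid_x <- sort(unique(c(bins$midpoint,
                          seq(min(bins$midpoint), max(bins$midpoint),
                              length.out = 101L))))
  pr <- stats::predict(fit, data.frame(midpoint = grid_x), se = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  grid <- data.frame(score = grid_x,
                     fit = pmin(pmax(pr$fit, 0), 1),
                     lower = pmin(pmax(pr$fit - z * pr$se.fit, 0), 1),
                     upper = pmin(pmax(pr$fit + z * pr$se.fit, 0), 1))
  curve <- structure(list(bins = bins, grid = grid, span = span,
                          level = level, n_bins = n_bins),
                     class = "relapse_curve")
  curve$train <- data.frame(score = scores,
                            likelihood = predict(curve, scores)$likelihood)
  curve
}

#' @export
print.relapse_curve <- function(x, ...) {
  cat(sprintf("<relapse_curve> loess over %d occupied / %d bins, span %.2f; fitted likelihood range [%.3f, %.3f]\n",
              nrow(x$bins), x$n_bins, x$span,
              min(x$grid$fit), max(x$grid$fit)))
  invisible(x)
}

#' Look up relapse likelihood for new scores
#'
#' Linear interpolation on the tabulated loess fit. Scores outside the fitted
#' support receive the nearest-endpoint likelihood and are flagged
#' `extrapolated`.
#'
#' @param object a `relapse_curve`.
#' @param scores numeric RFRS values.
#' @param ... unused.
#' @return Data frame (`score`, `likelihood`, `lower`, `upper`,
#'   `extrapolated`).
#' @export
predict.relapse_curve <- function(object, scores, ...) {
  scores <- as.numeric(scores)
  lo <- min(object$grid$score)
  hi <- max(object$grid$score)
  clamped <- pmin(pmax(scores, lo), hi)
  interp <- function(col) {
    stats::approx(object$grid$score, object$grid[[col]], xout = clamped,
                  rule = 2)$y
  }
  data.frame(score = scores,
             likelihood = interp("fit"),
             lower = interp("lower"),
             upper = interp("upper"),
             extrapolated = scores < lo | scores > hi)
}

#' Fraction of the training population at or below a predicted risk
#'
#' Answers questions of the form "what fraction of patients are predicted to
#' have a relapse likelihood of at most x?" using the training scores stored
#' with the curve.
#'
#' @param curve a `relapse_curve`.
#' @param likelihood one or more likelihood cut points in `[0, 1]`.
#' @return Numeric vector: fraction of training samples with fitted
#'   likelihood at or below each cut point.
#' @export
fraction_at_or_below <- function(curve, likelihood) {
  stopifnot(inherits(curve, "relapse_curve"))
  vapply(likelihood, function(x) mean(curve$train$likelihood <= x), numeric(1))
}

#' Full risk calibration bundle
#'
#' Fits thresholds from the OOB score distribution (unless supplied),
#' estimates prevalence-matched per-group relapse rates by repeated
#' down-sampling, and fits the score-to-likelihood loess curve on one seeded
#' down-sampled cohort (so the curve reflects the target prevalence, as a
#' population-realistic relapse likelihood should).
#'
#' @param scores OOB RFRS values of the training samples.
#' @param event logical 10-year relapse indicator, parallel to `scores`.
#' @param thresholds optional pre-computed [risk_thresholds()].
#' @param target_prevalence target overall relapse rate (default 0.15).
#' @param n_iterations down-sampling repetitions for the group rates.
#' @param fallback threshold-fit fallback passed to [fit_thresholds()]
#'   (default `"quantile"`, so a degenerate mixture falls back to tertiles
#'   rather than aborting a whole pipeline run).
#' @param seed integer seed.
#' @return An object of class `rfrs_calibration`: `thresholds`,
#'   `group_rates`, `curve`, `target_prevalence`, `n_iterations`.
#' @export
calibrate_rfrs <- function(scores, event, thresholds = NULL,
                           target_prevalence = 0.15, n_iterations = 1000L,
                           fallback = "quantile", seed = NULL) {
  event <- as.logical(event)
  stopifnot(length(scores) == length(event))
  thresholds <- thresholds %||% fit_thresholds(scores, fallback = fallback)
  group_rates <- estimate_group_rates(scores, event, thresholds = thresholds,
                                      target = target_prevalence,
                                      n_iterations = n_iterations, seed = seed)
  keep <- downsample_to_prevalence(event, target = target_prevalence,
                                   seed = if (is.null(seed)) NULL else seed + 1L)
  curve <- relapse_likelihood_curve(scores[keep], event[keep])
  structure(list(thresholds = thresholds,
                 group_rates = group_rates,
                 curve = curve,
                 target_prevalence = target_prevalence,
                 n_iterations = n_iterations),
            class = "rfrs_calibration")
}

#' @export
print.rfrs_calibration <- function(x, ...) {
  print(x$thresholds)
  gr <- x$group_rates
  cat(sprintf("  target prevalence %.0f%%, %d iterations\n",
              100 * x$target_prevalence, x$n_iterations))
  for (i in seq_len(nrow(gr))) {
    cat(sprintf("  %-12s %5.1f%% of patients, %5.1f%% relapse rate\n",
                gr$group[i], 100 * gr$proportion[i], 100 * gr$relapse_rate[i]))
  }
  invisible(x)
}

#' Serialize / restore a calibration bundle as JSON
#'
#' The bundle is fully tabulated (thresholds, group rates, curve grid, bins
#' and training-score likelihoods), so the JSON round-trips without any R
#' binary objects.
#'
#' @param calibration an `rfrs_calibration`.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns an `rfrs_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "rfrs_calibration"))
  payload <- list(
    format = "rfrs_calibration",
    version = 1L,
    thresholds = list(t_low = calibration$thresholds$t_low,
                      t_high = calibration$thresholds$t_high),
    target_prevalence = calibration$target_prevalence,
    n_iterations = calibration$n_iterations,
    group_rates = calibration$group_rates,
    curve = list(bins = calibration$curve$bins,
                 grid = calibration$curve$grid,
                 span = calibration$curve$span,
                 level = calibration$curve$level,
                 n_bins = calibration$curve$n_bins,
                 train = calibration$curve$train))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "rfrs_calibration")) {
    stop("not an rfrs calibration file: ", path, call. = FALSE)
  }
  gr <- payload$group_rates
  gr$group <- factor(gr$group, levels = c("low", "intermediate", "high"),
                     ordered = TRUE)
  curve <- structure(list(bins = payload$curve$bins,
                          grid = payload$curve$grid,
                          span = payload$curve$span,
                          level = payload$curve$level,
                          n_bins = payload$curve$n_bins,
                          train = payload$curve$train),
                     class = "relapse_curve")
  structure(list(thresholds = risk_thresholds(payload$thresholds$t_low,
                                              payload$thresholds$t_high),
                 group_rates = gr,
                 curve = curve,
                 target_prevalence = payload$target_prevalence,
                 n_iterations = payload$n_iterations),
            class = "rfrs_calibration")
}
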