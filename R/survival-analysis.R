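#' Kaplan-Meier curves per risk group
#'
#' Product-limit estimator per group via the survival package. Censored
#' samples contribute to risk sets until their follow-up time; at tied
#' event/censoring times, events precede censorings (standard convention).
#'
#' @param time follow-up time (years), strictly positive (time-zero events
#'   are excluded upstream).
#' @param event logical event indicator.
#' @param group optional grouping factor (NULL = one curve).
#' @return A list of class `km_curves`: `curves` (per-group data frames with
#'   `time`, `n_risk`, `n_event`, `survival`) and the underlying
#'   `survival::survfit` object.
#' @export
km_fit <- function(time, event, group = NULL) {
  event <- as.logical(event)
  if (any(time <= 0)) stop("times must be strictly positive", call. = FALSE)
  group <- factor(group %||% rep("all", length(time)))
  empty <- setdiff(levels(group), unique(as.character(group)))
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    rep(levels(group)[1L], length(s$time))
  } else {
    sub("^group=", "", as.character(s$strata))
  }
  df <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                   n_event = s$n.event, survival = s$surv,
                   stringsAsFactors = FALSE)
  structure(list(curves = split(df[-1L], df$group), survfit = fit),
            class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    cat(sprintf("%-14s %3d event times, final survival %.3f\n",
                g, sum(cv$n_event > 0), min(c(1, cv$survival))))
  }
  invisible(x)
}

#' Write KM curves as TSV
#'
#' @param km a `km_curves` object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_km <- function(km, path) {
  df <- do.call(rbind, lapply(names(km$curves), function(g) {
    cbind(group = g, km$curves[[g]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-rank test for linear trend across ordered groups
#'
#' At each distinct event time the observed minus expected event count per
#' group is computed under the conditional hypergeometric model; the trend
#' statistic is `(sum_j s_j (O_j - E_j))^2 / Var(sum_j s_j (O_j - E_j))`
#' with equally spaced group scores `s_j = 0, 1, 2, ...` by default, referred
#' to a chi-square with 1 degree of freedom. With two groups this reduces to
#' the standard two-sample log-rank test. The statistic is invariant to
#' affine transforms of the group scores.
#'
#' @param time follow-up times (> 0).
#' @param event logical event indicator.
#' @param group ordered grouping factor (>= 2 nonempty groups).
#' @param scores numeric group scores for the trend (default equally spaced).
#' @return A list of class `logrank_trend`: `statistic`, `df` (= 1),
#'   `p.value`, per-group `observed` and `expected`, and the `scores` used.
#' @export
logrank_trend <- function(time, event, group, scores = NULL) {
  event <- as.logical(event)
  if (any(time <= 0)) stop("times must be strictly positive", call. = FALSE)
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("at least two nonempty groups are required", call. = FALSE)
  scores <- scores %||% (seq_len(k) - 1)
  if (length(scores) != k) stop("`scores` must match the number of groups", call. = FALSE)

  gi <- as.integer(group)
  event_times <- sort(unique(time[event]))
  u <- 0
  v <- 0
  observed <- expected <- stats::setNames(numeric(k), levels(group))
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- tabulate(gi[at_risk], nbins = k)
    dj <- tabulate(gi[at_risk & event & time == t], nbins = k)
    d <- sum(dj)
    if (d == 0L || n < 2L) next
    ej <- d * nj / n
    observed <- observed + dj
    expected <- expected + ej
    u <- u + sum(scores * (dj - ej))
    # covariance of (d_j) under the multivariate hypergeometric draw
    f <- d * (n - d) / (n - 1) / n
    vjj <- f * nj * (n - nj) / n
    vt <- sum(scores^2 * vjj)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        vt <- vt - 2 * scores[a] * scores[b] * f * nj[a] * nj[b] / n
      }
    }
    v <- v + vt
  }
  if (v <= 0) stop("trend variance is zero; no usable event times", call. = FALSE)
  stat <- u^2 / v
  structure(list(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 observed = observed, expected = expected,
                 scores = stats::setNames(scores, levels(group))),
            class = "logrank_trend")
}

#' @export
print.logrank_trend <- function(x, ...) {
  cat(sprintf("Log-rank test for linear trend: chi-square = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2),
                   score = x$scores))
  invisible(x)
}
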