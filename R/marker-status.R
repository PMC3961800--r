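#' ER marker score
#'
#' The ER score of a sample is simply the linear-scale intensity of the
#' designated ER marker feature (on Affymetrix U133A, the probe set
#' 205225_at is the usual choice).
#'
#' @param expr an [expression_matrix()].
#' @param er_feature_id feature id of the ER marker probe.
#' @return Named numeric vector of per-sample scores.
#' @export
er_score <- function(expr, er_feature_id) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!er_feature_id %in% feature_ids(expr)) {
    stop(sprintf("ER feature '%s' not present in the expression matrix",
                 er_feature_id), call. = FALSE)
  }
  expr$values[, er_feature_id]
}

#' HER2 rank-sum score
#'
#' HER2 amplification status is scored as the sum, over the four co-amplified
#' HER2-region probes (canonically ERBB2, GRB7, STARD3 and PGAP3), of each
#' sample's ascending expression rank for that probe (average ranks on ties).
#' Scores therefore lie in [4, 4 n] and are invariant to any monotone
#' transform of each feature's values.
#'
#' @param expr an [expression_matrix()] with at least 2 samples.
#' @param her2_feature_ids character vector of exactly four feature ids.
#' @return Named numeric vector of per-sample rank-sum scores.
#' @export
her2_rank_sum <- function(expr, her2_feature_ids) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(her2_feature_ids) != 4L) {
    stop("exactly four HER2-region features are required", call. = FALSE)
  }
  missing <- setdiff(her2_feature_ids, feature_ids(expr))
  if (length(missing)) {
    stop("HER2 feature(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (n_samples(expr) < 2L) stop("at least 2 samples required", call. = FALSE)
  ranks <- vapply(her2_feature_ids,
                  function(f) rank(expr$values[, f]),
                  numeric(n_samples(expr)))
  stats::setNames(rowSums(ranks), sample_ids(expr))
}

# Two- or three-component univariate Gaussian mixture boundaries: fit by EM
# (mclust, unequal variances), assign each value to its maximum-responsibility
# component, and take as boundary k the maximum value assigned to the k-th
# lowest-mean component. EM is restarted from several initializations
# (mclust's hierarchical default, k-means, and equal-count quantile splits)
# and the highest-log-likelihood fit wins: a single deterministic start can
# land in a split-bulk local optimum when one component is narrow.
# For exactly-separable degenerate inputs where every EM collapses, an exact
# k-means split stands in (only when essentially perfect).
mixture_boundaries <- function(scores, g, min_weight = 0.01) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  if (length(scores) < 20L) {
    warning(sprintf("only %d values supplied; mixture cutoffs are unstable below 20",
                    length(scores)))
  }
  if (stats::var(scores) == 0) {
    stop("scores are constant; mixture cutoff undefined", call. = FALSE)
  }
  fit <- best_mixture_fit(scores, g)
  if (is.null(fit)) {
    uq <- sort(unique(scores))
    if (length(uq) < g) {
      stop("mixture model fit is degenerate; supply a manual cutoff",
           call. = FALSE)
    }
    ctr <- matrix(stats::quantile(uq, probs = seq(0, 1, length.out = g),
                                  names = FALSE), ncol = 1)
    km <- stats::kmeans(scores, centers = ctr)
    if (km$betweenss / km$totss < 0.999) {
      stop("mixture model fit is degenerate; supply a manual cutoff",
           call. = FALSE)
    }
    mu <- tapply(scores, km$cluster, mean)
    ord <- order(mu)
    classification <- match(km$cluster, ord)
    weights <- as.numeric(table(factor(km$cluster, levels = ord))) / length(scores)
    means <- as.numeric(mu[ord])
    sds <- rep(0, g)
  } else {
    pro <- fit$parameters$pro
    if (any(pro < min_weight) || length(unique(fit$classification)) < g) {
      stop(sprintf("mixture component collapsed (min weight %.3f); supply a manual cutoff or use the quantile fallback",
                   min(pro)), call. = FALSE)
    }
    mu <- fit$parameters$mean
    ord <- order(mu)
    classification <- match(fit$classification, ord)
    weights <- pro[ord]
    means <- as.numeric(mu[ord])
    sds <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sds) == 1L) sds <- rep(sds, g)
    sds <- sds[ord]
  }
  boundaries <- vapply(seq_len(g - 1L),
                       function(k) max(scores[classification == k]),
                       numeric(1))
  sep <- min(diff(means) / pmax(apply(cbind(sds[-g], sds[-1]), 1, max), 1e-12))
  if (min(weights) < 0.05 || sep < 2) {
    warning(sprintf(
      "low-confidence mixture cutoff: mixing weights [%s], component separation %.2f sd",
      paste(sprintf("%.3f", weights), collapse = ", "), sep))
  }
  list(boundaries = boundaries, means = means, sds = sds, weights = weights,
       classification = classification)
}

# Fit a G-component unequal-variance univariate Gaussian mixture, restarting
# EM from several initial partitions and keeping the highest log-likelihood
# fit. Returns an object with elements $parameters and $classification, or
# NULL when every start fails.
best_mixture_fit <- function(scores, g, n_kmeans_starts = 25L) {
  fits <- list()
  fits$mclust <- tryCatch(
    suppressWarnings(Mclust(scores, G = g, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL)

  em_from <- function(cl) {
    tryCatch({
      z <- unmap(cl, groups = seq_len(g))
      f <- suppressWarnings(me(data = scores, modelName = "V", z = z))
      if (is.null(f) || !is.finite(f$loglik)) return(NULL)
      f$classification <- map(f$z)
      f
    }, error = function(e) NULL)
  }

  km_cl <- tryCatch({
    km <- stats::kmeans(scores, centers = g, nstart = n_kmeans_starts)
    km$cluster
  }, error = function(e) NULL)
  if (!is.null(km_cl)) fits$kmeans <- em_from(km_cl)

  qcl <- as.integer(cut(rank(scores, ties.method = "first"),
                        breaks = g, labels = FALSE))
  fits$quantile <- em_from(qcl)
  # heavy-tail split: isolate the top tail as its own start
  if (g == 2L) {
    tail_cl <- ifelse(scores > stats::quantile(scores, 0.9), 2L, 1L)
    if (length(unique(tail_cl)) == 2L) fits$tail <- em_from(tail_cl)
  }

  fits <- Filter(Negate(is.null), fits)
  fits <- Filter(function(f) is.finite(f$loglik %||% NA_real_), fits)
  if (!length(fits)) return(NULL)
  fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
}

#' Two-component mixture-model cutoff
#'
#' Fits a two-component univariate Gaussian mixture (unequal variances) to the
#' scores by EM, assigns each value to its maximum-responsibility component,
#' and returns the maximum value assigned to the lower-mean component as the
#' cutoff. Positivity downstream is strictly greater-than: the cutoff value
#' itself belongs to the negative (lower) class. A warning flags
#' low-confidence fits (mixing weight < 0.05 or component separation < 2 sd);
#' a collapsed component (weight < 0.01) is an error advising a manual cutoff.
#'
#' @param scores numeric vector of per-sample marker scores (>= 20 values
#'   recommended; fewer triggers a warning).
#' @param min_weight mixing-weight floor below which the fit is rejected.
#' @return The cutoff (numeric scalar) with attributes `means`, `sds` and
#'   `weights` describing the fitted components.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 0), rnorm(100, 10))
#' cut <- mixture_cutoff(x)
#' @export
mixture_cutoff <- function(scores, min_weight = 0.01) {
  fit <- mixture_boundaries(scores, g = 2L, min_weight = min_weight)
  structure(fit$boundaries[1L], means = fit$means, sds = fit$sds,
            weights = fit$weights)
}

#' Array-based ER and HER2 status calls
#'
#' Computes per-sample ER scores ([er_score()]) and HER2 rank-sum scores
#' ([her2_rank_sum()]), derives a cutoff for each by two-component
#' mixture-model clustering ([mixture_cutoff()]), and calls a sample positive
#' when its score strictly exceeds the cutoff.
#'
#' Intensity mixtures on microarrays are approximately log-normal within
#' mode, so by default the ER mixture is fitted on log2 intensities and the
#' resulting cutoff back-transformed to the linear scale (the positivity
#' call is unchanged by any monotone transform; the fit is just much better
#' conditioned). The HER2 rank-sum score is already rank-based and is fitted
#' as-is.
#'
#' @param expr an [expression_matrix()].
#' @param er_feature_id ER marker feature id.
#' @param her2_feature_ids four HER2-region feature ids.
#' @param log2_er fit the ER mixture on the log2 scale (default TRUE).
#' @return Data frame (`sample_id`, `er_score`, `er_array`, `her2_score`,
#'   `her2_array`) with attributes `er_cutoff` and `her2_cutoff`.
#' @export
call_status <- function(expr, er_feature_id, her2_feature_ids,
                        log2_er = TRUE) {
  er <- er_score(expr, er_feature_id)
  her2 <- her2_rank_sum(expr, her2_feature_ids)
  er_cut <- if (log2_er) 2^mixture_cutoff(log2(er)) else mixture_cutoff(er)
  her2_cut <- mixture_cutoff(her2)
  structure(
    data.frame(sample_id = sample_ids(expr),
               er_score = unname(er),
               er_array = ifelse(er > as.numeric(er_cut), "+", "-"),
               her2_score = unname(her2),
               her2_array = ifelse(her2 > as.numeric(her2_cut), "+", "-"),
               stringsAsFactors = FALSE),
    er_cutoff = as.numeric(er_cut),
    her2_cutoff = as.numeric(her2_cut))
}

#' Write status calls and their cutoffs
#'
#' @param status output of [call_status()].
#' @param path TSV path for the per-sample calls.
#' @param cutoff_path optional sidecar TSV recording the two cutoffs.
#' @return `path`, invisibly.
#' @export
write_status <- function(status, path, cutoff_path = NULL) {
  utils::write.table(status, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cutoff_path)) {
    utils::write.table(
      data.frame(marker = c("er", "her2"),
                 cutoff = c(attr(status, "er_cutoff"),
                            attr(status, "her2_cutoff"))),
      cutoff_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
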