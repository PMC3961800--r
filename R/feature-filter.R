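#' Probe-filtering configuration
#'
#' Defaults follow the standard preprocessing regime for GCRMA-normalized
#' linear intensities: a feature is retained when it exceeds the background
#' threshold (raw value > 100) in at least 20% of samples and its coefficient
#' of variation (sd/mean, computed on the linear scale) lies between 0.7 and
#' 10.
#'
#' @param background_threshold linear intensity above which a value counts as
#'   expressed.
#' @param min_expressed_fraction minimum fraction of samples above background.
#' @param cov_min,cov_max retained band for the coefficient of variation.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(background_threshold = 100,
                          min_expressed_fraction = 0.20,
                          cov_min = 0.7, cov_max = 10) {
  if (!is_fraction(min_expressed_fraction)) {
    stop("`min_expressed_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (cov_min >= cov_max) stop("`cov_min` must be < `cov_max`", call. = FALSE)
  structure(list(background_threshold = background_threshold,
                 min_expressed_fraction = min_expressed_fraction,
                 cov_min = cov_min, cov_max = cov_max),
            class = "filter_config")
}

#' Filter features by expressed fraction and coefficient of variation
#'
#' Keeps a feature iff the fraction of samples with linear value above
#' `background_threshold` is at least `min_expressed_fraction` and its COV
#' (sd/mean on the linear scale) lies in `[cov_min, cov_max]`. The operation
#' is idempotent and invariant to feature order.
#'
#' @param expr an [expression_matrix()] of linear-scale values.
#' @param cfg a [filter_config()].
#' @return Character vector of retained feature ids, with a `stats` attribute
#'   (per-feature expressed fraction, mean, sd, COV).
#' @examples
#' m <- matrix(c(rep(50, 8), 2000, 2000), 10, 1,
#'             dimnames = list(paste0("s", 1:10), "ft1"))
#' filter_features(expression_matrix(m))  # retained: COV ~1.87, 20% expressed
#' @export
filter_features <- function(expr, cfg = filter_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(cfg, "filter_config"))
  v <- expr$values
  frac <- colMeans(v > cfg$background_threshold)
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  cov <- sdv / mu
  keep <- frac >= cfg$min_expressed_fraction &
    cov >= cfg$cov_min & cov <= cfg$cov_max
  keep[is.na(keep)] <- FALSE
  stats_df <- data.frame(feature_id = feature_ids(expr),
                         expressed_fraction = unname(frac),
                         mean = unname(mu), sd = unname(sdv),
                         cov = unname(cov),
                         retained = unname(keep),
                         stringsAsFactors = FALSE)
  structure(feature_ids(expr)[keep], stats = stats_df)
}

#' Global reference-gene selection
#'
#' Selects stable, highly expressed features suitable as normalization
#' references on platforms that need them. Steps, applied in order: (1) keep
#' features expressed above the background threshold (raw value > 100) in at
#' least 99% of samples; (2) keep only the top 5th percentile of the
#' survivors by mean expression; (3) keep only the top 10th percentile of the
#' remainder by standard deviation; (4) rank survivors by COV ascending (most
#' stable first) and return the top `n_top`.
#'
#' Step (3) as stated keeps the *most* variable remainder, which is atypical
#' for reference genes; `sd_direction = "bottom"` flips it to the least
#' variable.
#'
#' @param expr an [expression_matrix()].
#' @param n_top number of reference features to return.
#' @param expressed_fraction required fraction of samples above background.
#' @param background_threshold linear background intensity.
#' @param sd_direction `"top"` (as stated) or `"bottom"` (least variable).
#' @return Data frame of the selected features (`feature_id`, `gene_symbol`,
#'   `mean`, `sd`, `cov`), ranked by COV ascending; empty with a warning if
#'   nothing survives.
#' @export
select_reference_genes_global <- function(expr, n_top = 25L,
                                          expressed_fraction = 0.99,
                                          background_threshold = 100,
                                          sd_direction = c("top", "bottom")) {
  stopifnot(inherits(expr, "expr_matrix"))
  sd_direction <- match.arg(sd_direction)
  if (n_samples(expr) < 100L) {
    warning("fewer than 100 samples; reference-gene selection may be unstable")
  }
  v <- expr$values
  frac <- colMeans(v > background_threshold)
  pool <- feature_ids(expr)[frac >= expressed_fraction]
  if (!length(pool)) {
    warning("no features expressed above background in the required fraction of samples")
    return(reference_frame(expr, character(0)))
  }
  mu <- colMeans(v[, pool, drop = FALSE])
  pool <- pool[mu >= stats::quantile(mu, 0.95)]
  sdv <- apply(v[, pool, drop = FALSE], 2, stats::sd)
  q <- stats::quantile(sdv, if (sd_direction == "top") 0.90 else 0.10)
  pool <- if (sd_direction == "top") pool[sdv >= q] else pool[sdv <= q]
  if (!length(pool)) {
    warning("no features survive the reference-gene filters")
    return(reference_frame(expr, character(0)))
  }
  out <- reference_frame(expr, pool)
  out <- out[order(out$cov, out$feature_id), ]
  utils::head(out, n_top)
}

#' Banded reference-gene selection
#'
#' Selects per-band reference features in three closed intervals of mean
#' linear expression (defaults: low 0-400, medium 500-900, high 1,200-1,600).
#' Within each band, features expressed above background in at least 99% of
#' samples are ranked by COV ascending and the top `n_top` returned.
#'
#' @inheritParams select_reference_genes_global
#' @param bands named list of `c(lower, upper)` closed intervals on mean
#'   linear intensity.
#' @param n_top features returned per band.
#' @return Named list of per-band data frames (see
#'   [select_reference_genes_global()]); empty bands yield empty frames with
#'   a warning.
#' @export
select_reference_genes_banded <- function(expr,
                                          bands = list(low = c(0, 400),
                                                       medium = c(500, 900),
                                                       high = c(1200, 1600)),
                                          n_top = 5L,
                                          expressed_fraction = 0.99,
                                          background_threshold = 100) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (n_samples(expr) < 100L) {
    warning("fewer than 100 samples; reference-gene selection may be unstable")
  }
  v <- expr$values
  frac <- colMeans(v > background_threshold)
  mu <- colMeans(v)
  lapply(bands, function(b) {
    pool <- feature_ids(expr)[frac >= expressed_fraction &
                                mu >= b[1] & mu <= b[2]]
    if (!length(pool)) {
      warning(sprintf("no reference candidates with mean in [%g, %g]", b[1], b[2]))
      return(reference_frame(expr, character(0)))
    }
    out <- reference_frame(expr, pool)
    out <- out[order(out$cov, out$feature_id), ]
    utils::head(out, n_top)
  })
}

reference_frame <- function(expr, features) {
  if (!length(features)) {
    return(data.frame(feature_id = character(0), gene_symbol = character(0),
                      mean = numeric(0), sd = numeric(0), cov = numeric(0),
                      stringsAsFactors = FALSE))
  }
  v <- expr$values[, features, drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  data.frame(feature_id = features,
             gene_symbol = unname(expr$feature_to_gene[features]),
             mean = unname(mu), sd = unname(sdv), cov = unname(sdv / mu),
             row.names = NULL, stringsAsFactors = FALSE)
}
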