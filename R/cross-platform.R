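#' Rescale an external cohort onto the training distribution
#'
#' Quantile-maps each external sample's values onto the pooled reference
#' (training) distribution: the r-th smallest of a sample's p values becomes
#' the (r - 0.5)/p quantile of the pooled reference values. Rank order within
#' a sample is preserved exactly, so downstream scoring is invariant to any
#' per-sample strictly monotone (e.g. affine) distortion of the external
#' platform's scale.
#'
#' @param expr external cohort: an [expression_matrix()] or numeric matrix
#'   (samples x features).
#' @param reference training distribution: an [expression_matrix()] or
#'   numeric vector of pooled training values.
#' @return Rescaled data of the same class/shape as `expr`.
#' @export
rescale_to_reference <- function(expr, reference) {
  is_em <- inherits(expr, "expr_matrix")
  values <- if (is_em) expr$values else as.matrix(expr)
  ref <- if (inherits(reference, "expr_matrix")) {
    as.numeric(reference$values)
  } else {
    as.numeric(reference)
  }
  if (anyNA(ref) || !length(ref)) stop("invalid reference distribution", call. = FALSE)
  ref <- sort(ref)
  p <- ncol(values)
  out <- t(apply(values, 1, function(x) {
    if (stats::sd(x) == 0) {
      stop("constant sample profile cannot be quantile-rescaled", call. = FALSE)
    }
    stats::quantile(ref, probs = (rank(x) - 0.5) / p, names = FALSE, type = 7)
  }))
  dimnames(out) <- dimnames(values)
  if (is_em) expression_matrix(out, expr$feature_to_gene) else out
}

#' Choose one platform probe per signature gene
#'
#' When several probes on an external platform map to the same signature
#' gene, one must be chosen. The default criterion keeps the probe with the
#' highest variance across samples (needs no outcome labels); alternatives
#' are highest mean and highest univariate AUC against supplied labels. Genes
#' with no candidate probe are reported missing, so that scoring can fail
#' fast naming them.
#'
#' @param candidates named list: gene symbol -> character vector of candidate
#'   feature ids on the external platform.
#' @param expr external [expression_matrix()].
#' @param criterion `"variance"`, `"mean"` or `"auc"`.
#' @param labels logical event labels (required for `criterion = "auc"`).
#' @return Data frame of class `platform_map` (`gene`, `chosen_feature`,
#'   `criterion`, `criterion_value`, `n_candidates`, `missing`).
#' @export
choose_probe_per_gene <- function(candidates, expr,
                                  criterion = c("variance", "mean", "auc"),
                                  labels = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(expr, "expr_matrix"))
  if (!length(candidates) || is.null(names(candidates))) {
    stop("`candidates` must be a nonempty named list (gene -> feature ids)",
         call. = FALSE)
  }
  if (criterion == "auc" && is.null(labels)) {
    stop("criterion \"auc\" requires `labels`", call. = FALSE)
  }
  score_feature <- function(f) {
    v <- expr$values[, f]
    switch(criterion,
           variance = stats::var(v),
           mean = mean(v),
           auc = roc_auc(v, labels))
  }
  rows <- lapply(names(candidates), function(g) {
    feats <- intersect(candidates[[g]], feature_ids(expr))
    if (!length(feats)) {
      return(data.frame(gene = g, chosen_feature = NA_character_,
                        criterion = criterion, criterion_value = NA_real_,
                        n_candidates = 0L, missing = TRUE,
                        stringsAsFactors = FALSE))
    }
    val <- vapply(feats, score_feature, numeric(1))
    best <- feats[order(-val, feats)][1L]
    data.frame(gene = g, chosen_feature = best, criterion = criterion,
               criterion_value = max(val), n_candidates = length(feats),
               missing = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$missing)) {
    warning("no candidate probe for gene(s): ",
            paste(out$gene[out$missing], collapse = ", "))
  }
  class(out) <- c("platform_map", class(out))
  out
}

#' Map an external cohort onto a signature's gene space
#'
#' Applies a platform map to produce an expression matrix whose features are
#' the signature genes themselves, ready for [rfrs_score()]. Fails fast,
#' listing the genes, if any mapped probe is missing.
#'
#' @param map a `platform_map` from [choose_probe_per_gene()].
#' @param expr external [expression_matrix()].
#' @return An [expression_matrix()] with one column per mapped gene.
#' @export
apply_platform_map <- function(map, expr) {
  stopifnot(inherits(map, "platform_map"), inherits(expr, "expr_matrix"))
  if (any(map$missing)) {
    stop("cannot score: missing probes for gene(s): ",
         paste(map$gene[map$missing], collapse = ", "), call. = FALSE)
  }
  v <- expr$values[, map$chosen_feature, drop = FALSE]
  colnames(v) <- map$gene
  expression_matrix(v)
}
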