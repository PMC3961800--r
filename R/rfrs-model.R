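#' Train the relapse classifier and compute out-of-bag RFRS
#'
#' Fits a random forest of `n_trees` classification trees (bootstrap sample
#' per tree, random feature subset of size floor(sqrt(p)) per split,
#' unlimited depth) to the binarized 10-year outcome. The Random Forests
#' Relapse Score (RFRS) of each training sample is the fraction of trees, among
#' those for which the sample was out-of-bag, voting "relapse" — an internal
#' cross-validation estimate. `n_trees` must be odd so that the binary vote
#' can never tie; the canonical forest size is 100,001 trees, which makes the
#' vote fractions stable to the third decimal (smaller forests trade that
#' stability for speed, not accuracy).
#'
#' @param expr an [expression_matrix()] restricted to the retained features;
#'   only samples labeled `relapse` / `no_relapse` are used.
#' @param labels either the data frame from [binarize_ten_year()] or a named
#'   character/factor vector of `"relapse"` / `"no_relapse"` labels.
#' @param n_trees odd number of trees (default 100,001).
#' @param mtry features tried per split (default floor(sqrt(p))).
#' @param seed integer seed; training is bit-reproducible under a fixed seed.
#' @return An object of class `rfrs_model`: the fitted forest, the ordered
#'   feature list and its gene map, per-training-sample OOB scores
#'   (`oob_scores`), per-feature Gini importance (`importance`), and
#'   `n_trees`.
#' @export
rfrs_train <- function(expr, labels, n_trees = 100001L, mtry = NULL,
                       seed = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  n_trees <- assert_count(n_trees, "n_trees")
  if (n_trees %% 2L == 0L) {
    stop("`n_trees` must be odd so the relapse vote can never tie", call. = FALSE)
  }
  y <- coerce_labels(labels)
  use <- intersect(sample_ids(expr), names(y))
  y <- y[use]
  if (min(table(y)) < 2L) {
    stop("need at least 2 training samples in each class (relapse / no_relapse)",
         call. = FALSE)
  }
  x <- expr$values[use, , drop = FALSE]
  rf <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(x))))))
  oob <- rf$votes[, "relapse"]
  imp <- stats::setNames(rf$importance[, "MeanDecreaseGini"], rownames(rf$importance))
  structure(list(forest = rf,
                 feature_ids = colnames(x),
                 feature_to_gene = expr$feature_to_gene[colnames(x)],
                 oob_scores = oob,
                 importance = imp,
                 n_trees = n_trees,
                 seed = seed,
                 classes = levels(y)),
            class = "rfrs_model")
}

coerce_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "class") %in% names(labels)))
    keep <- labels$class %in% c("relapse", "no_relapse")
    labels <- stats::setNames(as.character(labels$class[keep]),
                              labels$sample_id[keep])
  }
  if (is.null(names(labels))) stop("labels must be named by sample id", call. = FALSE)
  labels <- labels[labels %in% c("relapse", "no_relapse")]
  factor(labels, levels = c("no_relapse", "relapse"))
}

#' @export
print.rfrs_model <- function(x, ...) {
  cat(sprintf("<rfrs_model> %d trees, %d features, %d training samples\n",
              x$n_trees, length(x$feature_ids), length(x$oob_scores)))
  cat(sprintf("  OOB score range: [%.3f, %.3f]\n",
              min(x$oob_scores), max(x$oob_scores)))
  invisible(x)
}

#' Score new samples with a trained RFRS model
#'
#' Runs every tree of the forest on each input sample; the RFRS is the
#' fraction of trees voting "relapse", always in [0, 1]. Model features are
#' matched to input columns first by feature id and otherwise by gene symbol
#' (so patient tables keyed by gene symbol score directly); any unmatched
#' feature is an error naming the missing genes.
#'
#' @param model an `rfrs_model`.
#' @param expr an [expression_matrix()] (or numeric matrix with sample rows)
#'   of new samples.
#' @return Named numeric vector of RFRS values in [0, 1].
#' @export
rfrs_score <- function(model, expr) {
  stopifnot(inherits(model, "rfrs_model"))
  if (is.matrix(expr)) expr <- expression_matrix(expr)
  stopifnot(inherits(expr, "expr_matrix"))
  cols <- feature_ids(expr)
  by_gene <- stats::setNames(cols, unname(expr$feature_to_gene[cols]))
  pick <- ifelse(model$feature_ids %in% cols,
                 model$feature_ids,
                 by_gene[unname(model$feature_to_gene)])
  if (anyNA(pick)) {
    missing_genes <- unname(model$feature_to_gene[is.na(pick)])
    stop("input is missing model gene(s): ",
         paste(unique(missing_genes), collapse = ", "), call. = FALSE)
  }
  x <- expr$values[, pick, drop = FALSE]
  colnames(x) <- model$feature_ids
  votes <- stats::predict(model$forest, x, type = "vote")
  stats::setNames(votes[, "relapse"], sample_ids(expr))
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' The area under the ROC curve computed as the probability that a randomly
#' chosen event sample scores above a randomly chosen non-event sample, with
#' tied scores counted 1/2. Invariant to any strictly monotone transform of
#' the scores.
#'
#' @param scores numeric vector of scores (higher = more event-like).
#' @param labels logical (or 0/1) event indicator, same length; both classes
#'   must be present.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.4, 0.35, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("`scores` and `labels` must be equal-length and non-missing", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write per-sample RFRS scores as TSV
#'
#' @param scores named numeric vector of scores.
#' @param path output TSV (`sample_id`, `rfrs`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(
    data.frame(sample_id = names(scores), rfrs = signif(unname(scores), 6)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
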