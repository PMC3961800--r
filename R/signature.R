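#' Collapse a feature-level importance ranking to gene level
#'
#' When several probes map to the same gene, the probe with the highest Gini
#' importance represents the gene; the result is a gene-level ranking ordered
#' by importance (ties broken alphabetically by gene symbol, for
#' determinism).
#'
#' @param importance named numeric vector of per-feature Gini importances.
#' @param feature_to_gene named character vector mapping feature id to gene
#'   symbol (names = feature ids).
#' @return Data frame (`gene`, `feature_id`, `importance`) with one row per
#'   gene, sorted by decreasing importance.
#' @export
dedup_gene_importance <- function(importance, feature_to_gene) {
  if (is.null(names(importance))) {
    stop("`importance` must be named by feature id", call. = FALSE)
  }
  genes <- unname(feature_to_gene[names(importance)])
  if (anyNA(genes)) stop("`feature_to_gene` must cover every feature", call. = FALSE)
  df <- data.frame(gene = genes, feature_id = names(importance),
                   importance = unname(importance), stringsAsFactors = FALSE)
  df <- df[order(-df$importance, df$gene, df$feature_id), ]
  df <- df[!duplicated(df$gene), ]
  rownames(df) <- NULL
  df
}

#' Compact a gene ranking into a primary/alternate signature
#'
#' Takes the `top_n` genes by importance, clusters them into `k` groups by
#' k-means on their standardized (per-gene z-scored, log2) expression
#' profiles across training samples, removes excluded genes, and within each
#' surviving cluster designates the highest-importance gene as the primary
#' and the rest, ordered by importance, as its alternates. Clusters emptied
#' by exclusions are dropped, so the signature may have fewer than `k`
#' primaries (e.g. a 10-gene exclusion emptying 3 of 20 clusters leaves 17
#' primaries and 73 alternates from a top-100 pool). Alternates exist so a
#' primary that fails to migrate to another assay platform can be replaced by
#' a correlated neighbor.
#'
#' k-means uses k-means++ seeding with 100 restarts, making the
#' clustering deterministic under a fixed seed and robust to merge/split
#' local optima.
#'
#' @param gene_ranking gene-level ranking from [dedup_gene_importance()].
#' @param expr an [expression_matrix()] over the training samples.
#' @param k number of clusters requested.
#' @param top_n size of the importance pool to cluster.
#' @param exclusions character vector of gene symbols to drop after
#'   clustering (alignment failures, hypothetical proteins, ...).
#' @param nstart k-means++ restarts.
#' @param seed integer seed.
#' @return An object of class `rfrs_signature`: `clusters` (list, each with
#'   `primary`, `importance`, and an `alternates` data frame), plus
#'   `k_requested`, `top_n`, `exclusions_applied`, and the clustered `pool`.
#' @export
compact_signature <- function(gene_ranking, expr, k = 20L, top_n = 100L,
                              exclusions = character(), nstart = 100L,
                              seed = NULL) {
  stopifnot(inherits(expr, "expr_matrix"),
            all(c("gene", "feature_id", "importance") %in% names(gene_ranking)))
  top_n <- assert_count(top_n, "top_n")
  k <- assert_count(k, "k")
  if (top_n > nrow(gene_ranking)) {
    stop("`top_n` exceeds the number of available genes", call. = FALSE)
  }
  if (k > top_n) stop("`k` cannot exceed `top_n`", call. = FALSE)
  pool <- gene_ranking[seq_len(top_n), ]
  exclusions_applied <- intersect(exclusions, pool$gene)
  if (k > top_n - length(exclusions_applied)) {
    stop("`k` exceeds the number of genes remaining after exclusions", call. = FALSE)
  }
  missing <- setdiff(pool$feature_id, feature_ids(expr))
  if (length(missing)) {
    stop("expression matrix lacks pooled feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }

  # genes as points in sample space: log2, per-gene z-score
  x <- t(log2(expr$values[, pool$feature_id, drop = FALSE]))
  xz <- x - rowMeans(x)
  rsd <- apply(xz, 1, stats::sd)
  xz <- xz / ifelse(rsd > 0, rsd, 1)
  km <- with_seed(seed, kmeans_pp(xz, k, nstart = nstart))
  assignment <- stats::setNames(km$cluster, pool$gene)

  clusters <- lapply(seq_len(k), function(ci) {
    members <- pool[km$cluster == ci & !pool$gene %in% exclusions_applied, ]
    if (!nrow(members)) return(NULL)
    members <- members[order(-members$importance, members$gene), ]
    list(primary = members$gene[1L],
         importance = members$importance[1L],
         alternates = data.frame(gene = members$gene[-1L],
                                 importance = members$importance[-1L],
                                 stringsAsFactors = FALSE))
  })
  clusters <- clusters[!vapply(clusters, is.null, logical(1))]
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "importance"))]
  structure(list(clusters = clusters,
                 k_requested = k,
                 top_n = top_n,
                 exclusions_applied = exclusions_applied,
                 pool = pool,
                 cluster_assignment = assignment),
            class = "rfrs_signature")
}

#' Eight-gene signature variant
#'
#' Rebuilds the compaction from the top 90 genes after pre-removing the
#' exclusion list from the ranking (so the pool is the top-100 minus the ~10
#' problem genes), with k = 8 clusters.
#'
#' @inheritParams compact_signature
#' @export
eight_gene_signature <- function(gene_ranking, expr, exclusions = character(),
                                 top_n = 90L, k = 8L, nstart = 100L,
                                 seed = NULL) {
  kept <- gene_ranking[!gene_ranking$gene %in% exclusions, ]
  compact_signature(kept, expr, k = k, top_n = top_n,
                    exclusions = character(), nstart = nstart, seed = seed)
}

#' @rdname compact_signature
#' @param sig an `rfrs_signature`.
#' @export
primary_genes <- function(sig) {
  stopifnot(inherits(sig, "rfrs_signature"))
  vapply(sig$clusters, `[[`, character(1), "primary")
}

#' @rdname compact_signature
#' @export
alternate_genes <- function(sig) {
  stopifnot(inherits(sig, "rfrs_signature"))
  unlist(lapply(sig$clusters, function(cl) cl$alternates$gene),
         use.names = FALSE)
}

#' @export
print.rfrs_signature <- function(x, ...) {
  cat(sprintf("<rfrs_signature> %d primaries (k requested %d), %d alternates, %d exclusions applied\n",
              length(x$clusters), x$k_requested,
              length(alternate_genes(x)), length(x$exclusions_applied)))
  print(utils::head(signature_table(x), 8))
  invisible(x)
}

#' Wide signature table (primary + top alternates)
#'
#' @param sig an `rfrs_signature`.
#' @param n_alternates alternates shown per primary.
#' @return Data frame, one row per primary: gene/importance pairs for the
#'   primary and its top `n_alternates` alternates (NA where absent).
#' @export
signature_table <- function(sig, n_alternates = 2L) {
  stopifnot(inherits(sig, "rfrs_signature"))
  rows <- lapply(sig$clusters, function(cl) {
    out <- list(primary = cl$primary, importance = cl$importance)
    for (i in seq_len(n_alternates)) {
      out[[sprintf("alternate%d", i)]] <-
        if (i <= nrow(cl$alternates)) cl$alternates$gene[i] else NA_character_
      out[[sprintf("alternate%d_importance", i)]] <-
        if (i <= nrow(cl$alternates)) cl$alternates$importance[i] else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format signature listing
#'
#' @param sig an `rfrs_signature`.
#' @return Data frame (`cluster`, `role`, `rank`, `gene`, `importance`) with
#'   every primary and alternate.
#' @export
signature_long <- function(sig) {
  stopifnot(inherits(sig, "rfrs_signature"))
  rows <- lapply(seq_along(sig$clusters), function(i) {
    cl <- sig$clusters[[i]]
    data.frame(cluster = i,
               role = c("primary", rep("alternate", nrow(cl$alternates))),
               rank = c(1L, seq_len(nrow(cl$alternates)) + 1L),
               gene = c(cl$primary, cl$alternates$gene),
               importance = c(cl$importance, cl$alternates$importance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a signature as wide and long TSVs
#'
#' @param sig an `rfrs_signature`.
#' @param path wide-format TSV path.
#' @param long_path optional long-format companion TSV.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, long_path = NULL) {
  utils::write.table(signature_table(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    utils::write.table(signature_long(sig), long_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
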