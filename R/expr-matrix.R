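#' Expression matrix container
#'
#' Lightweight container for a normalized expression matrix on the linear
#' intensity scale (samples in rows, probes/genes in columns) together with a
#' probe-to-gene-symbol map. All pipeline stages consume and produce this
#' class. Values must be strictly positive and finite; identifiers must be
#' unique.
#'
#' @param values numeric matrix, samples x features, with unique row and
#'   column names. Linear-scale intensities (not log-transformed).
#' @param feature_to_gene named character vector mapping feature (probe) ids
#'   to gene symbols. Defaults to the identity map on column names.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `feature_to_gene`.
#' @examples
#' m <- matrix(runif(12, 50, 500), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' x <- expression_matrix(m)
#' n_samples(x)
#' @export
expression_matrix <- function(values, feature_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample (row) and feature (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated feature ids", call. = FALSE)
  if (!all(is.finite(values)) || any(values <= 0)) {
    stop("expression values must be finite and strictly positive (linear scale)",
         call. = FALSE)
  }
  if (is.null(feature_to_gene)) {
    feature_to_gene <- stats::setNames(colnames(values), colnames(values))
  }
  feature_to_gene <- feature_to_gene[colnames(values)]
  if (anyNA(feature_to_gene)) {
    stop("`feature_to_gene` must cover every feature id", call. = FALSE)
  }
  structure(list(values = values, feature_to_gene = feature_to_gene),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d features (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$feature_to_gene))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by sample and/or feature ids
#'
#' @param x an `expr_matrix`.
#' @param samples,features character vectors of ids to keep (NULL keeps all).
#' @return An `expr_matrix` restricted to the requested ids, in the order given.
#' @export
subset_expr <- function(x, samples = NULL, features = NULL) {
  samples <- samples %||% sample_ids(x)
  features <- features %||% feature_ids(x)
  missing_s <- setdiff(samples, sample_ids(x))
  missing_f <- setdiff(features, feature_ids(x))
  if (length(missing_s)) {
    stop("unknown sample ids: ", paste(missing_s, collapse = ", "), call. = FALSE)
  }
  if (length(missing_f)) {
    stop("unknown feature ids: ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  expression_matrix(x$values[samples, features, drop = FALSE],
                    x$feature_to_gene[features])
}

#' Write / read the tab-delimited expression format
#'
#' The on-disk format is a TSV with a `sample_id` column followed by one
#' column per feature; the probe-to-gene map travels in a two-column sidecar
#' TSV (`feature_id`, `gene_symbol`).
#'
#' @param x an `expr_matrix`.
#' @param path path of the expression TSV.
#' @param gene_map_path optional path of the feature-to-gene sidecar TSV.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns an `expr_matrix`.
#' @export
write_expression_matrix <- function(x, path, gene_map_path = NULL) {
  df <- data.frame(sample_id = sample_ids(x),
                   signif(x$values, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_map_path)) {
    utils::write.table(
      data.frame(feature_id = names(x$feature_to_gene),
                 gene_symbol = unname(x$feature_to_gene)),
      gene_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path, gene_map_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("expression file must contain a `sample_id` column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- df$sample_id
  map <- NULL
  if (!is.null(gene_map_path)) {
    gm <- utils::read.delim(gene_map_path, stringsAsFactors = FALSE)
    map <- stats::setNames(gm$gene_symbol, gm$feature_id)
  }
  expression_matrix(m, map)
}

clinical_columns <- c("sample_id", "study_id", "er_clinical", "her2_clinical",
                      "ln_status", "chemo", "hormone_therapy",
                      "relapse_event", "followup_years")

#' Write / read the tab-delimited clinical table
#'
#' Columns: `sample_id`, `study_id`, `er_clinical` and `her2_clinical`
#' (`+`/`-`/empty for missing), `ln_status` (`negative`/`positive`/empty),
#' `chemo` and `hormone_therapy` (TRUE/FALSE), `relapse_event` (TRUE/FALSE),
#' `followup_years` (nonnegative; the event time when `relapse_event` is TRUE,
#' otherwise the censoring time).
#'
#' @param clinical a data frame with the columns above.
#' @param path file path.
#' @return `write_clinical_table` returns `path` invisibly;
#'   `read_clinical_table` returns a validated data frame.
#' @export
write_clinical_table <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  out <- clinical
  out$er_clinical[is.na(out$er_clinical)] <- ""
  out$her2_clinical[is.na(out$her2_clinical)] <- ""
  out$ln_status[is.na(out$ln_status)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_clinical(df)
}

validate_clinical <- function(clinical) {
  missing <- setdiff(clinical_columns, names(clinical))
  if (length(missing)) {
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  clinical <- clinical[clinical_columns]
  if (anyDuplicated(clinical$sample_id)) {
    stop("duplicated sample_id in clinical table", call. = FALSE)
  }
  chk <- function(x, allowed, name) {
    bad <- !is.na(x) & !x %in% allowed
    if (any(bad)) stop(sprintf("invalid %s value(s): %s", name,
                               paste(unique(x[bad]), collapse = ", ")),
                       call. = FALSE)
  }
  chk(clinical$er_clinical, c("+", "-"), "er_clinical")
  chk(clinical$her2_clinical, c("+", "-"), "her2_clinical")
  chk(clinical$ln_status, c("negative", "positive"), "ln_status")
  clinical$chemo <- as.logical(clinical$chemo)
  clinical$hormone_therapy <- as.logical(clinical$hormone_therapy)
  clinical$relapse_event <- as.logical(clinical$relapse_event)
  if (any(is.na(clinical$followup_years)) || any(clinical$followup_years < 0)) {
    stop("`followup_years` must be nonnegative and non-missing", call. = FALSE)
  }
  clinical
}
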