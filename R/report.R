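#' Read a patient expression table
#'
#' Patient data arrive as tab-delimited text with one column per signature
#' gene (header row of gene symbols) and one row per patient, containing
#' normalized linear-scale expression values. The columns are validated
#' against the required gene list: missing genes are an error naming them;
#' extra columns are ignored with a warning; non-numeric cells are rejected
#' with their row/column coordinates.
#'
#' @param path TSV path. The first column may be a `sample_id` column;
#'   otherwise patients are numbered `patient1`, `patient2`, ...
#' @param signature an `rfrs_signature` whose primary genes are required, or
#'   NULL if `genes` is given.
#' @param genes explicit character vector of required gene symbols
#'   (overrides `signature`).
#' @return An [expression_matrix()] with the required genes as features (in
#'   signature order).
#' @export
read_patient_table <- function(path, signature = NULL, genes = NULL) {
  if (is.null(genes)) {
    if (is.null(signature)) stop("supply `signature` or `genes`", call. = FALSE)
    genes <- primary_genes(signature)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!nrow(df)) stop("patient table is empty: ", path, call. = FALSE)
  if (names(df)[1L] == "sample_id") {
    ids <- df[[1L]]
    df <- df[-1L]
  } else {
    ids <- sprintf("patient%d", seq_len(nrow(df)))
  }
  missing <- setdiff(genes, names(df))
  if (length(missing)) {
    stop("patient table is missing required gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), genes)
  if (length(extra)) {
    warning("ignoring ", length(extra), " extra column(s): ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  df <- df[genes]
  m <- matrix(NA_real_, nrow(df), length(genes),
              dimnames = list(ids, genes))
  for (j in seq_along(genes)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "")
    if (length(bad) || anyNA(v)) {
      bad <- if (length(bad)) bad else which(is.na(v))
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1L], genes[j]), call. = FALSE)
    }
    m[, j] <- v
  }
  expression_matrix(m)
}

#' Per-patient RFRS report
#'
#' Combines RFRS values with a calibration bundle: each patient receives a
#' risk group (by the calibrated thresholds, with scores at a threshold
#' falling in the upper group) and an estimated 10-year relapse likelihood
#' with confidence bounds from the loess calibration curve. Scores outside
#' the curve's fitted support take the nearest-endpoint likelihood and are
#' flagged.
#'
#' @param scores named numeric vector of RFRS values (from [rfrs_score()]).
#' @param calibration an `rfrs_calibration` bundle.
#' @param model_id,signature_id optional identifier strings recorded on the
#'   report.
#' @return Data frame of class `patient_report` (`sample_id`, `rfrs`,
#'   `risk_group`, `likelihood`, `lower`, `upper`, `extrapolated`) with
#'   attributes `thresholds`, `model_id`, `signature_id`.
#' @export
make_report <- function(scores, calibration, model_id = NA_character_,
                        signature_id = NA_character_) {
  stopifnot(inherits(calibration, "rfrs_calibration"))
  if (is.null(names(scores))) {
    names(scores) <- sprintf("patient%d", seq_along(scores))
  }
  grp <- assign_risk_group(scores, calibration$thresholds)
  lik <- predict(calibration$curve, scores)
  out <- data.frame(sample_id = names(scores),
                    rfrs = unname(scores),
                    risk_group = grp,
                    likelihood = lik$likelihood,
                    lower = lik$lower,
                    upper = lik$upper,
                    extrapolated = lik$extrapolated,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- calibration$thresholds
  attr(out, "model_id") <- model_id
  attr(out, "signature_id") <- signature_id
  class(out) <- c("patient_report", class(out))
  out
}

#' @export
print.patient_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("RFRS patient report (%d patient(s); thresholds %.3f / %.3f)\n",
              nrow(x), th$t_low, th$t_high))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s RFRS %.3f -> %s risk; est. 10-y relapse likelihood %.1f%% (%.1f-%.1f%%)%s\n",
                x$sample_id[i], x$rfrs[i], x$risk_group[i],
                100 * x$likelihood[i], 100 * x$lower[i], 100 * x$upper[i],
                if (x$extrapolated[i]) " [outside curve support]" else ""))
  }
  invisible(x)
}

#' Write a patient report as TSV and/or JSON
#'
#' @param report a `patient_report`.
#' @param path TSV path.
#' @param json_path optional machine-readable JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, json_path = NULL) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    th <- attr(report, "thresholds")
    jsonlite::write_json(
      list(thresholds = list(t_low = th$t_low, t_high = th$t_high),
           model_id = attr(report, "model_id"),
           signature_id = attr(report, "signature_id"),
           patients = as.data.frame(report)),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
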