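#' Detect duplicate samples
#'
#' Groups samples that share an alias identifier (e.g. the same patient id
#' appearing under two array accessions) or whose expression profiles are
#' near-identical: pairwise Pearson correlation above `cor_threshold`
#' (default r > 0.99), computed over all features after log2 transform to
#' stabilize r against intensity outliers. Pairwise links are closed
#' transitively into groups and one representative per group is retained.
#'
#' The representative is the member from the study listed earliest in
#' `precedence` (default: study order of first appearance in `clinical`);
#' ties break on sample id. Without a clinical table, the first member in
#' matrix order is kept.
#'
#' @param expr an [expression_matrix()] with at least two samples.
#' @param clinical optional clinical table supplying `study_id` for
#'   representative selection.
#' @param cor_threshold correlation above which a pair is called duplicate.
#' @param precedence character vector of study ids in decreasing retention
#'   priority.
#' @param alias optional named character vector (names = sample ids); samples
#'   with equal non-missing alias values are grouped regardless of
#'   correlation.
#' @return A list of class `duplicate_groups`: `groups` (list of character
#'   vectors, each a duplicate group), `keep` (retained sample ids, in matrix
#'   order), `dropped` (removed ids).
#' @export
detect_duplicates <- function(expr, clinical = NULL, cor_threshold = 0.99,
                              precedence = NULL, alias = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  ids <- sample_ids(expr)
  n <- length(ids)
  if (n < 2L) stop("duplicate detection requires at least 2 samples", call. = FALSE)

  cmat <- suppressWarnings(stats::cor(t(log2(expr$values))))
  if (anyNA(cmat)) {
    warning("correlation undefined for some sample pairs (zero-variance profile); treating those pairs as non-duplicate")
    cmat[is.na(cmat)] <- 0
  }
  adj <- cmat > cor_threshold
  diag(adj) <- FALSE

  if (!is.null(alias)) {
    al <- alias[ids]
    for (v in unique(al[!is.na(al)])) {
      hit <- which(!is.na(al) & al == v)
      if (length(hit) > 1L) adj[hit, hit] <- TRUE
    }
    diag(adj) <- FALSE
  }

  # union-find transitive closure
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(link))) {
    a <- find(link[k, 1L]); b <- find(link[k, 2L])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) > 1L])

  study <- NULL
  if (!is.null(clinical)) {
    study <- stats::setNames(clinical$study_id, clinical$sample_id)[ids]
    if (is.null(precedence)) precedence <- unique(clinical$study_id)
  }
  representative <- function(g) {
    if (!is.null(study)) {
      pr <- match(study[g], precedence)
      pr[is.na(pr)] <- length(precedence) + 1L
      g <- g[order(pr, g)]
    } else {
      g <- g[order(match(g, ids))]
    }
    g[1L]
  }
  dropped <- unlist(lapply(groups, function(g) setdiff(g, representative(g))))
  dropped <- as.character(dropped %||% character(0))
  structure(list(groups = groups,
                 keep = setdiff(ids, dropped),
                 dropped = dropped),
            class = "duplicate_groups")
}

#' @export
print.duplicate_groups <- function(x, ...) {
  cat(sprintf("<duplicate_groups> %d group(s), %d sample(s) dropped, %d retained\n",
              length(x$groups), length(x$dropped), length(x$keep)))
  invisible(x)
}

#' Apply the cohort eligibility filter
#'
#' Retains samples that are lymph-node negative, chemotherapy naive,
#' HER2-negative by array, and ER-positive, where ER positivity requires the
#' clinical and array determinations to agree when a clinical call exists and
#' falls back to the array call alone when the clinical call is missing.
#' Samples with missing LN status are excluded with a logged reason.
#'
#' @param clinical clinical table (see [read_clinical_table()]).
#' @param status status-call table from [call_status()], covering every
#'   clinical sample.
#' @return A list of class `eligibility_filter`: `eligible` (character vector
#'   of sample ids) and `report` (per-sample data frame with an `eligible`
#'   flag and exclusion `reason`).
#' @export
filter_eligibility <- function(clinical, status) {
  clinical <- validate_clinical(clinical)
  missing <- setdiff(clinical$sample_id, status$sample_id)
  if (length(missing)) {
    stop("status calls missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  st <- status[match(clinical$sample_id, status$sample_id), ]
  er_ok <- ifelse(is.na(clinical$er_clinical),
                  st$er_array == "+",
                  clinical$er_clinical == "+" & st$er_array == "+")
  ln_ok <- !is.na(clinical$ln_status) & clinical$ln_status == "negative"
  her2_ok <- st$her2_array == "-"
  chemo_ok <- !clinical$chemo

  reason <- character(nrow(clinical))
  reason[!er_ok] <- "not ER-positive (clinical+array agreement required)"
  reason[!her2_ok] <- "HER2-positive by array"
  reason[!chemo_ok] <- "received systemic chemotherapy"
  reason[!ln_ok & is.na(clinical$ln_status)] <- "missing LN status"
  reason[!ln_ok & !is.na(clinical$ln_status)] <- "lymph-node positive"
  eligible <- er_ok & ln_ok & her2_ok & chemo_ok
  reason[eligible] <- ""

  structure(list(eligible = clinical$sample_id[eligible],
                 report = data.frame(sample_id = clinical$sample_id,
                                     eligible = eligible,
                                     reason = reason,
                                     stringsAsFactors = FALSE)),
            class = "eligibility_filter")
}

#' @export
print.eligibility_filter <- function(x, ...) {
  cat(sprintf("<eligibility_filter> %d / %d samples eligible\n",
              length(x$eligible), nrow(x$report)))
  excl <- x$report$reason[x$report$reason != ""]
  if (length(excl)) print(sort(table(excl), decreasing = TRUE))
  invisible(x)
}

#' Binarize outcomes at the 10-year horizon
#'
#' Partitions samples into four disjoint classes: `relapse` (event in
#' (0, horizon]), `no_relapse` (no event and follow-up >= horizon),
#' `excluded_time_zero` (immediately postoperative event at time 0), and
#' `excluded_short_followup` (censored before the horizon; these are unusable
#' for classification but retained upstream for survival analysis).
#'
#' @param clinical clinical table.
#' @param horizon classification horizon in years (default 10).
#' @return Data frame with `sample_id` and `class` (factor with the four
#'   levels above).
#' @export
binarize_ten_year <- function(clinical, horizon = 10) {
  clinical <- validate_clinical(clinical)
  t <- clinical$followup_years
  ev <- clinical$relapse_event
  if (any(t < 0)) stop("negative follow-up times", call. = FALSE)
  cls <- ifelse(ev & t == 0, "excluded_time_zero",
         ifelse(ev & t <= horizon, "relapse",
         ifelse(!ev & t >= horizon, "no_relapse", "excluded_short_followup")))
  # events after the horizon count as relapse-free at the horizon only if
  # follow-up reaches it, which it does by definition (event time > horizon)
  cls[ev & t > horizon] <- "no_relapse"
  data.frame(sample_id = clinical$sample_id,
             class = factor(cls, levels = c("relapse", "no_relapse",
                                            "excluded_short_followup",
                                            "excluded_time_zero")),
             stringsAsFactors = FALSE)
}

#' Study- and outcome-balanced train/test split
#'
#' Randomly partitions samples into training and test sets while balancing
#' study of origin and outcome class: within each (study x class) stratum a
#' largest-remainder share of `train_fraction` goes to training, with the
#' per-stratum allocations adjusted so the global training size equals
#' `round(train_fraction * n)` exactly whenever possible. Single-member
#' strata are assigned to training. The split is reproducible under a fixed
#' seed and invariant to input row order.
#'
#' @param sample_id character vector of sample ids.
#' @param study_id,class optional stratification vectors parallel to
#'   `sample_id` (either may be NULL for a single stratum on that axis).
#' @param train_fraction fraction assigned to training, in (0, 1].
#' @param seed integer seed for the within-stratum randomization.
#' @return A list of class `cohort_split`: `train_ids`, `test_ids`, and
#'   `report` (per-stratum counts).
#' @examples
#' s <- stratified_split(sprintf("s%03d", 1:858), train_fraction = 2/3, seed = 1)
#' length(s$train_ids)  # 572
#' @export
stratified_split <- function(sample_id, study_id = NULL, class = NULL,
                             train_fraction = 2 / 3, seed = NULL) {
  if (anyDuplicated(sample_id)) stop("duplicated sample ids", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction > 1) {
    stop("`train_fraction` must be in (0, 1]", call. = FALSE)
  }
  n <- length(sample_id)
  study_id <- as.character(study_id %||% rep("all", n))
  class <- as.character(class %||% rep("all", n))
  stratum <- paste(study_id, class, sep = " / ")

  # canonical ordering makes the split invariant to input row order
  ord <- order(stratum, sample_id)
  sid <- sample_id[ord]
  str <- stratum[ord]
  strata <- split(sid, str)

  sizes <- vapply(strata, length, integer(1))
  target_total <- round(train_fraction * n)
  single <- sizes == 1L
  n_single <- sum(sizes[single])
  alloc <- integer(length(strata))
  alloc[single] <- 1L
  if (any(!single)) {
    want <- max(target_total - n_single, 0L)
    want <- min(want, sum(sizes[!single]))
    alloc[!single] <- largest_remainder(train_fraction * sizes[!single],
                                        want, cap = sizes[!single])
  }

  train_ids <- with_seed(seed, {
    unlist(lapply(seq_along(strata), function(i) {
      members <- sample(strata[[i]])
      members[seq_len(alloc[i])]
    }), use.names = FALSE)
  })
  train_ids <- as.character(train_ids %||% character(0))
  report <- data.frame(stratum = names(strata),
                       n = as.integer(sizes),
                       n_train = alloc,
                       n_test = as.integer(sizes) - alloc,
                       stringsAsFactors = FALSE)
  structure(list(train_ids = sample_id[sample_id %in% train_ids],
                 test_ids = sample_id[!sample_id %in% train_ids],
                 report = report),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  n <- length(x$train_ids) + length(x$test_ids)
  cat(sprintf("<cohort_split> %d train / %d test (%.1f%% train) over %d strata\n",
              length(x$train_ids), length(x$test_ids),
              100 * length(x$train_ids) / n, nrow(x$report)))
  invisible(x)
}

#' Write split membership as a two-column TSV
#'
#' @param split a `cohort_split`.
#' @param path output file (`sample_id`, `partition`).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
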