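#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: either paths to an expression
#' matrix / clinical table on disk, or a [sim_config()] to generate a
#' synthetic cohort; forest size; signature compaction settings; calibration
#' settings; and the master seed from which every stage's randomness is
#' derived.
#'
#' @param simulation a [sim_config()] used when no input paths are given.
#' @param expression_path,gene_map_path,clinical_path optional input files
#'   (see [read_expression_matrix()] / [read_clinical_table()]).
#' @param er_feature_id,her2_feature_ids marker feature ids; defaults to the
#'   synthetic cohort's markers when simulating (required for file input).
#' @param n_trees forest size (odd). The canonical forest uses 100,001
#'   trees; the default here (2,001) gives vote fractions stable to ~0.01 at
#'   interactive speed.
#' @param signature_k,signature_top_n compaction parameters (defaults 20 /
#'   100).
#' @param exclusions gene symbols excluded from signatures.
#' @param train_fraction training share of the cohort split.
#' @param filter a [filter_config()].
#' @param target_prevalence,n_iterations calibration settings.
#' @param seed master integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            expression_path = NULL,
                            gene_map_path = NULL,
                            clinical_path = NULL,
                            er_feature_id = NULL,
                            her2_feature_ids = NULL,
                            n_trees = 2001L,
                            signature_k = 20L,
                            signature_top_n = 100L,
                            exclusions = character(),
                            train_fraction = 2 / 3,
                            filter = filter_config(),
                            target_prevalence = 0.15,
                            n_iterations = 200L,
                            seed = 1L) {
  structure(list(simulation = simulation,
                 expression_path = expression_path,
                 gene_map_path = gene_map_path,
                 clinical_path = clinical_path,
                 er_feature_id = er_feature_id,
                 her2_feature_ids = her2_feature_ids,
                 n_trees = n_trees,
                 signature_k = signature_k,
                 signature_top_n = signature_top_n,
                 exclusions = exclusions,
                 train_fraction = train_fraction,
                 filter = filter,
                 target_prevalence = target_prevalence,
                 n_iterations = n_iterations,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full RFRS pipeline
#'
#' Executes assemble -> status -> eligibility -> binarize -> split -> filter
#' -> train -> calibrate -> compact -> validate, writing every intermediate
#' as TSV plus a JSON run manifest (package version, seed, configuration,
#' stage counts and md5 checksums of each output file) under `output_dir`.
#' Reruns with the same configuration reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir artifact directory (created if needed).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with every major artifact: the cohort, status
#'   calls, eligibility report, split, models (full / 17-gene-style /
#'   8-gene-style), signatures, calibration, test scores and AUCs, survival
#'   results, and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, code) {
    ts <- Sys.time()
    if (!quiet) message(sprintf("[%s] ...", name))
    out <- tryCatch(force(code), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), ts, units = "secs")), 2)
    out
  }

  # --- input ---------------------------------------------------------------
  if (is.null(config$expression_path)) {
    cohort <- stage("simulate", generate_cohort(config$simulation))
    expr <- cohort$expression
    clinical <- cohort$clinical
    er_ft <- config$er_feature_id %||% cohort$markers$er_feature
    her2_ft <- config$her2_feature_ids %||% cohort$markers$her2_features
  } else {
    cohort <- NULL
    expr <- stage("read", read_expression_matrix(config$expression_path,
                                                 config$gene_map_path))
    clinical <- read_clinical_table(config$clinical_path)
    er_ft <- config$er_feature_id
    her2_ft <- config$her2_feature_ids
    if (is.null(er_ft) || is.null(her2_ft)) {
      stop("file input requires `er_feature_id` and `her2_feature_ids`",
           call. = FALSE)
    }
  }
  write_expression_matrix(expr, file.path(output_dir, "expression.tsv"),
                          file.path(output_dir, "feature_map.tsv"))
  write_clinical_table(clinical, file.path(output_dir, "clinical.tsv"))

  # --- status + assembly ---------------------------------------------------
  status <- stage("status", call_status(expr, er_ft, her2_ft))
  write_status(status, file.path(output_dir, "status_calls.tsv"),
               file.path(output_dir, "status_cutoffs.tsv"))

  dups <- stage("duplicates", detect_duplicates(expr, clinical))
  expr <- subset_expr(expr, samples = dups$keep)
  clinical <- clinical[clinical$sample_id %in% dups$keep, ]

  elig <- stage("eligibility", filter_eligibility(clinical, status))
  utils::write.table(elig$report, file.path(output_dir, "eligibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clinical <- clinical[clinical$sample_id %in% elig$eligible, ]
  expr <- subset_expr(expr, samples = clinical$sample_id)

  labels <- stage("binarize", binarize_ten_year(clinical))
  utils::write.table(labels, file.path(output_dir, "outcome_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  split <- stage("split", stratified_split(
    clinical$sample_id, clinical$study_id, as.character(labels$class),
    train_fraction = config$train_fraction, seed = config$seed + 101L))
  write_split(split, file.path(output_dir, "split.tsv"))

  # --- features + training -------------------------------------------------
  train_expr <- subset_expr(expr, samples = split$train_ids)
  retained <- stage("filter", filter_features(train_expr, config$filter))
  writeLines(retained, file.path(output_dir, "retained_features.txt"))
  if (length(retained) < 2L) {
    stop("pipeline stage 'filter' failed: fewer than 2 features retained",
         call. = FALSE)
  }

  model <- stage("train", rfrs_train(
    subset_expr(train_expr, features = retained), labels,
    n_trees = config$n_trees, seed = config$seed + 202L))
  write_scores(model$oob_scores, file.path(output_dir, "oob_scores.tsv"))

  train_class <- labels[match(names(model$oob_scores), labels$sample_id), ]
  train_event <- train_class$class == "relapse"
  oob_auc <- roc_auc(model$oob_scores, train_event)

  calibration <- stage("calibrate", calibrate_rfrs(
    model$oob_scores, train_event,
    target_prevalence = config$target_prevalence,
    n_iterations = config$n_iterations, seed = config$seed + 303L))
  write_calibration(calibration, file.path(output_dir, "calibration.json"))

  # --- signatures + compact models ----------------------------------------
  ranking <- dedup_gene_importance(model$importance, model$feature_to_gene)
  top_n <- min(config$signature_top_n, nrow(ranking))
  k <- min(config$signature_k, top_n)
  sig <- stage("compact", compact_signature(
    ranking, train_expr, k = k, top_n = top_n,
    exclusions = config$exclusions, seed = config$seed + 404L))
  write_signature(sig, file.path(output_dir, "signature_primary.tsv"),
                  file.path(output_dir, "signature_long.tsv"))
  kept_n <- sum(!ranking$gene %in% config$exclusions)
  top_n8 <- min(90L, top_n - length(intersect(config$exclusions,
                                              ranking$gene[seq_len(top_n)])),
                kept_n)
  sig8 <- stage("compact8", eight_gene_signature(
    ranking, train_expr, exclusions = config$exclusions,
    top_n = top_n8, k = min(8L, top_n8), seed = config$seed + 505L))
  write_signature(sig8, file.path(output_dir, "signature_eight.tsv"))

  sig_features <- ranking$feature_id[match(primary_genes(sig), ranking$gene)]
  model_sig <- stage("train_compact", rfrs_train(
    subset_expr(train_expr, features = sig_features), labels,
    n_trees = config$n_trees, seed = config$seed + 606L))
  sig8_features <- ranking$feature_id[match(primary_genes(sig8), ranking$gene)]
  model_sig8 <- stage("train_eight", rfrs_train(
    subset_expr(train_expr, features = sig8_features), labels,
    n_trees = config$n_trees, seed = config$seed + 707L))

  # --- validation on the held-out test set --------------------------------
  test_expr <- subset_expr(expr, samples = split$test_ids)
  test_class <- labels[match(split$test_ids, labels$sample_id), ]
  test_event <- test_class$class == "relapse"
  classifiable <- test_class$class %in% c("relapse", "no_relapse")
  test_scores <- stage("score_test", lapply(
    list(full = model, compact = model_sig, eight = model_sig8),
    function(m) rfrs_score(m, test_expr)))
  test_auc <- vapply(test_scores, function(s) {
    tryCatch(roc_auc(s[classifiable], test_event[classifiable]),
             error = function(e) NA_real_)
  }, numeric(1))
  write_scores(test_scores$full, file.path(output_dir, "test_scores.tsv"))

  # survival: training samples keep their OOB score; short-follow-up training
  # samples and all test samples are scored de novo
  surv <- stage("survival", {
    extra_train <- setdiff(split$train_ids, names(model$oob_scores))
    train_scores <- c(model$oob_scores,
                      if (length(extra_train)) {
                        rfrs_score(model, subset_expr(expr, samples = extra_train))
                      })
    cl_train <- clinical[match(names(train_scores), clinical$sample_id), ]
    ok <- cl_train$followup_years > 0
    grp <- assign_risk_group(pmin(pmax(train_scores[ok], 0), 1),
                             calibration$thresholds)
    list(km = km_fit(cl_train$followup_years[ok], cl_train$relapse_event[ok], grp),
         trend = tryCatch(
           logrank_trend(cl_train$followup_years[ok],
                         cl_train$relapse_event[ok], grp),
           error = function(e) NULL))
  })
  write_km(surv$km, file.path(output_dir, "km_training.tsv"))

  # --- manifest ------------------------------------------------------------
  files <- sort(list.files(output_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(output_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "rfrs",
    version = as.character(utils::packageVersion("rfrs")),
    seed = config$seed,
    n_trees = config$n_trees,
    counts = list(samples_input = nrow(elig$report),
                  duplicates_dropped = length(dups$dropped),
                  eligible = length(elig$eligible),
                  train = length(split$train_ids),
                  test = length(split$test_ids),
                  features_retained = length(retained),
                  primaries = length(primary_genes(sig)),
                  primaries_eight = length(primary_genes(sig8))),
    auc = c(list(oob_full = oob_auc), as.list(test_auc)),
    thresholds = list(t_low = calibration$thresholds$t_low,
                      t_high = calibration$thresholds$t_high),
    timings_sec = timings,
    files_md5 = checksums)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!quiet) {
    message(sprintf("pipeline complete in %.1fs: OOB AUC %.3f; test AUC full %.3f / compact %.3f / eight %.3f",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    oob_auc, test_auc["full"], test_auc["compact"],
                    test_auc["eight"]))
  }
  invisible(list(cohort = cohort, status = status, duplicates = dups,
                 eligibility = elig, labels = labels, split = split,
                 retained_features = retained, model = model,
                 model_compact = model_sig, model_eight = model_sig8,
                 signature = sig, signature_eight = sig8,
                 calibration = calibration, oob_auc = oob_auc,
                 test_scores = test_scores, test_auc = test_auc,
                 survival = surv, manifest = manifest))
}
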