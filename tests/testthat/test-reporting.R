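demo_calibration <- function() {
  memo("demo_calibration", function() {
    withr::with_seed(77, {
      s <- stats::runif(400)
      ev <- stats::runif(400) < (0.05 + 0.4 * s)
      calibrate_rfrs(s, ev, thresholds = risk_thresholds(0.333, 0.606),
                     n_iterations = 20, seed = 5)
    })
  })
}

write_patient_file <- function(genes, rows, ids = NULL) {
  path <- tempfile(fileext = ".txt")
  df <- as.data.frame(rows)
  colnames(df) <- genes
  if (!is.null(ids)) df <- cbind(sample_id = ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("patient tables are validated against the signature gene list", {
  genes8 <- paste0("G", 1:8)
  path <- write_patient_file(genes8, matrix(100, 1, 8))
  ex <- read_patient_table(path, genes = genes8)
  expect_equal(dim(ex$values), c(1L, 8L))

  # superset rule: 17-gene file against an 8-gene list is accepted with
  # a warning and the extra columns dropped
  path17 <- write_patient_file(paste0("G", 1:17), matrix(100, 2, 17))
  expect_warning(ex17 <- read_patient_table(path17, genes = genes8), "extra")
  expect_equal(feature_ids(ex17), genes8)

  # a missing required gene is an error naming it
  path_missing <- write_patient_file(setdiff(genes8, "G3"), matrix(100, 1, 7))
  expect_error(read_patient_table(path_missing, genes = genes8), "G3")

  # non-numeric cells are rejected with coordinates
  bad <- matrix("100", 2, 8)
  bad[2, 4] <- "oops"
  path_bad <- write_patient_file(genes8, bad)
  expect_error(read_patient_table(path_bad, genes = genes8), "row 2.*G4")
})

test_that("reports combine thresholds and likelihood curve correctly", {
  cal <- demo_calibration()
  scores <- c(p_low = 0.1, p_mid = 0.45, p_high = 0.70, p_zero = 0.0)
  rep <- make_report(scores, cal)
  expect_equal(as.character(rep$risk_group),
               c("low", "intermediate", "high", "low"))
  expect_true(all(rep$likelihood >= 0 & rep$likelihood <= 1))
  # group assignment consistent with thresholds at every score
  expect_equal(as.character(rep$risk_group),
               as.character(assign_risk_group(rep$rfrs, cal$thresholds)))
  # order preserved, one row per patient
  expect_equal(rep$sample_id, names(scores))

  # score 0: left-endpoint likelihood, flagged if outside support
  left <- predict(cal$curve, 0)
  expect_equal(rep$likelihood[4], left$likelihood)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$sample_id, rep$sample_id)
  expect_equal(back$rfrs, rep$rfrs)
})

test_that("the full pipeline runs end-to-end and reruns reproduce outputs", {
  cfg <- pipeline_config(
    simulation = sim_config(n_samples = 220, n_features = 250,
                            n_signal_features = 25, n_signal_blocks = 5,
                            seed = 31),
    n_trees = 501L, n_iterations = 20L,
    signature_top_n = 40L, signature_k = 10L, seed = 7)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res1 <- suppressWarnings(run_pipeline(cfg, dir1, quiet = TRUE))
  res2 <- suppressWarnings(run_pipeline(cfg, dir2, quiet = TRUE))

  # determinism: identical content hashes for every artifact
  expect_identical(res1$manifest$files_md5, res2$manifest$files_md5)

  # split report shows per-study ~2/3 train balance
  rep <- res1$split$report
  agg <- stats::aggregate(cbind(n, n_train) ~ sub(" / .*", "", stratum),
                          data = rep, FUN = sum)
  frac <- agg$n_train / agg$n
  expect_true(all(abs(frac - 2 / 3) < 0.25))

  # manifest counts are internally consistent
  cnt <- res1$manifest$counts
  expect_equal(cnt$train + cnt$test, cnt$eligible)
  expect_true(file.exists(file.path(dir1, "manifest.json")))

  # artifacts round-trip
  cal <- read_calibration(file.path(dir1, "calibration.json"))
  expect_equal(cal$thresholds$t_low, res1$calibration$thresholds$t_low)
  sc <- utils::read.delim(file.path(dir1, "oob_scores.tsv"))
  expect_equal(nrow(sc), length(res1$model$oob_scores))
})

test_that("patients scored through the signature model get consistent reports", {
  co <- small_cohort()
  lb <- binarize_ten_year(co$clinical)
  keep <- lb$sample_id[lb$class %in% c("relapse", "no_relapse")]
  ex <- subset_expr(co$expression, samples = keep)
  m <- rfrs_train(ex, lb, n_trees = 501L, seed = 3)
  rk <- dedup_gene_importance(m$importance, m$feature_to_gene)
  sig <- compact_signature(rk, ex, k = 8, top_n = 24, seed = 4)
  feats <- rk$feature_id[match(primary_genes(sig), rk$gene)]
  msig <- rfrs_train(subset_expr(ex, features = feats), lb,
                     n_trees = 501L, seed = 5)

  # write two patients as a gene-keyed table, read back, score, report
  genes <- primary_genes(sig)
  vals <- ex$values[1:2, feats, drop = FALSE]
  path <- write_patient_file(genes, vals, ids = c("pt1", "pt2"))
  pat <- read_patient_table(path, signature = sig)
  s <- rfrs_score(msig, pat)
  expect_length(s, 2)
  direct <- rfrs_score(msig, subset_expr(ex, samples = sample_ids(ex)[1:2]))
  expect_equal(unname(s), unname(direct), tolerance = 1e-6)

  cal <- demo_calibration()
  repd <- make_report(s, cal, model_id = "demo", signature_id = "8-gene")
  expect_equal(nrow(repd), 2)
})
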