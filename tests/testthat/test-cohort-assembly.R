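test_that("duplicate detection groups by alias, exact copies, and r > 0.99", {
  withr::local_seed(5)
  base <- matrix(2^stats::rnorm(5 * 1000, 8, 2), 5, 1000,
                 dimnames = list(paste0("s", 1:5), sprintf("f%04d", 1:1000)))
  # s6 = exact copy of s1; s7 independent
  values <- rbind(base, s6 = base[1, ], s7 = 2^stats::rnorm(1000, 8, 2))
  ex <- expression_matrix(values)

  d <- detect_duplicates(ex)
  expect_equal(d$groups, list(c("s1", "s6")))
  expect_equal(d$dropped, "s6")

  # brute-force Pearson on two independent profiles stays below 0.99
  r <- sum(scale(log2(values["s5", ])) * scale(log2(values["s7", ]))) / 999
  expect_lt(abs(r), 0.99)

  # alias identity groups regardless of correlation
  d2 <- detect_duplicates(ex, alias = c(s2 = "pt1", s7 = "pt1"))
  expect_true(list(c("s2", "s7")) %in% d2$groups ||
              any(vapply(d2$groups, setequal, logical(1), c("s2", "s7"))))
})

test_that("duplicate grouping is transitive and idempotent after removal", {
  withr::local_seed(8)
  x <- 2^stats::rnorm(500, 8, 2)
  values <- rbind(a = x,
                  b = x * 2^stats::rnorm(500, 0, 0.05),
                  c = x * 2^stats::rnorm(500, 0, 0.05),
                  d = 2^stats::rnorm(500, 8, 2))
  colnames(values) <- sprintf("f%03d", 1:500)
  ex <- expression_matrix(values)
  d <- detect_duplicates(ex)
  expect_length(d$groups, 1L)
  expect_setequal(d$groups[[1]], c("a", "b", "c"))
  # re-running on the deduplicated matrix finds nothing
  d2 <- detect_duplicates(subset_expr(ex, samples = d$keep))
  expect_length(d2$groups, 0L)
})

test_that("representative retention follows study precedence", {
  withr::local_seed(2)
  x <- 2^stats::rnorm(300, 8, 2)
  values <- rbind(s1 = x, s2 = x * 2^stats::rnorm(300, 0, 0.03))
  colnames(values) <- sprintf("f%03d", 1:300)
  ex <- expression_matrix(values)
  clin <- data.frame(sample_id = c("s1", "s2"), study_id = c("B", "A"))
  d <- detect_duplicates(ex, clin, precedence = c("A", "B"))
  expect_equal(d$keep, "s2")
  d2 <- detect_duplicates(ex, clin, precedence = c("B", "A"))
  expect_equal(d2$keep, "s1")
})

make_clin <- function(n, ...) {
  args <- list(...)
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                   study_id = "st1", er_clinical = "+", her2_clinical = "-",
                   ln_status = "negative", chemo = FALSE,
                   hormone_therapy = FALSE, relapse_event = FALSE,
                   followup_years = 12, stringsAsFactors = FALSE)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  df
}

test_that("eligibility enforces the clinical-and-array ER agreement rule", {
  clin <- make_clin(4, er_clinical = c("+", "+", NA, NA))
  status <- data.frame(sample_id = clin$sample_id,
                       er_array = c("+", "-", "+", "-"),
                       her2_array = "-")
  el <- filter_eligibility(clin, status)
  # clinical+ & array- excluded; clinical missing relies on array alone
  expect_equal(el$eligible, c("s01", "s03"))
  expect_match(el$report$reason[2], "ER-positive")
})

test_that("eligibility excludes HER2+, chemo, LN-positive and missing LN", {
  clin <- make_clin(10,
                    ln_status = c(rep("negative", 8), "positive", NA),
                    chemo = c(rep(FALSE, 7), TRUE, FALSE, FALSE))
  status <- data.frame(sample_id = clin$sample_id, er_array = "+",
                       her2_array = c(rep("-", 5), "+", "+", rep("-", 3)))
  el <- filter_eligibility(clin, status)
  expect_equal(el$eligible, sprintf("s%02d", 1:5))
  expect_equal(sum(el$report$reason == "HER2-positive by array"), 2)
  expect_equal(sum(el$report$reason == "missing LN status"), 1)

  # toy count check: 10 eligible-but-for-HER2 with 2 array-HER2+ keeps 8
  clin2 <- make_clin(10)
  status2 <- data.frame(sample_id = clin2$sample_id, er_array = "+",
                        her2_array = c("+", "+", rep("-", 8)))
  expect_length(filter_eligibility(clin2, status2)$eligible, 8)

  # status must cover every sample
  expect_error(filter_eligibility(clin, status[-1, ]), "missing for sample")
})

test_that("ten-year binarization partitions into the four classes", {
  clin <- make_clin(6,
                    relapse_event = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                    followup_years = c(4.2, 0, 8, 10, 12, 15))
  lb <- binarize_ten_year(clin)
  expect_equal(as.character(lb$class),
               c("relapse", "excluded_time_zero", "excluded_short_followup",
                 "no_relapse", "no_relapse", "no_relapse"))
  # partition: every sample in exactly one class
  expect_false(anyNA(lb$class))
  expect_equal(nrow(lb), 6)

  clin$followup_years[1] <- -1
  expect_error(binarize_ten_year(clin), "nonnegative")

  # boundary: event at exactly 10 years is a relapse
  lb2 <- binarize_ten_year(make_clin(1, relapse_event = TRUE,
                                     followup_years = 10))
  expect_equal(as.character(lb2$class), "relapse")
})

test_that("stratified split hits the 858-sample 2/3 allocation exactly", {
  ids <- sprintf("x%03d", 1:858)
  sp <- stratified_split(ids, train_fraction = 2 / 3, seed = 1)
  expect_length(sp$train_ids, 572)
  expect_length(sp$test_ids, 286)

  # fraction 1 keeps everything in training
  sp1 <- stratified_split(ids[1:20], train_fraction = 1, seed = 1)
  expect_length(sp1$train_ids, 20)
  expect_length(sp1$test_ids, 0)
})

test_that("split balances strata, is reproducible, and ignores row order", {
  withr::local_seed(13)
  n <- 540
  study <- sample(sprintf("study%d", 1:9), n, replace = TRUE)
  cls <- sample(c("relapse", "no_relapse"), n, replace = TRUE)
  ids <- sprintf("s%04d", seq_len(n))
  sp <- stratified_split(ids, study, cls, train_fraction = 2 / 3, seed = 77)
  expect_length(sp$train_ids, round(2 / 3 * n))
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)

  # per-study balance within 1/n_study of the global fraction
  for (st in unique(study)) {
    in_st <- ids[study == st]
    frac <- mean(in_st %in% sp$train_ids)
    expect_lt(abs(frac - 2 / 3), 1 / sum(study == st) + 0.05)
  }

  sp_again <- stratified_split(ids, study, cls, train_fraction = 2 / 3, seed = 77)
  expect_identical(sp$train_ids, sp_again$train_ids)

  perm <- sample(n)
  sp_perm <- stratified_split(ids[perm], study[perm], cls[perm],
                              train_fraction = 2 / 3, seed = 77)
  expect_setequal(sp_perm$train_ids, sp$train_ids)

  # single-member strata always go to training
  sp_single <- stratified_split(c("a", "b", "c"), c("s1", "s2", "s3"),
                                train_fraction = 2 / 3, seed = 1)
  expect_setequal(sp_single$train_ids, c("a", "b", "c"))
})
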