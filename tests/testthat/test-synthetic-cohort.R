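test_that("cohort generation is deterministic and validates its config", {
  cfg <- sim_config(n_samples = 80, n_features = 120, n_signal_features = 12,
                    n_signal_blocks = 4, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_error(sim_config(n_samples = 0), "positive integer")
  expect_error(sim_config(duplicate_fraction = 1), "< 1")
  expect_error(sim_config(duplicate_fraction = -0.1), "fractions")
  expect_error(sim_config(n_signal_features = 500, n_features = 100),
               "marker features")
})

test_that("injected duplicates are counted exactly and correlate above 0.99", {
  co <- generate_cohort(sim_config(n_samples = 200, n_features = 150,
                                   duplicate_fraction = 0.05, seed = 9))
  tp <- co$truth$duplicate_pairs
  expect_equal(nrow(tp), 10)  # round(0.05 * 200)
  expect_equal(n_samples(co$expression), 210)
  lg <- log2(co$expression$values)
  r <- mapply(function(a, b) stats::cor(lg[a, ], lg[b, ]),
              tp$original, tp$duplicate)
  expect_true(all(r > 0.99))
})

test_that("expression is strictly positive and null latent effect gives null association", {
  co <- generate_cohort(sim_config(n_samples = 500, n_features = 100,
                                   latent_effect = 0, duplicate_fraction = 0,
                                   seed = 17))
  expect_true(all(co$expression$values > 0))
  r <- stats::cor(co$truth$latent, as.numeric(co$clinical$relapse_event))
  expect_lt(abs(r), 0.1)
})

test_that("ER mixture recovers the configured positive fraction", {
  co <- generate_cohort(sim_config(n_samples = 1000, n_features = 50,
                                   n_signal_features = 5, n_signal_blocks = 2,
                                   duplicate_fraction = 0, seed = 23))
  er <- log2(er_score(co$expression, co$markers$er_feature))
  fit <- mclust::Mclust(er, G = 2, modelNames = "V", verbose = FALSE)
  hi <- which.max(fit$parameters$mean)
  expect_equal(unname(fit$parameters$pro[hi]), 0.8, tolerance = 0.05 / 0.8)
})

test_that("KM 10-year event fraction matches the configured baseline hazard", {
  # with no latent effect and no treatment effect the model is exponential
  # with P(event by 10y) = baseline_event_prob exactly
  co <- generate_cohort(sim_config(n_samples = 2000, n_features = 30,
                                   n_signal_features = 3, n_signal_blocks = 1,
                                   latent_effect = 0, treatment_effect = 1,
                                   duplicate_fraction = 0, seed = 31))
  km <- km_fit(co$clinical$followup_years, co$clinical$relapse_event)
  cv <- km$curves[[1]]
  s10 <- min(cv$survival[cv$time <= 10])
  p10 <- 1 - s10
  # Greenwood-free bound: 3 binomial SEs at n = 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(p10 - 0.25), 3 * se + 0.02)
})

test_that("planted signal features rank highly by univariate association", {
  co <- generate_cohort(sim_config(n_samples = 500, n_features = 300,
                                   n_signal_features = 20, n_signal_blocks = 5,
                                   latent_effect = 0.8, duplicate_fraction = 0,
                                   seed = 41))
  lb <- binarize_ten_year(co$clinical)
  keep <- lb$sample_id[lb$class %in% c("relapse", "no_relapse")]
  ev <- lb$class[match(keep, lb$sample_id)] == "relapse"
  lg <- log2(co$expression$values[keep, ])
  stat <- apply(lg, 2, function(x) abs(stats::t.test(x[ev], x[!ev])$statistic))
  top <- names(sort(stat, decreasing = TRUE))[seq_len(2 * 20)]
  expect_gte(mean(co$truth$signal_features %in% top), 0.5)
})

test_that("cohort round-trips through the on-disk formats", {
  co <- generate_cohort(sim_config(n_samples = 30, n_features = 40,
                                   n_signal_features = 6, n_signal_blocks = 2,
                                   seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ex <- read_expression_matrix(file.path(dir, "expression.tsv"),
                               file.path(dir, "feature_map.tsv"))
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(sample_ids(ex), sample_ids(co$expression))
  expect_equal(ex$feature_to_gene, co$expression$feature_to_gene)
  # values survive at the 6-significant-digit output precision
  expect_equal(ex$values, co$expression$values, tolerance = 1e-5)
  expect_equal(cl$sample_id, co$clinical$sample_id)
  expect_equal(cl$relapse_event, co$clinical$relapse_event)
})
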