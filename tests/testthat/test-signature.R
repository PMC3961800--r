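test_that("gene-level deduplication keeps the best feature per gene", {
  imp <- c(p1 = 0.6, p2 = 0.3, p3 = 0.9, p4 = 0.1)
  map <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "C")
  rk <- dedup_gene_importance(imp, map)
  expect_equal(rk$gene, c("B", "A", "C"))
  expect_equal(rk$feature_id, c("p3", "p1", "p4"))
  expect_equal(rk$importance, c(0.9, 0.6, 0.1))

  # no multi-feature genes: output = input order by importance
  imp2 <- c(q1 = 0.2, q2 = 0.8)
  rk2 <- dedup_gene_importance(imp2, c(q1 = "X", q2 = "Y"))
  expect_equal(rk2$gene, c("Y", "X"))

  # 3 genes x 2 features each collapses to 3 rows
  imp3 <- stats::setNames(stats::runif(6), paste0("r", 1:6))
  map3 <- stats::setNames(rep(c("G1", "G2", "G3"), each = 2), paste0("r", 1:6))
  expect_equal(nrow(dedup_gene_importance(imp3, map3)), 3)
})

test_that("compaction recovers planted correlation blocks", {
  fx <- planted_block_expr(sizes = rep(5, 5), n = 120, seed = 31)
  sig <- compact_signature(fx$ranking, fx$expr, k = 5, top_n = 25, seed = 2)
  expect_length(sig$clusters, 5)
  ari <- rand_index_adjusted(sig$cluster_assignment[fx$ranking$gene],
                             fx$truth_block)
  expect_gt(ari, 0.9)
  # within each cluster the primary has maximal importance
  for (cl in sig$clusters) {
    if (nrow(cl$alternates)) {
      expect_true(all(cl$importance >= cl$alternates$importance))
    }
  }
  # union of primaries and alternates is the whole pool, no repeats
  all_genes <- c(primary_genes(sig), alternate_genes(sig))
  expect_setequal(all_genes, fx$ranking$gene[1:25])
  expect_false(anyDuplicated(all_genes) > 0)
})

test_that("k = top_n yields singleton clusters and determinism holds", {
  fx <- planted_block_expr(sizes = rep(2, 4), n = 60, seed = 5)
  sig <- compact_signature(fx$ranking, fx$expr, k = 8, top_n = 8, seed = 3)
  expect_length(sig$clusters, 8)
  expect_length(alternate_genes(sig), 0)

  sig2 <- compact_signature(fx$ranking, fx$expr, k = 8, top_n = 8, seed = 3)
  expect_identical(signature_long(sig), signature_long(sig2))

  expect_error(compact_signature(fx$ranking, fx$expr, k = 9, top_n = 8), "k")
  expect_error(compact_signature(fx$ranking, fx$expr, k = 2, top_n = 99),
               "top_n")
})

test_that("exclusions emptying clusters reproduce the 17-primary/73-alternate shape", {
  # 20 planted blocks over 100 genes; the last three blocks (3+3+4 genes)
  # are excluded wholesale, so 3 clusters die: 17 primaries + 73 alternates
  sizes <- c(rep(5, 12), rep(6, 5), 3, 3, 4)
  fx <- planted_block_expr(sizes, n = 150, seed = 7)
  excl <- fx$ranking$gene[fx$truth_block >= 18]
  expect_length(excl, 10)
  sig <- compact_signature(fx$ranking, fx$expr, k = 20, top_n = 100,
                           exclusions = excl, seed = 11)
  expect_length(primary_genes(sig), 17)
  expect_length(alternate_genes(sig), 73)
  expect_setequal(sig$exclusions_applied, excl)
  expect_false(any(excl %in% c(primary_genes(sig), alternate_genes(sig))))
})

test_that("eight-gene variant compacts the pre-excluded top-90 pool", {
  sizes <- c(rep(5, 12), rep(6, 5), 3, 3, 4)
  fx <- planted_block_expr(sizes, n = 150, seed = 7)
  excl <- fx$ranking$gene[fx$truth_block >= 18]
  sig8 <- eight_gene_signature(fx$ranking, fx$expr, exclusions = excl,
                               seed = 13)
  expect_length(primary_genes(sig8), 8)
  expect_equal(sig8$top_n, 90)
  expect_false(any(excl %in% c(primary_genes(sig8), alternate_genes(sig8))))
  # every primary has >= 2 alternates when the pool is dominated by
  # multi-gene correlated blocks
  n_alt <- vapply(sig8$clusters, function(cl) nrow(cl$alternates), integer(1))
  expect_true(all(n_alt >= 2))

  # nested-inclusion diagnostic is reportable (subset test well-defined)
  sig17 <- compact_signature(fx$ranking, fx$expr, k = 20, top_n = 100,
                             exclusions = excl, seed = 11)
  nested <- mean(primary_genes(sig8) %in%
                 c(primary_genes(sig17), alternate_genes(sig17)))
  expect_true(is.finite(nested))
})

test_that("signature tables round-trip to TSV", {
  fx <- planted_block_expr(sizes = rep(4, 5), n = 80, seed = 19)
  sig <- compact_signature(fx$ranking, fx$expr, k = 5, top_n = 20, seed = 1)
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, wide, long)
  wtab <- utils::read.delim(wide)
  ltab <- utils::read.delim(long)
  expect_equal(wtab$primary, primary_genes(sig))
  expect_equal(nrow(ltab), 20)
  expect_equal(sum(ltab$role == "primary"), 5)
})
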