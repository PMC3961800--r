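# Shared fixtures, built in code. Expensive objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# tiny expr_matrix from a bare matrix (auto names if absent)
tiny_expr <- function(values, genes = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  }
  map <- if (is.null(genes)) NULL else stats::setNames(genes, colnames(values))
  expression_matrix(values, map)
}

# small default cohort reused by several unit tests
small_cohort <- function() {
  memo("small_cohort", function() {
    generate_cohort(sim_config(n_samples = 250, n_features = 300,
                               n_signal_features = 30, n_signal_blocks = 6,
                               seed = 421))
  })
}

# planted correlation blocks: `sizes[b]` genes per block, tight within-block
# correlation, well-separated block profiles; importance decreases smoothly
# with gene index so the whole set is the "top pool"
planted_block_expr <- function(sizes, n = 150, noise_sd = 0.3, seed = 7) {
  withr::with_seed(seed, {
    n_genes <- sum(sizes)
    centers <- matrix(stats::rnorm(length(sizes) * n, sd = 3),
                      nrow = length(sizes))
    logx <- do.call(rbind, lapply(seq_along(sizes), function(b) {
      matrix(rep(centers[b, ], sizes[b]), nrow = sizes[b], byrow = TRUE) +
        matrix(stats::rnorm(sizes[b] * n, sd = noise_sd), nrow = sizes[b])
    }))
    genes <- sprintf("G%03d", seq_len(n_genes))
    values <- t(2^(logx / 2 + 8))  # positive linear scale
    rownames(values) <- sprintf("s%03d", seq_len(n))
    colnames(values) <- genes
    list(expr = expression_matrix(values),
         truth_block = rep(seq_along(sizes), sizes),
         ranking = data.frame(gene = genes, feature_id = genes,
                              importance = seq(2, 1, length.out = n_genes),
                              stringsAsFactors = FALSE))
  })
}

# separable two-class expression set for forest tests
separable_expr <- function(n = 200, seed = 11) {
  withr::with_seed(seed, {
    x <- matrix(c(stats::runif(n / 2, 50, 100), stats::runif(n / 2, 500, 1000)),
                ncol = 1, dimnames = list(sprintf("s%03d", seq_len(n)), "f1"))
    lab <- stats::setNames(rep(c("no_relapse", "relapse"), each = n / 2),
                           rownames(x))
    list(expr = expression_matrix(x), labels = lab,
         event = lab == "relapse")
  })
}

# adjusted Rand index between two partitions (independent of any package code)
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Independent brute-force two-group log-rank statistic, written directly
# from the O-E / hypergeometric-variance definition; used as the oracle.
logrank_two_group_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  u <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g == 2L)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g == 2L)
    if (n < 2 || d == 0) next
    u <- u + (d1 - d * n1 / n)
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}
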