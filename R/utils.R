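# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers never perturb it.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Largest-remainder (Hamilton) apportionment of `total` integer units over
# real-valued targets, optionally capped per cell. Ties broken by index order.
largest_remainder <- function(target, total, cap = NULL) {
  stopifnot(is.numeric(target), total >= 0)
  base <- floor(target)
  if (!is.null(cap)) base <- pmin(base, cap)
  base <- pmax(base, 0)
  rem <- target - base
  d <- total - sum(base)
  if (d > 0) {
    for (i in order(-rem, seq_along(target))) {
      if (d == 0) break
      lim <- if (is.null(cap)) Inf else cap[i]
      if (base[i] < lim) {
        base[i] <- base[i] + 1
        d <- d - 1
      }
    }
  } else if (d < 0) {
    for (i in order(rem, seq_along(target))) {
      if (d == 0) break
      if (base[i] > 0) {
        base[i] <- base[i] - 1
        d <- d + 1
      }
    }
  }
  as.integer(base)
}

# k-means with k-means++ (D^2 sampling) initialization and restarts.
# stats::kmeans with random restarts reliably merges tight, well-separated
# clusters when k is large relative to n; D^2 seeding avoids that.
kmeans_pp <- function(x, k, nstart = 100L, iter.max = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  if (k == n) {
    # trivial solution: every point its own cluster (stats::kmeans rejects
    # k = n outright)
    return(list(cluster = stats::setNames(seq_len(n), rownames(x)),
                centers = x, totss = sum(scale(x, scale = FALSE)^2),
                withinss = rep(0, k), tot.withinss = 0,
                betweenss = sum(scale(x, scale = FALSE)^2),
                size = rep(1L, k)))
  }
  seed_centers <- function() {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k)[-1L]) {
      probs <- pmax(d2, 1e-300)
      centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
    centers
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- tryCatch(
      stats::kmeans(x, centers = seed_centers(), iter.max = iter.max),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  best
}

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
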