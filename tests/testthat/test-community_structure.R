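test_that("Jensen-Shannon divergence matches its definition and bounds", {
  expect_equal(jsDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), log(2))

  # independent term-by-term KL summation oracle
  p <- c(0.5, 0.5); q <- c(1, 0); m <- (p + q) / 2
  oracle <- 0.5 * (0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25)) +
    0.5 * (1 * log(1 / 0.75))
  expect_equal(jsDivergence(p, q), oracle, tolerance = 1e-15)

  expect_error(jsDivergence(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(jsDivergence(c(0.9, 0.2), c(0.5, 0.5)), "summing to 1")
})

test_that("JSD is symmetric, bounded by log 2 and zero only at equality", {
  set.seed(100)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    p <- as.vector(mgInferEval:::.rdirichlet(1, rep(0.5, k)))
    q <- as.vector(mgInferEval:::.rdirichlet(1, rep(0.5, k)))
    d <- jsDivergence(p, q)
    expect_equal(d, jsDivergence(q, p), tolerance = 1e-14)
    expect_gte(d, 0)
    expect_lte(d, log(2) + 1e-12)
    expect_gt(d, 0)  # distinct draws almost surely differ
  }
})

test_that("distance matrix agrees with scalar calls and is well-formed", {
  set.seed(7)
  m <- mgInferEval:::.rdirichlet(6, rep(1, 5))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:5))
  m[2, ] <- m[1, ]   # identical pair
  tab <- abundanceTable(m, scale = "relative")
  d <- jsdDistanceMatrix(tab)
  expect_equal(d[1, 2], 0)
  expect_identical(diag(d), stats::setNames(rep(0, 6), rownames(m)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], jsDivergence(m[i, ], m[j, ]), tolerance = 1e-12)
  expect_true(all(d <= log(2) + 1e-12))
  expect_error(jsdDistanceMatrix(abundanceTable(m * 2)), "relative")
})

test_that("Ward clustering matches a Lance-Williams recurrence oracle", {
  # two points: single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- wardClustering(d2)
  expect_equal(h2$height, 0.3)

  # two tight, well-separated pairs merge within pairs first
  pts <- c(0, 0.01, 10, 10.01)
  d4 <- as.matrix(stats::dist(pts))
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  h4 <- wardClustering(d4)
  expect_equal(sort(h4$height)[1:2], c(0.01, 0.01))
  expect_equal(unname(cutClusters(h4, 2)), c(1, 1, 2, 2))

  # 6-sample instance vs a direct Ward.D2 Lance-Williams evaluation
  set.seed(42)
  x <- matrix(rnorm(12), nrow = 6)
  d6 <- as.matrix(stats::dist(x))
  dimnames(d6) <- list(paste0("s", 1:6), paste0("s", 1:6))
  lwWard <- function(d) {
    # agglomerate greedily, updating squared distances by the Ward.D2 rule
    d2m <- d^2
    sizes <- rep(1, nrow(d))
    active <- seq_len(nrow(d))
    heights <- numeric(0)
    while (length(active) > 1) {
      sub <- d2m[active, active]
      diag(sub) <- Inf
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      i <- active[ij[1]]; j <- active[ij[2]]
      heights <- c(heights, sqrt(d2m[i, j]))
      ni <- sizes[i]; nj <- sizes[j]
      for (k in setdiff(active, c(i, j))) {
        nk <- sizes[k]
        d2m[i, k] <- d2m[k, i] <-
          ((ni + nk) * d2m[i, k] + (nj + nk) * d2m[j, k] -
             nk * d2m[i, j]) / (ni + nj + nk)
      }
      sizes[i] <- ni + nj
      active <- setdiff(active, j)
    }
    heights
  }
  h6 <- wardClustering(d6)
  expect_equal(h6$height, lwWard(d6), tolerance = 1e-10)
})

test_that("cutClusters covers limits, rejects bad k, and nests", {
  set.seed(3)
  d <- as.matrix(stats::dist(matrix(rnorm(16), 8)))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  hc <- wardClustering(d)
  expect_identical(length(unique(cutClusters(hc, 8))), 8L)
  expect_identical(length(unique(cutClusters(hc, 1))), 1L)
  expect_error(cutClusters(hc, 0), "between 1")
  expect_error(cutClusters(hc, 9), "between 1")
  # cutting at k-1 only merges clusters from the k-cut, never splits them
  for (k in 3:8) {
    fine <- cutClusters(hc, k)
    coarse <- cutClusters(hc, k - 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("validation statistics match exhaustive small-instance oracles", {
  set.seed(21)
  x <- matrix(rnorm(16, sd = 2), nrow = 8)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  hc <- wardClustering(d)
  val <- validateClustering(d, hc, kRange = 2:4, neighbors = 3)

  connOracle <- function(d, lab, L) {
    tot <- 0
    for (i in seq_len(nrow(d))) {
      others <- setdiff(seq_len(nrow(d)), i)
      nn <- others[order(d[i, others])][1:L]
      for (j in seq_len(L))
        if (lab[nn[j]] != lab[i]) tot <- tot + 1 / j
    }
    tot
  }
  silOracle <- function(d, lab) {
    s <- numeric(nrow(d))
    for (i in seq_len(nrow(d))) {
      own <- setdiff(which(lab == lab[i]), i)
      if (!length(own)) { s[i] <- 0; next }
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(g) mean(d[i, lab == g]), numeric(1)))
      s[i] <- (b - a) / max(a, b)
    }
    mean(s)
  }
  dunnOracle <- function(d, lab) {
    inter <- Inf; intra <- 0
    for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
      if (lab[i] == lab[j]) intra <- max(intra, d[i, j])
      else inter <- min(inter, d[i, j])
    }
    inter / intra
  }
  for (r in seq_len(nrow(val))) {
    lab <- cutClusters(hc, val$k[r])
    expect_equal(val$connectivity[r], connOracle(d, lab, 3), tolerance = 1e-10)
    expect_equal(val$silhouette[r], silOracle(d, lab), tolerance = 1e-10)
    expect_equal(val$dunn[r], dunnOracle(d, lab), tolerance = 1e-10)
  }
  expect_error(validateClustering(d, hc, 2:3, neighbors = 8), "smaller")
})

test_that("two far-apart tight blobs validate cleanly at k = 2", {
  pts <- c(0, 0.05, 0.1, 5, 5.05, 5.1)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  hc <- wardClustering(d)
  val <- validateClustering(d, hc, kRange = 2:3, neighbors = 2)
  k2 <- val[val$k == 2, ]
  expect_equal(k2$connectivity, 0)
  expect_gt(k2$silhouette, 0.9)
  expect_gt(k2$dunn, 1)
})

test_that("alpha diversity matches closed forms and direct summation", {
  m <- rbind(u = rep(0.25, 4), s = c(1, 0, 0, 0), w = c(0.5, 0.3, 0.2, 0))
  colnames(m) <- paste0("t", 1:4)
  m <- m / rowSums(m)
  tab <- abundanceTable(m, scale = "relative")
  div <- alphaDiversity(tab)
  get <- function(s, met) div$value[div$sample_id == s & div$metric == met]
  expect_equal(get("u", "shannon"), log(4))
  expect_equal(get("u", "invsimpson"), 4)
  expect_equal(get("s", "shannon"), 0)
  expect_equal(get("s", "simpson"), 0)
  expect_equal(get("s", "observed"), 1)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(get("w", "shannon"), -sum(p * log(p)))
  expect_equal(get("w", "simpson"), 1 - sum(p^2))
  expect_equal(get("w", "invsimpson"), 1 / sum(p^2))
  expect_equal(get("w", "observed"), 3)
  expect_error(alphaDiversity(tab, metrics = "chao1"), "unknown")
})

test_that("cross-tabulation counts label pairs and conserves totals", {
  ct <- crossTabulateClusterings(c("x", "x", "y"), c("u", "v", "v"))
  expect_equal(ct["x", "u"], 1)
  expect_equal(ct["x", "v"], 1)
  expect_equal(ct["y", "v"], 1)
  expect_equal(sum(ct), 3)
  idct <- crossTabulateClusterings(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(sum(diag(idct)), 3)
  a <- stats::setNames(c("x", "y"), c("s1", "s2"))
  b <- stats::setNames(c("y", "x"), c("s2", "s1"))
  ct2 <- crossTabulateClusterings(a, b)  # aligned by name
  expect_equal(ct2["x", "x"], 1)
  expect_error(crossTabulateClusterings(a, stats::setNames("x", "s9")),
               "different samples")
})
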