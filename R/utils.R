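# Internal numerical helpers shared across modules.

# Tolerance for "rows sum to one" checks on relative-abundance tables.
.REL_TOL <- 1e-9

# Deterministic child seed derived from a master seed and a key path, so each
# stage / table / replicate / feature gets its own reproducible stream.
# Polynomial rolling hash over the UTF-8 bytes of "seed/part1/part2/...",
# reduced modulo a prime below 2^31 (R seeds are 32-bit integers).
.childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- Reduce(function(a, b) (a * 31 + b) %% 2147483629, utf8ToInt(key), 0)
  as.integer(h)
}

# Dirichlet sampler via the normalized-gamma construction.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sums <- rowSums(g)
  if (any(sums == 0)) {
    # numerically possible only for tiny shapes; resample offending rows
    bad <- which(sums == 0)
    g[bad, ] <- matrix(stats::rgamma(length(bad) * k, shape = rep(alpha, each = length(bad))),
                       nrow = length(bad))
    sums <- rowSums(g)
  }
  g / sums
}

# Row-normalize a non-negative matrix; errors (naming rows) on all-zero rows.
.rowNormalize <- function(m, what = "sample") {
  sums <- rowSums(m)
  if (any(sums <= 0)) {
    bad <- rownames(m)[sums <= 0]
    stop("cannot normalize: ", what, "(s) with zero total: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  m / sums
}

# Column-wise Spearman correlation between two aligned sample x feature
# matrices: mid-rank transform then column-wise Pearson. Constant columns in
# either matrix give NA (undefined), never a silent zero.
.colSpearman <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  rx <- apply(x, 2L, rank)
  ry <- apply(y, 2L, rank)
  rx <- sweep(rx, 2L, colMeans(rx))
  ry <- sweep(ry, 2L, colMeans(ry))
  den <- sqrt(colSums(rx^2) * colSums(ry^2))
  num <- colSums(rx * ry)
  ifelse(den == 0, NA_real_, num / den)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop("'", name, "' must be a single finite number in [",
         lower, ", ", upper, "]", call. = FALSE)
  invisible(x)
}
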