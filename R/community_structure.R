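#' @include AllClasses.R
NULL

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, natural
#' logarithms, and `0 * log(0/x)` taken as 0. Symmetric, zero iff `p == q`,
#' and bounded above by `log(2)`. This is the sample-to-sample distance used
#' for community state type clustering (used directly, not square-rooted).
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to
#'   one within 1e-9.
#' @return A single number in `[0, log(2)]`.
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))  # log(2)
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > .REL_TOL || abs(sum(q) - 1) > .REL_TOL)
    stop("'p' and 'q' must be probability vectors summing to 1", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' @param table a relative-scale [AbundanceTable-class].
#' @return Symmetric numeric matrix (zero diagonal) of pairwise divergences
#'   between sample rows, with sample identifiers as dimnames.
#' @export
jsdDistanceMatrix <- function(table) {
  stopifnot(methods::is(table, "AbundanceTable"))
  if (abundanceScale(table) != "relative")
    stop("JSD requires a relative-scale table; call normalizeRelative() first",
         call. = FALSE)
  v <- abundances(table)
  n <- nrow(v)
  # JSD(p, q) = H(m) - (H(p) + H(q))/2; vectorized over pairs via entropies
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  h <- apply(v, 1L, ent)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- ent((v[i, ] + v[j, ]) / 2) - (h[i] + h[j]) / 2
    }
  }
  # entropy differencing can go epsilon-negative at p == q
  d[d < 0] <- 0
  d
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix needs sample names", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  invisible(d)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward.D2 criterion (squared-distance
#' Lance-Williams update on the supplied distances), the variant matching
#' Ward's original method when given plain (unsquared) distances.
#'
#' @param d symmetric distance matrix with zero diagonal (e.g. from
#'   [jsdDistanceMatrix()]).
#' @return An `hclust` object.
#' @export
wardClustering <- function(d) {
  .checkDistanceMatrix(d)
  if (nrow(d) < 2L) stop("need at least two samples to cluster", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param dend an `hclust` object.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster labels (1..k) per sample.
#' @export
cutClusters <- function(dend, k) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (k < 1L || k > n)
    stop("'k' must lie between 1 and the number of samples (", n, ")",
         call. = FALSE)
  stats::cutree(dend, k = k)
}

# Connectivity in the local-neighbourhood sense: for each observation, its L
# nearest neighbours (by the supplied distances, ties broken by sample order)
# contribute 1/j when the j-th nearest neighbour is not co-clustered.
.connectivity <- function(d, labels, neighbors) {
  n <- nrow(d)
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])           # stable: ties by position
    nn <- seq_len(n)[-i][ord][seq_len(neighbors)]
    mismatch <- labels[nn] != labels[i]
    total <- total + sum((1 / seq_len(neighbors))[mismatch])
  }
  total
}

# Dunn index: smallest between-cluster distance over largest within-cluster
# diameter.
.dunn <- function(d, labels) {
  cl <- unique(labels)
  between <- Inf
  diam <- 0
  for (a in cl) {
    ia <- which(labels == a)
    if (length(ia) > 1L) diam <- max(diam, max(d[ia, ia]))
    for (b in cl[cl != a]) {
      between <- min(between, min(d[ia, which(labels == b), drop = FALSE]))
    }
  }
  if (diam == 0) return(Inf)
  between / diam
}

#' Internal validation statistics over a range of cluster counts
#'
#' For each candidate k the dendrogram is cut and three statistics computed
#' from the distance matrix: connectivity (local-neighbour violations, lower
#' better), mean silhouette width (higher better) and the Dunn index (higher
#' better). The optimum per statistic is flagged.
#'
#' @param d symmetric distance matrix.
#' @param dend `hclust` object built from `d`.
#' @param kRange integer vector of cluster counts (each between 2 and n-1).
#' @param neighbors neighbourhood size for connectivity (default 10, the
#'   convention of standard cluster-validation software).
#' @return A `data.frame` with columns `k`, `connectivity`, `silhouette`,
#'   `dunn` and logical `best_*` flags.
#' @export
validateClustering <- function(d, dend, kRange = 2:6, neighbors = 10L) {
  .checkDistanceMatrix(d)
  n <- nrow(d)
  if (neighbors >= n)
    stop("'neighbors' must be smaller than the number of samples", call. = FALSE)
  if (any(kRange < 2L | kRange > n - 1L))
    stop("each k must lie in [2, n-1]", call. = FALSE)
  res <- lapply(kRange, function(k) {
    labels <- cutClusters(dend, k)
    sil <- cluster::silhouette(labels, stats::as.dist(d))
    data.frame(k = k,
               connectivity = .connectivity(d, labels, neighbors),
               silhouette = mean(sil[, "sil_width"]),
               dunn = .dunn(d, labels))
  })
  out <- do.call(rbind, res)
  out$best_connectivity <- out$connectivity == min(out$connectivity)
  out$best_silhouette <- out$silhouette == max(out$silhouette)
  out$best_dunn <- out$dunn == max(out$dunn)
  out
}

#' Alpha diversity of each sample
#'
#' Supported metrics: `"observed"` richness (number of features with value
#' greater than zero), `"shannon"` (natural log), `"simpson"` (1 - sum p^2)
#' and `"invsimpson"` (1 / sum p^2).
#'
#' @param table an [AbundanceTable-class] (counts or relative; richness on
#'   relative data uses presence = value > 0).
#' @param metrics character vector of metric names.
#' @return A long `data.frame` with columns `sample_id`, `metric`, `value`.
#' @export
alphaDiversity <- function(table, metrics = c("observed", "shannon",
                                              "simpson", "invsimpson")) {
  stopifnot(methods::is(table, "AbundanceTable"))
  known <- c("observed", "shannon", "simpson", "invsimpson")
  bad <- setdiff(metrics, known)
  if (length(bad))
    stop("unknown alpha-diversity metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- abundances(table)
  one <- function(m) {
    val <- switch(m,
      observed = rowSums(v > 0),
      shannon = vegan::diversity(v, index = "shannon"),
      simpson = vegan::diversity(v, index = "simpson"),
      invsimpson = vegan::diversity(v, index = "invsimpson"))
    data.frame(sample_id = rownames(v), metric = m, value = as.numeric(val),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(metrics, one))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate two clusterings of the same samples
#'
#' @param a,b cluster label vectors over the same samples; if both are named
#'   they are aligned by name first.
#' @return A contingency `table` of label-pair counts.
#' @export
crossTabulateClusterings <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("the two labelings cover different samples", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("the two labelings have different lengths", call. = FALSE)
  }
  table(a = a, b = b)
}
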