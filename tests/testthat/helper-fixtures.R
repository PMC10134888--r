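# Shared fixtures built in code.

# small abundance matrix with dimnames
mat2 <- function(vals, samples, feats) {
  matrix(vals, nrow = length(samples), byrow = TRUE,
         dimnames = list(samples, feats))
}

# tiny relative table
tinyRelative <- function() {
  abundanceTable(mat2(c(0.6, 0.4, 0.5, 0.5), c("s1", "s2"), c("f1", "f2")),
                 scale = "relative")
}

# reference model with every taxon perfectly referenced
perfectReference <- function(taxa = mgInferEval:::.DEFAULT_TAXA,
                             mode = "retain_blend") {
  referenceModel(stats::setNames(rep(1, length(taxa)), taxa), mode = mode)
}

# the noise-free, perfectly-referenced generator (perfect-prediction limit)
noiseFreeConfig <- function(seed = 1L, ...) {
  generatorConfig(seed = seed, noiseSD = 0, depth = Inf,
                  reference = perfectReference(), ...)
}

# differential-reference model: the iners-like taxon below
# the discard threshold, everything else perfect
inersErrorReference <- function(ani_iners = 0.90,
                                mode = "discard_renormalize") {
  ani <- stats::setNames(rep(1, length(mgInferEval:::.DEFAULT_TAXA)),
                         mgInferEval:::.DEFAULT_TAXA)
  ani["L_iners"] <- ani_iners
  referenceModel(ani, mode = mode)
}

# independent mid-rank + Pearson Spearman oracle
spearmanOracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# independent exhaustive two-sided rank-sum oracle: walks all subsets of the
# pooled indices via bit masks (different traversal than the implementation)
wilcoxonOracle <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  centre <- m * (m + n + 1) / 2
  wobs <- sum(r[seq_len(m)])
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^(m + n) - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m + n) - 1)) > 0)
    if (length(idx) != m) next
    total <- total + 1L
    if (abs(sum(r[idx]) - centre) >= abs(wobs - centre) - 1e-12)
      hits <- hits + 1L
  }
  hits / total
}
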