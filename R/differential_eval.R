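#' @include concordance_eval.R
NULL

# Exact two-sided rank-sum P by enumeration of all group assignments of the
# pooled mid-ranks (tie-aware): the fraction of assignments whose rank sum is
# at least as far from its null mean as the observed one.
.exactWilcoxP <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(m)])
  centre <- m * (length(r) + 1) / 2
  combs <- utils::combn(length(r), m)
  w <- colSums(matrix(r[combs], nrow = m))
  mean(abs(w - centre) >= abs(wobs - centre) - 1e-12)
}

#' Two-sided Wilcoxon rank-sum P value
#'
#' Case/control test of the null that a KO's relative abundances do not
#' differ between groups. Exact P values are used wherever feasible: when
#' both groups have at most 10 values the two-sided P is computed by
#' exhaustive enumeration of group assignments of the pooled mid-ranks,
#' which stays exact under ties; for tie-free data with both groups below
#' 50 the classical exact rank-sum distribution is used; otherwise the
#' normal approximation with tie and continuity corrections. Completely
#' tied data (no separation information at all) give P = 1.
#'
#' @param x,y numeric vectors for the two groups (each non-empty, at least 3
#'   values combined).
#' @param exact logical overriding the exact/approximate switch, or `NULL`
#'   (default policy above).
#' @return The two-sided P value in (0, 1].
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # 1/3 by enumeration
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  if (all(c(x, y) == c(x, y)[1L])) return(1)   # no separation at all
  if (length(x) + length(y) < 3L)
    stop("need at least 3 values in total", call. = FALSE)
  small <- length(x) <= 10L && length(y) <= 10L
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- small || (!ties && max(length(x), length(y)) < 50L)
  if (exact && small) return(.exactWilcoxP(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact && !ties, correct = TRUE)$p.value)
}

#' Signed log10 transformation of a P value
#'
#' `Pt = log10(P) * sign(mean_case - mean_control)`: a single signed quantity
#' carrying both the significance and the direction of a case/control
#' abundance difference. Large negative values mean strongly elevated in
#' cases; large positive values strongly elevated in controls; values near 0
#' mean no evidence either way. `sign(0)` gives `Pt = 0`, and P is floored at
#' 1e-300 so the transform stays finite.
#'
#' @param p P value(s) in (0, 1].
#' @param meanCase,meanControl group mean relative abundances.
#' @return `Pt`, vectorized over the inputs.
#' @examples
#' transformP(0.001, 2, 1)   # -3
#' transformP(0.05, 1, 2)    # +1.30103
#' @export
transformP <- function(p, meanCase, meanControl) {
  if (any(p <= 0 | p > 1))
    stop("P values must lie in (0, 1]", call. = FALSE)
  log10(pmax(p, 1e-300)) * sign(meanCase - meanControl)
}

#' Concordance of signed log10 P values between observed and predicted data
#'
#' For the overall stratum and each community cluster: Wilcoxon case/control
#' tests are run per KO separately on the observed and on the predicted
#' values, using only that stratum's samples; each P value is transformed
#' with [transformP()]; and one Spearman correlation is computed between the
#' two Pt vectors across KOs. When an annotation is supplied, the overall
#' Pt vectors are additionally correlated within each level-1 category
#' (categories partition KOs, not samples).
#'
#' @param observed,predicted sample-aligned, feature-aligned
#'   [AbundanceTable-class]s restricted to shared KOs.
#' @param frame per-sample metadata with `outcome` and optional `cluster`.
#' @param annotation optional annotation from [featureAnnotation()].
#' @param method label recorded on the outputs.
#' @param strata `"all"` (overall plus clusters) or `"overall"`.
#' @param exact passed to [wilcoxonRankSum()].
#' @return A list with `records` (one row per feature, dataset and stratum:
#'   `P`, `mean_case`, `mean_control`, `sign`, `Pt`) and `concordance` (one
#'   row per stratum and method: `rho`, `n_kos`). Strata lacking cases or
#'   controls are reported with `NA` and a diagnostic reason, never silently
#'   dropped.
#' @export
pvalueConcordance <- function(observed, predicted, frame, annotation = NULL,
                              method = "predicted",
                              strata = c("all", "overall"), exact = NULL) {
  strata <- match.arg(strata)
  obs <- abundances(observed)
  pred <- abundances(predicted)
  if (!identical(dimnames(obs), dimnames(pred)))
    stop("observed and predicted tables must be sample- and feature-aligned",
         call. = FALSE)
  if (!identical(rownames(obs), frame$sample_id))
    stop("tables and sample frame are not aligned", call. = FALSE)
  groups <- .strataOf(frame, strata)
  records <- list()
  conc <- list()
  ptOverall <- NULL
  for (s in names(groups)) {
    ids <- groups[[s]]
    type <- if (s == "overall") "overall" else "cluster"
    sub <- frame[match(ids, frame$sample_id), ]
    case <- sub$outcome == "case"
    if (!any(case) || all(case)) {
      conc[[s]] <- data.frame(stratum = s, stratum_type = type,
                              method = method, rho = NA_real_, n_kos = 0L,
                              reason = "stratum lacks cases or controls",
                              stringsAsFactors = FALSE)
      next
    }
    one <- function(values, label) {
      m <- values[ids, , drop = FALSE]
      pt <- vapply(seq_len(ncol(m)), function(j) {
        x <- m[case, j]; y <- m[!case, j]
        p <- wilcoxonRankSum(x, y, exact = exact)
        c(p, mean(x), mean(y))
      }, numeric(3L))
      data.frame(feature_id = colnames(m), dataset = label, stratum = s,
                 stratum_type = type, P = pt[1L, ], mean_case = pt[2L, ],
                 mean_control = pt[3L, ],
                 sign = sign(pt[2L, ] - pt[3L, ]),
                 Pt = transformP(pt[1L, ], pt[2L, ], pt[3L, ]),
                 stringsAsFactors = FALSE)
    }
    ro <- one(obs, "observed")
    rp <- one(pred, method)
    records[[s]] <- rbind(ro, rp)
    rho <- spearmanRho(ro$Pt, rp$Pt)
    conc[[s]] <- data.frame(stratum = s, stratum_type = type, method = method,
                            rho = rho, n_kos = nrow(ro),
                            reason = if (is.na(rho)) "constant Pt vector" else "",
                            stringsAsFactors = FALSE)
    if (s == "overall") ptOverall <- list(obs = ro, pred = rp)
  }
  if (!is.null(annotation) && !is.null(ptOverall)) {
    cat <- annotation$category_l1[match(ptOverall$obs$feature_id,
                                        annotation$feature_id)]
    if (anyNA(cat))
      stop("annotation does not cover all features", call. = FALSE)
    for (c in unique(cat)) {
      i <- cat == c
      rho <- if (sum(i) >= 3L)
        spearmanRho(ptOverall$obs$Pt[i], ptOverall$pred$Pt[i]) else NA_real_
      conc[[paste0("category:", c)]] <-
        data.frame(stratum = c, stratum_type = "category", method = method,
                   rho = rho, n_kos = sum(i),
                   reason = if (is.na(rho)) "undefined (constant or too few KOs)" else "",
                   stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  conc <- do.call(rbind, conc)
  rownames(records) <- rownames(conc) <- NULL
  list(records = records, concordance = conc)
}

#' Tabulate Pt-concordance results
#'
#' Pass-through tabulation of the concordance rows from
#' [pvalueConcordance()] (possibly row-bound over methods), ordered by
#' stratum type and flagged where undefined.
#'
#' @param concordance the `concordance` element of [pvalueConcordance()]
#'   output.
#' @return The same rows with a logical `defined` column, ordered by
#'   `stratum_type`, `stratum`, `method`.
#' @export
summarizePConcordance <- function(concordance) {
  stopifnot(nrow(concordance) >= 1L)
  out <- concordance
  out$defined <- !is.na(out$rho)
  out[order(out$stratum_type, out$stratum, out$method), , drop = FALSE]
}
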