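#' @include AllClasses.R
NULL

#' Restrict observed and predicted tables to their shared KOs
#'
#' A KO qualifies in a dataset when its relative abundance exceeds zero in at
#' least one sample of that dataset; the shared set is the intersection of
#' the qualifying sets of the observed table and every predicted table.
#' Values are kept as-is after restriction (no renormalization) by default,
#' so correlations are computed on the abundances as produced; set
#' `renormalize = TRUE` to rescale each restricted table's rows to sum to
#' one instead.
#'
#' @param observed observed KO [AbundanceTable-class].
#' @param predicted a predicted KO [AbundanceTable-class] or named list of
#'   them.
#' @param renormalize logical; renormalize rows after restriction (default
#'   `FALSE`).
#' @return A list with `observed`, `predicted` (named list), and `shared`, a
#'   list holding `features` (the shared identifiers, in observed-table
#'   order) and `counts` (qualifying-feature count per source table).
#' @export
restrictToSharedFeatures <- function(observed, predicted, renormalize = FALSE) {
  if (methods::is(predicted, "AbundanceTable"))
    predicted <- list(predicted = predicted)
  stopifnot(methods::is(observed, "AbundanceTable"), length(predicted) >= 1L)
  positive <- function(t) featureIDs(t)[colSums(abundances(t) > 0) > 0]
  sets <- c(list(observed = positive(observed)), lapply(predicted, positive))
  shared <- Reduce(intersect, sets)
  if (!length(shared))
    stop("no KOs shared between the observed and all predicted tables",
         call. = FALSE)
  ord <- featureIDs(observed)
  shared <- ord[ord %in% shared]
  cut <- function(t) {
    out <- t[, shared]
    if (renormalize) out <- normalizeRelative(out)
    out
  }
  list(observed = cut(observed),
       predicted = lapply(predicted, cut),
       shared = list(features = shared,
                     counts = vapply(sets, length, integer(1L))))
}

#' Spearman rank correlation with explicit undefined handling
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Returns
#' `NA_real_` — never a coerced zero — when either vector is constant.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  if (identical(as.numeric(x), as.numeric(y))) return(1)  # exact, no rounding
  stats::cor(x, y, method = "spearman")
}

.strataOf <- function(frame, strata) {
  out <- list(overall = frame$sample_id)
  if (identical(strata, "overall")) return(out)
  cl <- frame$cluster
  if (any(!is.na(cl))) {
    for (c in unique(cl[!is.na(cl)]))
      out[[c]] <- frame$sample_id[!is.na(cl) & cl == c]
  }
  out
}

#' KO-specific concordance between observed and predicted abundances
#'
#' For the overall stratum and each community cluster in `frame`, computes
#' each KO's Spearman correlation between observed and predicted values
#' across that stratum's samples. Cluster labels are taken from `frame` as
#' given (typically from taxon-table clustering); this function never
#' clusters internally. KOs constant in either table within a stratum yield
#' undefined records, flagged rather than dropped.
#'
#' @param observed,predicted sample-aligned, feature-aligned
#'   [AbundanceTable-class]s (restrict with [restrictToSharedFeatures()]
#'   first).
#' @param frame per-sample metadata with optional `cluster` column.
#' @param method label recorded on the records (default `"predicted"`).
#' @param strata `"all"` (overall plus each cluster) or `"overall"`.
#' @return A `data.frame` with one row per (feature, stratum): `feature_id`,
#'   `stratum`, `stratum_type`, `method`, `rho`, `n_samples`, `defined`,
#'   `reason`.
#' @export
featureConcordance <- function(observed, predicted, frame,
                               method = "predicted",
                               strata = c("all", "overall")) {
  strata <- match.arg(strata)
  obs <- abundances(observed)
  pred <- abundances(predicted)
  if (!identical(dimnames(obs), dimnames(pred)))
    stop("observed and predicted tables must be sample- and feature-aligned",
         call. = FALSE)
  if (!identical(rownames(obs), frame$sample_id))
    stop("tables and sample frame are not aligned", call. = FALSE)
  groups <- .strataOf(frame, strata)
  res <- lapply(names(groups), function(s) {
    ids <- groups[[s]]
    type <- if (s == "overall") "overall" else "cluster"
    if (length(ids) < 3L) {
      return(data.frame(feature_id = colnames(obs), stratum = s,
                        stratum_type = type, method = method, rho = NA_real_,
                        n_samples = length(ids), defined = FALSE,
                        reason = "fewer than 3 samples",
                        stringsAsFactors = FALSE))
    }
    rho <- .colSpearman(obs[ids, , drop = FALSE], pred[ids, , drop = FALSE])
    data.frame(feature_id = colnames(obs), stratum = s, stratum_type = type,
               method = method, rho = rho, n_samples = length(ids),
               defined = !is.na(rho),
               reason = ifelse(is.na(rho), "constant vector", ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize concordance records by stratum (and functional category)
#'
#' Median, minimum and maximum of the defined correlations per
#' (stratum, method), with undefined records counted separately. When an
#' annotation is supplied, the overall-stratum records are additionally
#' grouped by level-1 functional category (categories partition KOs, not
#' samples, so the per-KO correlations are reused, not recomputed).
#'
#' @param records output of [featureConcordance()] (several methods may be
#'   row-bound).
#' @param annotation optional annotation from [featureAnnotation()].
#' @return A `data.frame` with columns `stratum`, `stratum_type`, `method`,
#'   `median_rho`, `min_rho`, `max_rho`, `n_defined`, `n_undefined`.
#' @export
summarizeConcordance <- function(records, annotation = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (!is.null(annotation)) {
    overall <- records[records$stratum_type == "overall", , drop = FALSE]
    cat <- annotation$category_l1[match(overall$feature_id,
                                        annotation$feature_id)]
    if (anyNA(cat))
      stop("annotation does not cover all features", call. = FALSE)
    extra <- overall
    extra$stratum <- cat
    extra$stratum_type <- "category"
    records <- rbind(records, extra)
  }
  key <- interaction(records$stratum, records$stratum_type, records$method,
                     drop = TRUE)
  res <- lapply(split(records, key), function(g) {
    ok <- g$rho[g$defined]
    data.frame(stratum = g$stratum[1L], stratum_type = g$stratum_type[1L],
               method = g$method[1L],
               median_rho = if (length(ok)) stats::median(ok) else NA_real_,
               min_rho = if (length(ok)) min(ok) else NA_real_,
               max_rho = if (length(ok)) max(ok) else NA_real_,
               n_defined = length(ok), n_undefined = sum(!g$defined),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$stratum_type, out$stratum, out$method), , drop = FALSE]
}

#' Permutation plan for the robustness check
#'
#' @param nPermutations number of replicates (default 100).
#' @param seed integer seed; each (table, replicate, KO) gets its own child
#'   stream so permutations are independent and exactly replayable.
#' @return A `permutation_plan` list.
#' @export
permutationPlan <- function(nPermutations = 100L, seed = 1L) {
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 1L) stop("need at least one permutation", call. = FALSE)
  structure(list(nPermutations = nPermutations, seed = as.integer(seed)),
            class = "permutation_plan")
}

.permuteTable <- function(table, plan, replicate, label) {
  v <- abundances(table)
  n <- nrow(v)
  for (j in seq_len(ncol(v))) {
    set.seed(.childSeed(plan$seed, label, replicate, j))
    v[, j] <- v[sample.int(n), j]
  }
  # independent per-column shuffles do not preserve row sums, so the result
  # is no longer compositional even when the input was
  methods::new("AbundanceTable", values = v, scale = "counts")
}

#' Independently permute each KO across samples in paired tables
#'
#' Within every table independently, each KO's values are shuffled across
#' samples by a seeded permutation, exactly preserving each column's multiset
#' of values. The observed and predicted tables (and different replicates)
#' use independent streams.
#'
#' @param observed observed KO [AbundanceTable-class].
#' @param predicted named list of predicted KO tables (or a single table).
#' @param plan a [permutationPlan()].
#' @param replicate replicate index in `1..nPermutations`.
#' @return A list with permuted `observed` and `predicted`.
#' @export
permutePair <- function(observed, predicted, plan, replicate) {
  stopifnot(inherits(plan, "permutation_plan"))
  if (replicate < 1L || replicate > plan$nPermutations)
    stop("'replicate' out of range", call. = FALSE)
  if (methods::is(predicted, "AbundanceTable"))
    predicted <- list(predicted = predicted)
  list(observed = .permuteTable(observed, plan, replicate, "observed"),
       predicted = mapply(function(t, nm) .permuteTable(t, plan, replicate, nm),
                          predicted, names(predicted), SIMPLIFY = FALSE))
}

#' Permutation-null distribution of an evaluation statistic
#'
#' Runs the chosen evaluator on each permuted replicate of the paired tables
#' and collects per-replicate stratum summaries. The unpermuted evaluation is
#' never included. A reliable evaluation statistic should collapse to about
#' zero under this null.
#'
#' @param observed observed KO [AbundanceTable-class] (already restricted to
#'   shared KOs).
#' @param predicted named list of predicted KO tables on the same features.
#' @param frame per-sample metadata.
#' @param plan a [permutationPlan()].
#' @param evaluator `"abundance"` (per-KO concordance medians) or `"pvalue"`
#'   (signed log10-P concordance).
#' @param strata `"overall"` (default, the robustness check's scope) or
#'   `"all"`.
#' @return A list with `replicates` (per-replicate stratum summaries, with a
#'   `replicate` column) and `summary` (distribution of the statistic across
#'   replicates per stratum and method: grand median and the 2.5/97.5%
#'   quantiles).
#' @export
permutationRobustness <- function(observed, predicted, frame, plan,
                                  evaluator = c("abundance", "pvalue"),
                                  strata = c("overall", "all")) {
  evaluator <- match.arg(evaluator)
  strata <- match.arg(strata)
  if (methods::is(predicted, "AbundanceTable"))
    predicted <- list(predicted = predicted)
  reps <- lapply(seq_len(plan$nPermutations), function(r) {
    perm <- permutePair(observed, predicted, plan, r)
    per_method <- lapply(names(perm$predicted), function(m) {
      if (evaluator == "abundance") {
        rec <- featureConcordance(perm$observed, perm$predicted[[m]], frame,
                                  method = m, strata = strata)
        s <- summarizeConcordance(rec)
        data.frame(replicate = r, stratum = s$stratum, method = s$method,
                   statistic = s$median_rho, stringsAsFactors = FALSE)
      } else {
        pc <- pvalueConcordance(perm$observed, perm$predicted[[m]], frame,
                                method = m, strata = strata)$concordance
        data.frame(replicate = r, stratum = pc$stratum, method = pc$method,
                   statistic = pc$rho, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, per_method)
  })
  reps <- do.call(rbind, reps)
  key <- interaction(reps$stratum, reps$method, drop = TRUE)
  summ <- lapply(split(reps, key), function(g) {
    st <- g$statistic[!is.na(g$statistic)]
    data.frame(stratum = g$stratum[1L], method = g$method[1L],
               grand_median = stats::median(st),
               q025 = stats::quantile(st, 0.025, names = FALSE),
               q975 = stats::quantile(st, 0.975, names = FALSE),
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}
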