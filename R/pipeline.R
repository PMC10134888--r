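#' @include synthetic_data.R concordance_eval.R differential_eval.R
#' @include community_structure.R composition_regression.R
NULL

# Name each estimated cluster after its most abundant taxon (mean within the
# cluster), so downstream stratified outputs read "L_crispatus" rather than
# "cluster 1". Duplicate dominant taxa get a numeric suffix.
.labelClusters <- function(taxonTab, labels) {
  v <- abundances(taxonTab)
  out <- character(length(labels))
  seen <- character(0)
  for (k in sort(unique(labels))) {
    i <- labels == k
    dom <- names(which.max(colMeans(v[i, , drop = FALSE])))
    if (dom %in% seen) dom <- paste0(dom, "_", k)
    seen <- c(seen, dom)
    out[i] <- dom
  }
  names(out) <- names(labels)
  out
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.stage <- function(name, expr) {
  message("[mgInferEval] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full evaluation pipeline
#'
#' Executes, in order: data acquisition (synthetic generation from `config`,
#' or reading the `inputs` paths), community clustering of the taxon table
#' (JSD + Ward, cut at `k`, with internal validation over `kRange`),
#' restriction to shared KOs, both evaluation approaches (per-KO abundance
#' concordance and signed log10-P concordance) for every predicted method,
#' the permutation robustness check, and the composition-coupling
#' regressions. Each stage's outputs are written as TSV before the next
#' stage begins, and a `manifest.yaml` echoing every resolved parameter is
#' written last; two runs with equal manifests produce identical outputs.
#'
#' @param outDir output directory (created if absent).
#' @param config a [GeneratorConfig-class] used when `inputs` is `NULL`.
#' @param inputs optional named list of file paths (`taxon`, `observed`,
#'   `predicted` — itself a named vector of method = path —, `metadata`,
#'   `annotation`) for real data.
#' @param k cluster count used for stratification (default 3; the choice of
#'   k is deliberately a user decision, never automated from the validation
#'   statistics).
#' @param kRange cluster counts scored by [validateClustering()].
#' @param nPermutations permutation replicates for the robustness check
#'   (default 100; set to 0 to skip).
#' @param seed integer seed driving the permutation plan.
#' @param predictors passed to [taxonCategoryCoupling()].
#' @return Invisibly, a list with the principal in-memory results
#'   (`dataset`, `clusters`, `validation`, `concordance`, `pt`,
#'   `permutation`, `coupling`, `manifest`).
#' @export
runPipeline <- function(outDir,
                        config = generatorConfig(),
                        inputs = NULL,
                        k = 3L,
                        kRange = 2:5,
                        nPermutations = 100L,
                        seed = 1L,
                        predictors = c("L_crispatus", "L_iners",
                                       "L_crispatus/L_iners")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ds <- if (is.null(inputs)) {
    .stage("simulate", generatePairedDataset(config, file.path(outDir, "data")))
  } else {
    .stage("read", {
      need <- c("taxon", "observed", "predicted", "metadata", "annotation")
      miss <- setdiff(need, names(inputs))
      if (length(miss))
        stop("missing input path(s): ", paste(miss, collapse = ", "))
      for (p in unlist(inputs))
        if (!file.exists(p)) stop("input file not found: ", p)
      taxa <- normalizeRelative(readAbundanceTable(inputs$taxon))
      obs <- normalizeRelative(readAbundanceTable(inputs$observed))
      preds <- lapply(inputs$predicted, function(p)
        normalizeRelative(readAbundanceTable(p)))
      frame <- readSampleFrame(inputs$metadata)
      ann <- readFeatureAnnotation(inputs$annotation)
      al <- alignSamples(c(list(taxa, obs), unname(preds)), frame)
      pairedDataset(al$tables[[1L]], al$tables[[2L]],
                    stats::setNames(al$tables[-(1:2)], names(preds)),
                    al$frame, ann)
    })
  }

  cl <- .stage("cluster", {
    d <- jsdDistanceMatrix(taxonTable(ds))
    dend <- wardClustering(d)
    labels <- .labelClusters(taxonTable(ds), cutClusters(dend, k))
    val <- validateClustering(d, dend, kRange = kRange,
                              neighbors = min(10L, nrow(d) - 1L))
    .writeTSV(data.frame(sample_id = sampleIDs(ds), cluster = labels),
              file.path(outDir, "clusters.tsv"))
    .writeTSV(val, file.path(outDir, "cluster_validation.tsv"))
    list(labels = labels, validation = val)
  })
  frame <- sampleData(ds)
  frame$cluster <- cl$labels[frame$sample_id]

  shared <- .stage("restrict", {
    r <- restrictToSharedFeatures(observedKO(ds), predictedKO(ds))
    .writeTSV(data.frame(feature_id = r$shared$features),
              file.path(outDir, "shared_features.tsv"))
    r
  })

  conc <- .stage("evaluate-abundance", {
    rec <- do.call(rbind, lapply(names(shared$predicted), function(m)
      featureConcordance(shared$observed, shared$predicted[[m]], frame,
                         method = m)))
    summ <- summarizeConcordance(rec, annotation = featureData(ds))
    .writeTSV(rec, file.path(outDir, "concordance_records.tsv"))
    .writeTSV(summ, file.path(outDir, "concordance_summary.tsv"))
    list(records = rec, summary = summ)
  })

  pt <- .stage("evaluate-pvalue", {
    res <- lapply(names(shared$predicted), function(m)
      pvalueConcordance(shared$observed, shared$predicted[[m]], frame,
                        annotation = featureData(ds), method = m))
    rec <- do.call(rbind, lapply(res, `[[`, "records"))
    con <- summarizePConcordance(do.call(rbind, lapply(res, `[[`, "concordance")))
    .writeTSV(rec, file.path(outDir, "pt_records.tsv"))
    .writeTSV(con, file.path(outDir, "pt_concordance.tsv"))
    list(records = rec, concordance = con)
  })

  perm <- NULL
  if (nPermutations > 0L) {
    perm <- .stage("permutation-null", {
      plan <- permutationPlan(nPermutations, seed)
      pr <- permutationRobustness(shared$observed, shared$predicted, frame,
                                  plan, evaluator = "abundance")
      pp <- permutationRobustness(shared$observed, shared$predicted, frame,
                                  plan, evaluator = "pvalue")
      .writeTSV(pr$replicates, file.path(outDir, "permutation_abundance.tsv"))
      .writeTSV(pp$replicates, file.path(outDir, "permutation_pvalue.tsv"))
      .writeTSV(rbind(cbind(evaluator = "abundance", pr$summary),
                      cbind(evaluator = "pvalue", pp$summary)),
                file.path(outDir, "permutation_summary.tsv"))
      list(abundance = pr, pvalue = pp)
    })
  }

  coup <- .stage("coupling", {
    co <- taxonCategoryCoupling(taxonTable(ds), observedKO(ds),
                                featureData(ds), predictors = predictors)
    .writeTSV(co, file.path(outDir, "coupling.tsv"))
    co
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mgInferEval")),
    mode = if (is.null(inputs)) "synthetic" else "files",
    generator_seed = if (is.null(inputs)) config@seed else NA,
    inputs = if (is.null(inputs)) NULL else lapply(inputs, as.vector),
    k = k, kRange = as.integer(kRange),
    nPermutations = as.integer(nPermutations), seed = as.integer(seed),
    predictors = predictors,
    n_samples = length(sampleIDs(ds)),
    n_shared_features = length(shared$shared$features))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  .stage("report", buildReport(outDir))

  invisible(list(dataset = ds, clusters = cl$labels,
                 validation = cl$validation, concordance = conc, pt = pt,
                 permutation = perm, coupling = coup, manifest = manifest))
}

#' Assemble report tables from a pipeline output directory
#'
#' Produces one tabular analog per headline analysis: abundance concordance
#' by cluster, abundance concordance by functional category, Pt concordance
#' by cluster and by category, permutation-null quantiles, and the coupling
#' R-squared grid. Missing upstream outputs are noted in the returned
#' `missing` element (the permutation section, for runs without
#' permutations) rather than failing, but an output directory with no
#' evaluation outputs at all is an error.
#'
#' @param outDir a directory written by [runPipeline()].
#' @return Invisibly, a named list of report `data.frame`s (also written as
#'   `report_*.tsv` in `outDir`) plus a character vector `missing`.
#' @export
buildReport <- function(outDir) {
  rd <- function(f) {
    p <- file.path(outDir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, sep = "\t", stringsAsFactors = FALSE)
  }
  summ <- rd("concordance_summary.tsv")
  ptc <- rd("pt_concordance.tsv")
  if (is.null(summ) && is.null(ptc))
    stop("no evaluation outputs found in ", outDir, call. = FALSE)
  out <- list()
  missing <- character(0)
  if (!is.null(summ)) {
    out$concordance_by_cluster <-
      summ[summ$stratum_type %in% c("overall", "cluster"), , drop = FALSE]
    out$concordance_by_category <-
      summ[summ$stratum_type == "category", , drop = FALSE]
  } else missing <- c(missing, "concordance")
  if (!is.null(ptc)) {
    out$pt_concordance <- ptc
  } else missing <- c(missing, "pt_concordance")
  ps <- rd("permutation_summary.tsv")
  if (!is.null(ps)) out$permutation_null <- ps
  else missing <- c(missing, "permutation_null")
  co <- rd("coupling.tsv")
  if (!is.null(co)) out$coupling <- co
  else missing <- c(missing, "coupling")
  for (nm in names(out))
    .writeTSV(out[[nm]], file.path(outDir, paste0("report_", nm, ".tsv")))
  if (length(missing))
    message("[mgInferEval] report sections absent: ",
            paste(missing, collapse = ", "))
  invisible(c(out, list(missing = missing)))
}
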