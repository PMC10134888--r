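#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## AbundanceTable
## ---------------------------------------------------------------------------

#' Sample-by-feature abundance table
#'
#' The universal exchange object of the package: a numeric matrix with
#' samples in rows and features (taxa or KEGG orthologs) in columns, plus a
#' declared measurement scale. On the `"relative"` scale every sample row
#' sums to one (within 1e-9) and all-zero rows are forbidden; on the
#' `"counts"` scale values are arbitrary non-negative numbers (raw counts,
#' or relative abundances of a feature subset that no longer sum to one).
#'
#' @slot values numeric matrix, samples x features, non-negative, no missing
#'   cells; dimnames hold unique sample and feature identifiers.
#' @slot scale `"counts"` or `"relative"`.
#'
#' @seealso [abundanceTable()], [readAbundanceTable()], [normalizeRelative()]
#' @export
setClass("AbundanceTable",
         slots = c(values = "matrix", scale = "character"))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry sample (row) and feature (column) names")
  if (anyDuplicated(rownames(v))) return("duplicated sample identifiers")
  if (anyDuplicated(colnames(v))) return("duplicated feature identifiers")
  if (anyNA(v) || any(!is.finite(v))) return("missing or non-finite cells")
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    return(sprintf("negative value at sample '%s', feature '%s'",
                   rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  if (length(object@scale) != 1L || !object@scale %in% c("counts", "relative"))
    return("'scale' must be \"counts\" or \"relative\"")
  if (object@scale == "relative") {
    sums <- rowSums(v)
    if (any(abs(sums - 1) > .REL_TOL)) {
      bad <- rownames(v)[which.max(abs(sums - 1))]
      return(sprintf("scale is \"relative\" but row '%s' sums to %.12g", bad,
                     sums[which.max(abs(sums - 1))]))
    }
  }
  TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   dimnames.
#' @param scale `"counts"` or `"relative"`. Default `"counts"`.
#' @return A validated [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.5, 0.5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' abundanceTable(m, scale = "relative")
#' @export
abundanceTable <- function(values, scale = c("counts", "relative")) {
  scale <- match.arg(scale)
  methods::new("AbundanceTable", values = values, scale = scale)
}

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) rownames(x@values))

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "AbundanceTable", function(x) colnames(x@values))

#' @rdname abundances
#' @export
setMethod("abundances", "AbundanceTable", function(x) x@values)

#' @rdname abundanceScale
#' @export
setMethod("abundanceScale", "AbundanceTable", function(x) x@scale)

setMethod("dim", "AbundanceTable", function(x) dim(x@values))

#' Subset an abundance table by sample and feature identifiers or indices
#'
#' Feature subsetting of a relative table generally breaks the rows-sum-to-one
#' invariant, in which case the result is returned on the `"counts"`
#' (unconstrained) scale with values untouched; re-normalize explicitly with
#' [normalizeRelative()] if proportions within the subset are wanted.
#'
#' @param x an [AbundanceTable-class].
#' @param i,j sample and feature selectors (names or indices).
#' @param ... ignored.
#' @param drop ignored; the result is always an `AbundanceTable`.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  scale <- x@scale
  if (scale == "relative" && any(abs(rowSums(v) - 1) > .REL_TOL))
    scale <- "counts"
  methods::new("AbundanceTable", values = v, scale = scale)
})

setMethod("show", "AbundanceTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("AbundanceTable: %d samples x %d features (scale: %s)\n",
              d[1L], d[2L], object@scale))
  cat("  samples:  ", paste(utils::head(sampleIDs(object), 4L), collapse = ", "),
      if (d[1L] > 4L) ", ..." else "", "\n", sep = "")
  cat("  features: ", paste(utils::head(featureIDs(object), 4L), collapse = ", "),
      if (d[2L] > 4L) ", ..." else "", "\n", sep = "")
})

#' @rdname normalizeRelative
#' @export
setMethod("normalizeRelative", "AbundanceTable", function(x) {
  v <- .rowNormalize(x@values)
  methods::new("AbundanceTable", values = v, scale = "relative")
})

## ---------------------------------------------------------------------------
## Sample metadata and feature annotation (validated data.frames)
## ---------------------------------------------------------------------------

#' Per-sample metadata frame
#'
#' Builds and validates the per-sample metadata used throughout the package:
#' one row per sample with a binary outcome (`"case"` / `"control"`) and an
#' optional community-cluster label.
#'
#' @param sample_id unique sample identifiers.
#' @param outcome `"case"` or `"control"` per sample.
#' @param cluster optional cluster label per sample (`NA` when unassigned).
#' @return A `data.frame` with columns `sample_id`, `outcome`, `cluster`.
#' @export
sampleFrame <- function(sample_id, outcome, cluster = NA_character_) {
  sample_id <- as.character(sample_id)
  outcome <- as.character(outcome)
  cluster <- rep_len(as.character(cluster), length(sample_id))
  if (anyDuplicated(sample_id))
    stop("duplicated sample identifiers in sample frame", call. = FALSE)
  if (length(outcome) != length(sample_id))
    stop("'outcome' must have one entry per sample", call. = FALSE)
  bad <- !outcome %in% c("case", "control")
  if (any(bad))
    stop("invalid outcome value(s): ",
         paste(unique(outcome[bad]), collapse = ", "), call. = FALSE)
  data.frame(sample_id = sample_id, outcome = outcome, cluster = cluster,
             stringsAsFactors = FALSE)
}

#' KO functional annotation frame
#'
#' One row per feature (KO), mapping it to exactly one level-1 functional
#' category and an optional level-2 category. KOs with several plausible
#' level-1 assignments must be resolved upstream: the stratified analyses
#' here require a partition of features.
#'
#' @param feature_id unique feature (KO) identifiers.
#' @param category_l1 level-1 functional category per feature.
#' @param category_l2 optional level-2 category per feature.
#' @return A `data.frame` with columns `feature_id`, `category_l1`,
#'   `category_l2`.
#' @export
featureAnnotation <- function(feature_id, category_l1, category_l2 = NA_character_) {
  feature_id <- as.character(feature_id)
  category_l1 <- as.character(category_l1)
  category_l2 <- rep_len(as.character(category_l2), length(feature_id))
  if (anyDuplicated(feature_id))
    stop("duplicated feature identifiers in annotation", call. = FALSE)
  if (length(category_l1) != length(feature_id) || anyNA(category_l1))
    stop("every feature needs exactly one level-1 category", call. = FALSE)
  data.frame(feature_id = feature_id, category_l1 = category_l1,
             category_l2 = category_l2, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## GenomeContent
## ---------------------------------------------------------------------------

#' Taxon-by-KO genome content
#'
#' Row-stochastic weights giving, for each taxon, the fraction of its genome's
#' functional content attributed to each KO. The matrix is the generative
#' analog of a reference genome database: differences between taxon rows are
#' what make community composition shifts translate into metagenome
#' composition shifts.
#'
#' @slot weights numeric matrix, taxa x KOs, non-negative, each row summing
#'   to one within 1e-9.
#' @seealso [buildGenomeContent()]
#' @export
setClass("GenomeContent", slots = c(weights = "matrix"))

setValidity("GenomeContent", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("'weights' must be numeric")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("'weights' must carry taxon and KO names")
  if (anyNA(w) || any(w < 0)) return("weights must be non-negative and complete")
  if (any(abs(rowSums(w) - 1) > .REL_TOL))
    return("each taxon row must sum to 1")
  TRUE
})

#' @rdname genomeWeights
#' @export
setMethod("genomeWeights", "GenomeContent", function(x) x@weights)

setMethod("show", "GenomeContent", function(object) {
  d <- dim(object@weights)
  cat(sprintf("GenomeContent: %d taxa x %d KOs (row-stochastic)\n", d[1L], d[2L]))
})

## ---------------------------------------------------------------------------
## ReferenceModel
## ---------------------------------------------------------------------------

#' Reference-database fidelity model for metagenome inference error
#'
#' Describes, per taxon, how well the inference tool's reference database
#' represents it, through an ANI-like similarity in \[0,1\], and how that
#' similarity is turned into prediction error:
#'
#' * `"discard_renormalize"` — taxa whose similarity falls below
#'   `aniThreshold` are removed from the composition before inference and the
#'   remaining taxa renormalized (the nearest-neighbour discard behaviour of
#'   Tax4Fun2-style tools at the conventional 97% ANI cut-off);
#' * `"retain_blend"` — every taxon is retained but its genome row is blended
#'   with a fixed seeded perturbation of itself, with weight `ani^blendExponent`
#'   on the true row (the reference-genome mismatch behaviour of
#'   PICRUSt2-style tools, graded by database proximity).
#'
#' @slot ani named numeric, similarity of each taxon to its nearest reference
#'   neighbour, in \[0,1\].
#' @slot aniThreshold discard threshold in (0,1); default 0.97.
#' @slot blendExponent positive real; larger values make predicted genome
#'   content degrade faster as `ani` falls below 1.
#' @slot perturbationSD standard deviation of the log-scale perturbation
#'   applied to sub-perfect taxa in blend mode.
#' @slot mode `"retain_blend"` or `"discard_renormalize"`.
#' @seealso [referenceModel()], [computePredictedKO()]
#' @export
setClass("ReferenceModel",
         slots = c(ani = "numeric", aniThreshold = "numeric",
                   blendExponent = "numeric", perturbationSD = "numeric",
                   mode = "character"))

setValidity("ReferenceModel", function(object) {
  if (is.null(names(object@ani)) || anyDuplicated(names(object@ani)))
    return("'ani' must be a named vector with unique taxon names")
  if (anyNA(object@ani) || any(object@ani < 0 | object@ani > 1))
    return("'ani' values must lie in [0, 1]")
  if (object@aniThreshold <= 0 || object@aniThreshold >= 1)
    return("'aniThreshold' must lie in (0, 1)")
  if (object@blendExponent <= 0) return("'blendExponent' must be positive")
  if (object@perturbationSD < 0) return("'perturbationSD' must be non-negative")
  if (!object@mode %in% c("retain_blend", "discard_renormalize"))
    return("'mode' must be \"retain_blend\" or \"discard_renormalize\"")
  TRUE
})

#' Construct a ReferenceModel
#'
#' @param ani named numeric vector of per-taxon reference similarities in
#'   \[0,1\].
#' @param aniThreshold discard threshold (default 0.97, the conventional ANI
#'   cut-off below which taxa are dropped).
#' @param blendExponent positive real (default 25); with ANI compressed into
#'   roughly \[0.9, 1\], an exponent of this size maps small similarity
#'   deficits to substantial genome-content degradation.
#' @param perturbationSD log-scale sd of the blend-mode perturbation
#'   (default 1).
#' @param mode `"retain_blend"` (default) or `"discard_renormalize"`.
#' @return A validated [ReferenceModel-class].
#' @export
referenceModel <- function(ani, aniThreshold = 0.97, blendExponent = 25,
                           perturbationSD = 1,
                           mode = c("retain_blend", "discard_renormalize")) {
  mode <- match.arg(mode)
  methods::new("ReferenceModel", ani = ani, aniThreshold = aniThreshold,
               blendExponent = blendExponent, perturbationSD = perturbationSD,
               mode = mode)
}

setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf("ReferenceModel (%s): threshold %.2f, blend exponent %g\n",
              object@mode, object@aniThreshold, object@blendExponent))
  print(round(object@ani, 3))
})

## ---------------------------------------------------------------------------
## GeneratorConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic paired-dataset generator
#'
#' Holds every parameter of the generative model: the community design
#' (samples and cases per cluster, cluster composition templates, Dirichlet
#' spread), the functional design (number of KOs, their partition into
#' level-1 categories, per-taxon category weights), the observation noise,
#' optional case/control effect KOs, the reference-fidelity model, and the
#' master seed. See [generatorConfig()] for defaults.
#'
#' @slot nSamples named integer, samples per cluster.
#' @slot nCases named integer, cases per cluster (rest are controls).
#' @slot templates numeric matrix, cluster x taxon composition templates
#'   (rows sum to one).
#' @slot concentration named numeric, concentration governing each cluster's
#'   compositional spread (dominated clusters: Beta concentration of the
#'   dominant taxon's abundance; mixed clusters: plain Dirichlet
#'   concentration).
#' @slot minorConcentration positive real, Dirichlet concentration of the
#'   conditional minor-taxon profile within dominated clusters.
#' @slot outcomeOddsRatio positive real, case-vs-control odds ratio of
#'   dominant-taxon abundance within dominated clusters (1 = no
#'   composition-outcome association; applied symmetrically so the cluster
#'   mean dominance stays at the template value).
#' @slot nKOs integer, number of KOs.
#' @slot categoryProportions named numeric, fraction of KOs per level-1
#'   category (sums to one).
#' @slot categoryWeights numeric matrix, taxon x category genome-content mass
#'   (rows sum to one).
#' @slot carriage named numeric in (0, 1\], per-taxon probability that a KO
#'   is carried by (present in) that taxon's genome.
#' @slot noiseSD non-negative real, log-normal sd of observed-table noise.
#' @slot depth positive real, mean sequencing depth (reads per sample) of
#'   the observed table's multinomial resampling; `Inf` disables counting
#'   noise.
#' @slot effectKOs named numeric, multiplicative case/control shifts keyed by
#'   KO identifier (empty for the outcome-null).
#' @slot reference a [ReferenceModel-class].
#' @slot seed integer master seed.
#' @seealso [generatorConfig()], [generatePairedDataset()]
#' @export
setClass("GeneratorConfig",
         slots = c(nSamples = "integer", nCases = "integer",
                   templates = "matrix", concentration = "numeric",
                   minorConcentration = "numeric",
                   outcomeOddsRatio = "numeric",
                   nKOs = "integer", categoryProportions = "numeric",
                   categoryWeights = "matrix", carriage = "numeric",
                   noiseSD = "numeric", depth = "numeric",
                   effectKOs = "numeric", reference = "ReferenceModel",
                   seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  cl <- rownames(object@templates)
  if (is.null(cl) || is.null(colnames(object@templates)))
    return("'templates' must carry cluster and taxon names")
  if (!identical(sort(names(object@nSamples)), sort(cl)) ||
      !identical(sort(names(object@nCases)), sort(cl)) ||
      !identical(sort(names(object@concentration)), sort(cl)))
    return("nSamples, nCases, concentration and templates must name the same clusters")
  if (any(object@nSamples <= 0L)) return("samples per cluster must be positive")
  if (any(object@nCases < 0L) ||
      any(object@nCases > object@nSamples[names(object@nCases)]))
    return("cases per cluster must lie in [0, samples per cluster]")
  if (any(object@concentration <= 0)) return("concentrations must be positive")
  if (object@minorConcentration <= 0)
    return("'minorConcentration' must be positive")
  if (object@outcomeOddsRatio <= 0)
    return("'outcomeOddsRatio' must be positive")
  if (any(object@templates < 0) ||
      any(abs(rowSums(object@templates) - 1) > 1e-8))
    return("template rows must be compositions summing to 1")
  if (object@nKOs < length(object@categoryProportions))
    return("need at least one KO per category")
  if (any(object@categoryProportions <= 0) ||
      abs(sum(object@categoryProportions) - 1) > 1e-8)
    return("categoryProportions must be positive and sum to 1")
  if (!identical(sort(colnames(object@categoryWeights)),
                 sort(names(object@categoryProportions))))
    return("categoryWeights columns must match category names")
  if (!identical(sort(rownames(object@categoryWeights)),
                 sort(colnames(object@templates))))
    return("categoryWeights rows must match taxa")
  if (any(object@categoryWeights < 0) ||
      any(abs(rowSums(object@categoryWeights) - 1) > 1e-8))
    return("categoryWeights rows must sum to 1")
  if (!identical(sort(names(object@carriage)),
                 sort(colnames(object@templates))))
    return("'carriage' must name exactly the configured taxa")
  if (any(object@carriage <= 0 | object@carriage > 1))
    return("'carriage' probabilities must lie in (0, 1]")
  if (object@noiseSD < 0) return("'noiseSD' must be non-negative")
  if (object@depth <= 0) return("'depth' must be positive (Inf allowed)")
  if (length(object@effectKOs) && is.null(names(object@effectKOs)))
    return("'effectKOs' must be named by KO identifier")
  if (!identical(sort(names(object@reference@ani)),
                 sort(colnames(object@templates))))
    return("reference model must cover exactly the configured taxa")
  TRUE
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat("  clusters: ",
      paste(sprintf("%s (n=%d, cases=%d)", names(object@nSamples),
                    object@nSamples, object@nCases[names(object@nSamples)]),
            collapse = "; "), "\n", sep = "")
  cat(sprintf("  taxa: %d, KOs: %d, noise sd: %g, effect KOs: %d, seed: %d\n",
              ncol(object@templates), object@nKOs, object@noiseSD,
              length(object@effectKOs), object@seed))
})

## ---------------------------------------------------------------------------
## PairedDataset
## ---------------------------------------------------------------------------

#' Paired taxon / observed-KO / predicted-KO dataset
#'
#' The central container: a taxon composition table, an observed KO table,
#' one or more predicted KO tables (one per inference method), all aligned on
#' the same sample axis, with per-sample metadata, KO annotation, and (for
#' synthetic data) the generator's ground truth.
#'
#' @slot taxa taxon [AbundanceTable-class], relative scale.
#' @slot observed observed KO [AbundanceTable-class], relative scale.
#' @slot predicted named list of predicted KO [AbundanceTable-class]s.
#' @slot frame per-sample metadata (see [sampleFrame()]).
#' @slot annotation KO annotation (see [featureAnnotation()]).
#' @slot truth list with elements `config`, `genome`, `reference`,
#'   `discarded` for synthetic data; empty otherwise.
#' @export
setClass("PairedDataset",
         slots = c(taxa = "AbundanceTable", observed = "AbundanceTable",
                   predicted = "list", frame = "data.frame",
                   annotation = "data.frame", truth = "list"))

setValidity("PairedDataset", function(object) {
  ids <- sampleIDs(object@taxa)
  if (!identical(sampleIDs(object@observed), ids))
    return("observed table is not sample-aligned with the taxon table")
  if (!length(object@predicted) || is.null(names(object@predicted)))
    return("'predicted' must be a non-empty named list")
  for (nm in names(object@predicted)) {
    p <- object@predicted[[nm]]
    if (!methods::is(p, "AbundanceTable"))
      return(sprintf("predicted[['%s']] is not an AbundanceTable", nm))
    if (!identical(sampleIDs(p), ids))
      return(sprintf("predicted[['%s']] is not sample-aligned", nm))
  }
  if (!identical(object@frame$sample_id, ids))
    return("sample frame is not aligned with the tables")
  if (!all(featureIDs(object@observed) %in% object@annotation$feature_id))
    return("observed KOs missing from the annotation")
  TRUE
})

#' Construct a PairedDataset
#'
#' @param taxa,observed relative-scale [AbundanceTable-class]s sharing a
#'   sample axis.
#' @param predicted named list of predicted KO tables (one per method).
#' @param frame per-sample metadata from [sampleFrame()].
#' @param annotation KO annotation from [featureAnnotation()].
#' @param truth generator ground truth (synthetic data only).
#' @return A validated [PairedDataset-class].
#' @export
pairedDataset <- function(taxa, observed, predicted, frame, annotation,
                          truth = list()) {
  methods::new("PairedDataset", taxa = taxa, observed = observed,
               predicted = predicted, frame = frame, annotation = annotation,
               truth = truth)
}

#' @rdname PairedDataset-accessors
#' @export
setMethod("taxonTable", "PairedDataset", function(x) x@taxa)

#' @rdname PairedDataset-accessors
#' @export
setMethod("observedKO", "PairedDataset", function(x) x@observed)

#' @rdname PairedDataset-accessors
#' @export
setMethod("predictedKO", "PairedDataset", function(x) x@predicted)

#' @rdname PairedDataset-accessors
#' @export
setMethod("sampleData", "PairedDataset", function(x) x@frame)

#' @rdname PairedDataset-accessors
#' @export
setMethod("featureData", "PairedDataset", function(x) x@annotation)

#' @rdname PairedDataset-accessors
#' @export
setMethod("generatorTruth", "PairedDataset", function(x) x@truth)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "PairedDataset", function(x) sampleIDs(x@taxa))

setMethod("show", "PairedDataset", function(object) {
  cat(sprintf("PairedDataset: %d samples, %d taxa, %d KOs, methods: %s\n",
              nrow(abundances(object@taxa)), ncol(abundances(object@taxa)),
              ncol(abundances(object@observed)),
              paste(names(object@predicted), collapse = ", ")))
  tab <- table(object@frame$cluster, object@frame$outcome)
  print(tab)
  if (length(object@truth)) cat("  generator truth attached\n")
})
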