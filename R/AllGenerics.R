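#' @include utils.R
NULL

#' Sample identifiers of a data object
#'
#' @param x an object with a sample axis.
#' @return Character vector of sample identifiers.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Feature identifiers of a data object
#'
#' @param x an object with a feature axis.
#' @return Character vector of feature identifiers.
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' Abundance matrix of a table
#'
#' @param x an [AbundanceTable-class] object.
#' @return Numeric matrix, samples in rows, features in columns.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' Measurement scale of an abundance table
#'
#' @param x an [AbundanceTable-class] object.
#' @return `"relative"` (rows sum to one) or `"counts"` (unconstrained
#'   non-negative values).
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' Convert a table to relative abundances
#'
#' Divides every sample row by its total so rows sum to one. Idempotent on
#' tables already on the relative scale; preserves within-row ratios and
#' sample/feature order.
#'
#' @param x an [AbundanceTable-class] object.
#' @return An [AbundanceTable-class] with `abundanceScale(x) == "relative"`.
#' @export
setGeneric("normalizeRelative", function(x) standardGeneric("normalizeRelative"))

#' Taxon-by-gene content weights
#'
#' @param x a [GenomeContent-class] object.
#' @return Row-stochastic numeric matrix (taxa in rows, gene families in
#'   columns).
#' @export
setGeneric("genomeWeights", function(x) standardGeneric("genomeWeights"))

#' Components of a paired taxon/function dataset
#'
#' `taxonTable()`, `observedKO()`, `predictedKO()`, `sampleData()`,
#' `featureData()` and `generatorTruth()` extract the aligned parts of a
#' [PairedDataset-class]: the taxon composition table, the observed
#' (shotgun-style) KO table, the named list of predicted KO tables, the
#' per-sample metadata, the KO functional annotation, and the generator's
#' ground-truth parameters (empty for non-synthetic data).
#'
#' @param x a [PairedDataset-class] object.
#' @return See the individual descriptions above.
#' @name PairedDataset-accessors
NULL

#' @rdname PairedDataset-accessors
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))

#' @rdname PairedDataset-accessors
#' @export
setGeneric("observedKO", function(x) standardGeneric("observedKO"))

#' @rdname PairedDataset-accessors
#' @export
setGeneric("predictedKO", function(x) standardGeneric("predictedKO"))

#' @rdname PairedDataset-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname PairedDataset-accessors
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname PairedDataset-accessors
#' @export
setGeneric("generatorTruth", function(x) standardGeneric("generatorTruth"))
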