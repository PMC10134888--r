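#' @include AllClasses.R
NULL

## TSV conventions: UTF-8, tab-delimited, '.' decimal. Abundance tables have
## the first column 'sample_id' and one column per feature. Features and
## samples are matched by identifier everywhere, never by position.

#' Read an abundance table from TSV
#'
#' Expects a header line `sample_id<TAB>feat1<TAB>feat2...` and one numeric
#' row per sample. The measurement scale is inferred unless given: if every
#' row sums to one within 1e-6 the table is taken as relative, otherwise as
#' counts.
#'
#' @param path path to a TSV file.
#' @param scale optional `"counts"` or `"relative"` hint overriding the
#'   inference.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, scale = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("abundance TSV needs a sample_id column plus at least one feature: ",
         path, call. = FALSE)
  ids <- df[[1L]]
  feats <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate sample identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(feats))
    stop("duplicate feature identifier(s) in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "), call. = FALSE)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(feats),
              dimnames = list(ids, feats))
  for (j in seq_along(feats)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      stop(sprintf("malformed numeric cell at sample '%s', feature '%s': \"%s\"",
                   ids[i], feats[j], col[i]), call. = FALSE)
    }
    m[, j] <- num
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 ids[neg[1L, 1L]], feats[neg[1L, 2L]]), call. = FALSE)
  if (is.null(scale)) {
    scale <- if (all(abs(rowSums(m) - 1) <= 1e-6)) "relative" else "counts"
    if (scale == "relative") m <- m / rowSums(m)   # snap to exact row sums
  }
  abundanceTable(m, scale = scale)
}

#' Write an abundance table to TSV
#'
#' Values are written with full precision (`format(..., digits = 17)`) so a
#' read/write round trip reproduces the table exactly.
#'
#' @param x an [AbundanceTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
  stopifnot(methods::is(x, "AbundanceTable"))
  m <- abundances(x)
  out <- data.frame(sample_id = rownames(m),
                    format(m, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns `sample_id`, `outcome` (`case`/`control`) and optionally `cluster`.
#'
#' @param path TSV path.
#' @return `readSampleFrame()` returns the validated metadata `data.frame`;
#'   `writeSampleFrame()` returns `path` invisibly.
#' @export
readSampleFrame <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("sample_id", "outcome") %in% colnames(df)))
    stop("metadata TSV must have 'sample_id' and 'outcome' columns: ", path,
         call. = FALSE)
  cl <- if ("cluster" %in% colnames(df)) df$cluster else NA_character_
  sampleFrame(df$sample_id, df$outcome, cl)
}

#' @rdname readSampleFrame
#' @param frame a metadata `data.frame` from [sampleFrame()].
#' @export
writeSampleFrame <- function(frame, path) {
  utils::write.table(frame, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write feature annotation TSV
#'
#' Columns `feature_id`, `category_l1` and optionally `category_l2`.
#'
#' @param path TSV path.
#' @return `readFeatureAnnotation()` returns the validated annotation
#'   `data.frame`; `writeFeatureAnnotation()` returns `path` invisibly.
#' @export
readFeatureAnnotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("feature_id", "category_l1") %in% colnames(df)))
    stop("annotation TSV must have 'feature_id' and 'category_l1' columns: ",
         path, call. = FALSE)
  l2 <- if ("category_l2" %in% colnames(df)) df$category_l2 else NA_character_
  featureAnnotation(df$feature_id, df$category_l1, l2)
}

#' @rdname readFeatureAnnotation
#' @param annotation an annotation `data.frame` from [featureAnnotation()].
#' @export
writeFeatureAnnotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict tables and metadata to their shared samples
#'
#' Intersects the sample sets of all tables (and the metadata frame, if any)
#' and returns every table restricted to the shared samples in one canonical
#' order: the order in which the shared samples appear in the first table.
#'
#' @param tables list of [AbundanceTable-class] objects.
#' @param frame optional metadata `data.frame` with a `sample_id` column.
#' @return A list with `tables` (the aligned tables, same names as input) and
#'   `frame` (the aligned metadata or `NULL`).
#' @export
alignSamples <- function(tables, frame = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  shared <- Reduce(intersect, lapply(tables, sampleIDs))
  if (!is.null(frame)) shared <- intersect(shared, frame$sample_id)
  if (!length(shared))
    stop("no samples shared across all tables", call. = FALSE)
  ord <- sampleIDs(tables[[1L]])
  shared <- ord[ord %in% shared]
  out <- lapply(tables, function(t) t[shared, ])
  fr <- NULL
  if (!is.null(frame))
    fr <- frame[match(shared, frame$sample_id), , drop = FALSE]
  if (!is.null(fr)) rownames(fr) <- NULL
  list(tables = out, frame = fr)
}
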