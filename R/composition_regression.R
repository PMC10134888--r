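#' @include AllClasses.R
NULL

#' Aggregate KO abundances into functional-category abundances
#'
#' Per sample, each level-1 category's value is the sum of its member KOs'
#' abundances; per-sample total mass is conserved exactly, so a complete
#' relative KO table yields a relative category table.
#'
#' @param koTable a KO [AbundanceTable-class].
#' @param annotation annotation from [featureAnnotation()] covering every KO
#'   in the table (unannotated KOs are an error listing the offenders).
#' @return An [AbundanceTable-class] over categories.
#' @export
categoryAbundance <- function(koTable, annotation) {
  stopifnot(methods::is(koTable, "AbundanceTable"))
  v <- abundances(koTable)
  cat <- annotation$category_l1[match(colnames(v), annotation$feature_id)]
  if (anyNA(cat)) {
    miss <- colnames(v)[is.na(cat)]
    stop("unannotated KO(s): ", paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) ", ..." else "", call. = FALSE)
  }
  agg <- t(rowsum(t(v), group = cat))
  methods::new("AbundanceTable", values = agg, scale = abundanceScale(koTable))
}

#' Simple least-squares fit: R-squared and slope sign
#'
#' Fits `y = a + b x` by ordinary least squares and returns the proportion of
#' response variation explained plus the sign of the slope. A constant
#' response gives `r_squared = 0` (slope sign 0) by convention; a constant
#' predictor is an error.
#'
#' @param x predictor vector (non-constant, length at least 3).
#' @param y response vector of the same length.
#' @return A list with `r_squared` in `[0, 1]` and `slope_sign` in
#'   `{-1, 0, 1}`.
#' @export
olsR2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("constant predictor", call. = FALSE)
  if (stats::var(y) == 0) return(list(r_squared = 0, slope_sign = 0))
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope_sign = sign(unname(stats::coef(fit)[2L])))
}

#' Coupling of functional-category abundance to community composition
#'
#' Regresses each functional category's relative abundance (response) on
#' each requested predictor: a taxon's relative abundance, or a taxon ratio
#' written `"A/B"` and computed as `(A + eps) / (B + eps)` with a
#' pseudocount guarding empty denominators. Reports the linear-model
#' R-squared and slope sign per (predictor, category) pair.
#'
#' @param taxonTable relative taxon [AbundanceTable-class].
#' @param koTable sample-aligned KO [AbundanceTable-class].
#' @param annotation annotation from [featureAnnotation()].
#' @param predictors character vector of taxon names and/or `"A/B"` ratio
#'   specifications (default: the two Lactobacillus taxa and their ratio).
#' @param pseudocount ratio pseudocount `eps` (default 1e-6).
#' @return A `data.frame` with columns `predictor`, `category`, `r_squared`,
#'   `slope_sign`, `n`.
#' @export
taxonCategoryCoupling <- function(taxonTable, koTable, annotation,
                                  predictors = c("L_crispatus", "L_iners",
                                                 "L_crispatus/L_iners"),
                                  pseudocount = 1e-6) {
  stopifnot(methods::is(taxonTable, "AbundanceTable"))
  tv <- abundances(taxonTable)
  if (!identical(rownames(tv), sampleIDs(koTable)))
    stop("taxon and KO tables must be sample-aligned", call. = FALSE)
  catTab <- abundances(categoryAbundance(koTable, annotation))
  predVec <- function(spec) {
    if (grepl("/", spec, fixed = TRUE)) {
      parts <- strsplit(spec, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !all(parts %in% colnames(tv)))
        stop("unknown taxon in ratio predictor '", spec, "'", call. = FALSE)
      (tv[, parts[1L]] + pseudocount) / (tv[, parts[2L]] + pseudocount)
    } else {
      if (!spec %in% colnames(tv))
        stop("unknown taxon name '", spec, "'", call. = FALSE)
      tv[, spec]
    }
  }
  rows <- list()
  for (p in predictors) {
    x <- predVec(p)
    for (cat in colnames(catTab)) {
      fit <- olsR2(x, catTab[, cat])
      rows[[paste(p, cat)]] <-
        data.frame(predictor = p, category = cat,
                   r_squared = fit$r_squared, slope_sign = fit$slope_sign,
                   n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
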