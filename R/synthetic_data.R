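#' @include AllClasses.R
NULL

.DEFAULT_TAXA <- c("L_crispatus", "L_iners", "G_vaginalis", "A_vaginae",
                   "P_bivia", "S_anginosus", "M_curtisii", "F_vaginae")

.DEFAULT_CATEGORIES <- c(metabolism = 0.30,
                         genetic_information_processing = 0.16,
                         environmental_information_processing = 0.10,
                         cellular_processes = 0.08,
                         organismal_systems = 0.06,
                         human_diseases = 0.06,
                         brite_hierarchies = 0.14,
                         uncharacterized = 0.10)

# Cluster composition templates. The dominated clusters put the dominant
# Lactobacillus at its configured mean; the mixed cluster spreads mass over a
# Gardnerella-like taxon and several anaerobes.
.defaultTemplates <- function(taxa, dominance) {
  stopifnot(length(taxa) >= 8L)
  tm <- matrix(0, nrow = 3L, ncol = length(taxa),
               dimnames = list(c("crispatus", "iners", "mixed"), taxa))
  rest <- setdiff(taxa, c("L_crispatus", "L_iners", "G_vaginalis"))
  d1 <- dominance[["crispatus"]]
  tm["crispatus", "L_crispatus"] <- d1
  tm["crispatus", "L_iners"] <- 0.04
  tm["crispatus", "G_vaginalis"] <- 0.02
  tm["crispatus", rest] <- (1 - d1 - 0.06) / length(rest)
  d2 <- dominance[["iners"]]
  tm["iners", "L_iners"] <- d2
  tm["iners", "L_crispatus"] <- 0.03
  tm["iners", "G_vaginalis"] <- 0.03
  tm["iners", rest] <- (1 - d2 - 0.06) / length(rest)
  mixed <- c(L_crispatus = 0.04, L_iners = 0.12, G_vaginalis = 0.32)
  tm["mixed", names(mixed)] <- mixed
  tm["mixed", rest] <- 0.52 / length(rest)
  tm / rowSums(tm)
}

# Per-taxon genome mass over level-1 functional categories. The iners-like
# taxon is enriched for genetic information processing (replication/repair,
# transcription, translation) and depleted for uncharacterized genes; the
# crispatus-like taxon is the reverse. Background taxa sit at the KO-partition
# proportions.
.defaultCategoryWeights <- function(taxa, categories) {
  base <- categories[names(categories)]
  w <- matrix(rep(base, each = length(taxa)), nrow = length(taxa),
              dimnames = list(taxa, names(categories)))
  w["L_crispatus", ] <- c(0.42, 0.08, 0.09, 0.06, 0.04, 0.04, 0.09, 0.18)
  w["L_iners", ]     <- c(0.20, 0.36, 0.08, 0.06, 0.04, 0.04, 0.12, 0.10)
  w / rowSums(w)
}

.DEFAULT_ANI <- c(L_crispatus = 0.995, L_iners = 0.93, G_vaginalis = 0.955,
                  A_vaginae = 0.94, P_bivia = 0.98, S_anginosus = 0.99,
                  M_curtisii = 0.96, F_vaginae = 0.975)

# Per-taxon probability that a given KO is present in the genome. Real
# genomes carry only a subset of the KO universe; presence/absence is what
# lets loss of one taxon's reference remove information rather than merely
# rescale it.
.DEFAULT_CARRIAGE <- c(L_crispatus = 0.50, L_iners = 0.55, G_vaginalis = 0.50,
                       A_vaginae = 0.45, P_bivia = 0.45, S_anginosus = 0.45,
                       M_curtisii = 0.45, F_vaginae = 0.45)

#' Configure the synthetic paired-dataset generator
#'
#' Defaults reproduce the community design under which differential
#' metagenome-inference error arises in vaginal microbiome data: 72 samples
#' in three community state clusters (17 L. crispatus-dominated with 11
#' cases, 31 L. iners-dominated with 13 cases, 24 mixed with 11 cases),
#' within-cluster dominant-taxon mean relative abundance 0.87 (crispatus) and
#' 0.86 (iners), 500 KOs over eight level-1 functional categories, an
#' iners-like taxon enriched for genetic-information-processing gene content,
#' and a reference-fidelity map in which the iners-like taxon falls below the
#' 0.97 ANI discard threshold while the crispatus-like taxon is
#' near-perfectly referenced.
#'
#' @param nSamples named integer, samples per cluster.
#' @param nCases named integer, case (e.g. early preterm birth) count per
#'   cluster; the remainder are controls.
#' @param dominance named numeric, mean relative abundance of the dominant
#'   taxon in the `crispatus` and `iners` clusters.
#' @param concentration named numeric controlling each cluster's
#'   compositional spread: in dominated clusters the Beta concentration of
#'   the dominant taxon's abundance (default 12, giving a broad, realistic
#'   dominance distribution of about 0.87 +/- 0.09), in the mixed cluster a
#'   plain Dirichlet concentration.
#' @param minorConcentration Dirichlet concentration of the conditional
#'   minor-taxon profile within dominated clusters (default 60: the minor
#'   profile is comparatively stable, so the dominance seesaw is the main
#'   within-cluster compositional axis, as in real community state types).
#' @param outcomeOddsRatio case-vs-control odds ratio of dominant-taxon
#'   abundance within dominated clusters (default 0.6: cases trend toward
#'   lower Lactobacillus dominance, the composition-outcome association
#'   underlying vaginal case-control designs; the shift is applied
#'   symmetrically — cases down by `sqrt(OR)`, controls up — so each
#'   cluster's mean dominance stays at its configured value; set to 1 for
#'   an outcome-null composition).
#' @param taxa character vector of taxon names (>= 8; must include
#'   `L_crispatus`, `L_iners`, `G_vaginalis`).
#' @param nKOs number of KOs.
#' @param categoryProportions named numeric partition of KOs over level-1
#'   categories (sums to one).
#' @param categoryWeights optional taxon x category matrix of genome-content
#'   mass (rows sum to one); default as described above.
#' @param carriage named numeric, per-taxon probability that a KO is carried
#'   by that taxon's genome (genome sparsity).
#' @param templates optional cluster x taxon template matrix overriding the
#'   built-in templates.
#' @param noiseSD log-normal sd of multiplicative noise on the observed KO
#'   table (default 0.25).
#' @param depth mean read depth per sample for the observed table's
#'   multinomial counting noise (default 20000; `Inf` disables resampling,
#'   e.g. for noise-free limits).
#' @param effectKOs named numeric of multiplicative case/control abundance
#'   shifts (default none: the outcome-null).
#' @param reference a [ReferenceModel-class]; default uses the ANI map above
#'   in `"retain_blend"` mode.
#' @param seed integer master seed; every random draw in the generator flows
#'   from it through named child streams.
#' @return A validated [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(seed = 1)
#' cfg
#' @export
generatorConfig <- function(nSamples = c(crispatus = 17L, iners = 31L, mixed = 24L),
                            nCases = c(crispatus = 11L, iners = 13L, mixed = 11L),
                            dominance = c(crispatus = 0.87, iners = 0.86),
                            concentration = c(crispatus = 12, iners = 12, mixed = 25),
                            minorConcentration = 60,
                            outcomeOddsRatio = 0.6,
                            taxa = .DEFAULT_TAXA,
                            nKOs = 500L,
                            categoryProportions = .DEFAULT_CATEGORIES,
                            categoryWeights = NULL,
                            carriage = .DEFAULT_CARRIAGE,
                            templates = NULL,
                            noiseSD = 0.25,
                            depth = 20000,
                            effectKOs = numeric(0),
                            reference = NULL,
                            seed = 1L) {
  if (is.null(templates)) templates <- .defaultTemplates(taxa, dominance)
  if (is.null(categoryWeights))
    categoryWeights <- .defaultCategoryWeights(taxa, categoryProportions)
  if (identical(carriage, .DEFAULT_CARRIAGE) &&
      !identical(taxa, .DEFAULT_TAXA)) {
    carriage <- .DEFAULT_CARRIAGE[taxa]
    carriage[is.na(carriage)] <- 0.45
    names(carriage) <- taxa
  }
  if (is.null(reference)) {
    ani <- .DEFAULT_ANI[taxa]
    ani[is.na(ani)] <- 0.98
    names(ani) <- taxa
    reference <- referenceModel(ani)
  }
  methods::new("GeneratorConfig",
               nSamples = as.integer(round(nSamples)) |> stats::setNames(names(nSamples)),
               nCases = as.integer(round(nCases)) |> stats::setNames(names(nCases)),
               templates = templates,
               concentration = concentration,
               minorConcentration = minorConcentration,
               outcomeOddsRatio = outcomeOddsRatio,
               nKOs = as.integer(nKOs),
               categoryProportions = categoryProportions,
               categoryWeights = categoryWeights,
               carriage = carriage,
               noiseSD = noiseSD,
               depth = depth,
               effectKOs = effectKOs,
               reference = reference,
               seed = as.integer(seed))
}

# Partition KO identifiers into level-1 categories, at least one KO each,
# sizes proportional to categoryProportions (largest-remainder rounding).
.koCategories <- function(config) {
  props <- config@categoryProportions
  n <- config@nKOs
  counts <- pmax(1L, floor(props * n))
  while (sum(counts) != n) {
    if (sum(counts) < n) {
      frac <- props * n - counts
      i <- which.max(frac)
      counts[i] <- counts[i] + 1L
    } else {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
    }
  }
  kos <- sprintf("K%05d", seq_len(n))
  data.frame(feature_id = kos,
             category_l1 = rep(names(props), counts),
             stringsAsFactors = FALSE)
}

#' Draw taxon-by-KO genome content
#'
#' KOs are partitioned across level-1 categories. Each taxon carries a
#' Bernoulli-thinned subset of each category's KOs (probability
#' `carriage[taxon]`, at least one KO per category), and its weights over the
#' carried KOs are drawn from a within-category Dirichlet, scaled so the
#' taxon's total mass per category equals its configured category weights.
#' Under the defaults the iners-like taxon carries more
#' genetic-information-processing mass than the crispatus-like taxon, which
#' carries more uncharacterized mass — the genome-composition asymmetry that
#' couples community state to metagenome composition. Sparsity means a KO
#' can be absent from a genome entirely, so discarding a taxon removes
#' information instead of merely rescaling it.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer; defaults to a child stream of the config
#'   seed.
#' @return A [GenomeContent-class].
#' @export
buildGenomeContent <- function(config, seed = NULL) {
  stopifnot(methods::is(config, "GeneratorConfig"))
  if (is.null(seed)) seed <- .childSeed(config@seed, "genome")
  cats <- .koCategories(config)
  taxa <- rownames(config@categoryWeights)
  w <- matrix(0, nrow = length(taxa), ncol = nrow(cats),
              dimnames = list(taxa, cats$feature_id))
  for (t in taxa) {
    set.seed(.childSeed(seed, "taxon", t))
    for (cat in names(config@categoryProportions)) {
      idx <- which(cats$category_l1 == cat)
      mass <- config@categoryWeights[t, cat]
      if (!length(idx)) {
        if (mass > 0)
          stop("category '", cat, "' has positive weight but zero KOs",
               call. = FALSE)
        next
      }
      carried <- idx[stats::runif(length(idx)) < config@carriage[[t]]]
      if (!length(carried)) carried <- idx[sample.int(length(idx), 1L)]
      w[t, carried] <- mass * as.vector(.rdirichlet(1L, rep(1, length(carried))))
    }
  }
  methods::new("GenomeContent", weights = w / rowSums(w))
}

#' Simulate the taxon composition table and sample metadata
#'
#' Dominated clusters (template maximum above 0.5) use a hierarchical
#' composition model: the dominant taxon's abundance is Beta-distributed with
#' mean equal to the template dominance and concentration equal to the
#' cluster's `concentration`, and the remaining mass is split among the minor
#' taxa by a Dirichlet with concentration `minorConcentration` centred on the
#' template's conditional minor profile. The mixed cluster uses a plain
#' Dirichlet centred on its template. Cluster means equal the templates
#' exactly in expectation; outcome labels are assigned per the configured
#' cases-per-cluster.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer; defaults to a child stream of the config
#'   seed.
#' @return A list with `table` (relative [AbundanceTable-class], samples x
#'   taxa) and `frame` (metadata from [sampleFrame()] with cluster labels
#'   populated).
#' @export
sampleTaxonTable <- function(config, seed = NULL) {
  stopifnot(methods::is(config, "GeneratorConfig"))
  if (is.null(seed)) seed <- .childSeed(config@seed, "taxa")
  clusters <- rownames(config@templates)
  comp <- NULL
  cl <- out <- character(0)
  for (c in clusters) {
    n <- config@nSamples[[c]]
    k <- config@nCases[[c]]
    isCase <- rep(c(TRUE, FALSE), c(k, n - k))
    set.seed(.childSeed(seed, "cluster", c))
    tpl <- config@templates[c, ]
    conc <- config@concentration[[c]]
    if (max(tpl) > 0.5) {
      dom <- which.max(tpl)
      # case/control dominance shift on the odds scale, symmetric about the
      # template so the cluster mean dominance is preserved
      odds <- tpl[dom] / (1 - tpl[dom]) *
        ifelse(isCase, sqrt(config@outcomeOddsRatio),
               1 / sqrt(config@outcomeOddsRatio))
      mu <- odds / (1 + odds)
      d <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
      minors <- tpl[-dom] / sum(tpl[-dom])
      x <- matrix(0, nrow = n, ncol = length(tpl),
                  dimnames = list(NULL, names(tpl)))
      x[, dom] <- d
      x[, -dom] <- (1 - d) *
        .rdirichlet(n, minors * config@minorConcentration)
    } else {
      x <- .rdirichlet(n, tpl * conc)
    }
    comp <- rbind(comp, x)
    cl <- c(cl, rep(c, n))
    out <- c(out, ifelse(isCase, "case", "control"))
  }
  ids <- sprintf("S%03d", seq_len(nrow(comp)))
  dimnames(comp) <- list(ids, colnames(config@templates))
  list(table = abundanceTable(comp / rowSums(comp), scale = "relative"),
       frame = sampleFrame(ids, out, cl))
}

#' Compute the observed (shotgun-style) KO table
#'
#' The noise-free functional profile of a sample is its taxon composition
#' times the genome-content matrix. Optional case/control effects multiply
#' selected KOs in case samples; multiplicative log-normal noise (sd
#' `noiseSD`) perturbs each cell; and finally, when `depth` is finite, each
#' sample's profile is resampled as `depth` multinomial reads and returned
#' as count proportions — the counting noise of finite sequencing depth,
#' which makes low-abundance KOs unreliable just as in real shotgun data.
#' Rows always sum to one. With `noiseSD = 0` and `depth = Inf` the result
#' is the exact noise-free projection.
#'
#' @param taxa relative taxon [AbundanceTable-class].
#' @param genome a [GenomeContent-class] covering the table's taxa.
#' @param noiseSD log-normal sd of the multiplicative noise (0 = none).
#' @param depth reads per sample for multinomial resampling (`Inf` = none).
#' @param seed optional integer seed for the noise streams.
#' @param effectKOs named numeric of multiplicative shifts applied to case
#'   samples (requires `frame`).
#' @param frame metadata identifying case samples, when `effectKOs` is used.
#' @return A relative [AbundanceTable-class], samples x KOs.
#' @export
computeObservedKO <- function(taxa, genome, noiseSD = 0, depth = Inf,
                              seed = NULL, effectKOs = numeric(0),
                              frame = NULL) {
  stopifnot(methods::is(taxa, "AbundanceTable"),
            methods::is(genome, "GenomeContent"),
            abundanceScale(taxa) == "relative")
  w <- genomeWeights(genome)
  comp <- abundances(taxa)
  stopifnot(identical(colnames(comp), rownames(w)))
  m <- comp %*% w
  if (length(effectKOs)) {
    if (is.null(frame))
      stop("'frame' is required to locate case samples for effectKOs",
           call. = FALSE)
    cases <- frame$sample_id[frame$outcome == "case"]
    miss <- setdiff(names(effectKOs), colnames(m))
    if (length(miss))
      stop("effect KOs absent from the genome: ",
           paste(miss, collapse = ", "), call. = FALSE)
    m[cases, names(effectKOs)] <-
      sweep(m[cases, names(effectKOs), drop = FALSE], 2L, effectKOs, `*`)
  }
  if (is.null(seed)) seed <- 0L
  if (noiseSD > 0) {
    set.seed(.childSeed(seed, "obs-noise"))
    m <- m * exp(matrix(stats::rnorm(length(m), sd = noiseSD), nrow = nrow(m)))
  }
  m <- .rowNormalize(m)
  if (is.finite(depth)) {
    set.seed(.childSeed(seed, "obs-depth"))
    for (i in seq_len(nrow(m)))
      m[i, ] <- stats::rmultinom(1L, size = round(depth), prob = m[i, ]) / round(depth)
  }
  abundanceTable(m, scale = "relative")
}

#' Compute a predicted (inference-style) KO table under reference error
#'
#' Applies the configured [ReferenceModel-class] to the taxon composition
#' before projecting through the genome content:
#'
#' * `"discard_renormalize"`: taxa with `ani` below the threshold are removed
#'   and the remaining composition renormalized — a sample consisting
#'   entirely of discarded taxa is an error naming the sample;
#' * `"retain_blend"`: each taxon's genome row becomes
#'   `ani^blendExponent * true row + (1 - ani^blendExponent) * perturbed row`,
#'   where the perturbed row is a fixed, seeded log-normal corruption of the
#'   true row.
#'
#' With all `ani = 1` both modes return exactly the noise-free observed
#' table.
#'
#' @param taxa relative taxon [AbundanceTable-class].
#' @param genome a [GenomeContent-class].
#' @param ref a [ReferenceModel-class] covering the table's taxa.
#' @param seed optional integer seed for the blend-mode perturbation rows.
#' @return A list with `table` (relative [AbundanceTable-class]) and
#'   `discarded` (named per-sample fraction of composition discarded; all
#'   zero in blend mode).
#' @export
computePredictedKO <- function(taxa, genome, ref, seed = NULL) {
  stopifnot(methods::is(taxa, "AbundanceTable"),
            methods::is(genome, "GenomeContent"),
            methods::is(ref, "ReferenceModel"),
            abundanceScale(taxa) == "relative")
  comp <- abundances(taxa)
  w <- genomeWeights(genome)
  stopifnot(identical(colnames(comp), rownames(w)))
  ani <- ref@ani[colnames(comp)]
  if (anyNA(ani))
    stop("reference model does not cover all taxa", call. = FALSE)
  if (is.null(seed)) seed <- 0L
  if (ref@mode == "discard_renormalize") {
    keep <- ani >= ref@aniThreshold
    discarded <- rowSums(comp[, !keep, drop = FALSE])
    names(discarded) <- rownames(comp)
    if (!any(keep))
      stop("all taxa fall below the ANI threshold", call. = FALSE)
    kept <- comp[, keep, drop = FALSE]
    sums <- rowSums(kept)
    if (any(sums <= 0))
      stop("entire composition discarded for sample(s): ",
           paste(rownames(comp)[sums <= 0], collapse = ", "), call. = FALSE)
    pred <- (kept / sums) %*% w[keep, , drop = FALSE]
  } else {
    wt <- ani^ref@blendExponent
    wpred <- w
    for (t in rownames(w)) {
      if (wt[[t]] >= 1) next
      set.seed(.childSeed(seed, "perturb", t))
      pert <- w[t, ] * exp(stats::rnorm(ncol(w), sd = ref@perturbationSD))
      pert <- pert / sum(pert)
      wpred[t, ] <- wt[[t]] * w[t, ] + (1 - wt[[t]]) * pert
    }
    pred <- comp %*% wpred
    discarded <- stats::setNames(numeric(nrow(comp)), rownames(comp))
  }
  list(table = abundanceTable(.rowNormalize(pred), scale = "relative"),
       discarded = discarded)
}

#' Generate a complete synthetic paired dataset
#'
#' Orchestrates [buildGenomeContent()], [sampleTaxonTable()],
#' [computeObservedKO()] and [computePredictedKO()] into a
#' [PairedDataset-class] with two predicted tables: `"blend"`
#' (retain-and-blend reference error) and `"discard"` (discard-and-
#' renormalize reference error), both driven by the same ANI map. Case/control
#' effects, if configured, are injected into the observed table only, so
#' predictions can recover differential signal only through the taxon
#' composition — the structural reason inference attenuates case/control
#' signal. The run is fully determined by `config`'s seed.
#'
#' @param config a [GeneratorConfig-class].
#' @param outDir optional directory; when given, all tables, metadata,
#'   annotation and a truth summary are written there (see
#'   [writePairedDataset()]).
#' @return A [PairedDataset-class] with `generatorTruth()` populated.
#' @examples
#' ds <- generatePairedDataset(generatorConfig(seed = 42))
#' ds
#' @export
generatePairedDataset <- function(config, outDir = NULL) {
  stopifnot(methods::is(config, "GeneratorConfig"))
  genome <- buildGenomeContent(config)
  tx <- sampleTaxonTable(config)
  observed <- computeObservedKO(tx$table, genome, noiseSD = config@noiseSD,
                                depth = config@depth,
                                seed = .childSeed(config@seed, "observed"),
                                effectKOs = config@effectKOs, frame = tx$frame)
  predSeed <- .childSeed(config@seed, "predict")
  modes <- c(blend = "retain_blend", discard = "discard_renormalize")
  predicted <- list()
  discarded <- list()
  for (m in names(modes)) {
    ref <- config@reference
    ref@mode <- modes[[m]]
    p <- computePredictedKO(tx$table, genome, ref, seed = predSeed)
    predicted[[m]] <- p$table
    discarded[[m]] <- p$discarded
  }
  cats <- .koCategories(config)
  ann <- featureAnnotation(cats$feature_id, cats$category_l1,
                           paste0(cats$category_l1, "_sub",
                                  1L + seq_len(nrow(cats)) %% 2L))
  ds <- pairedDataset(tx$table, observed, predicted, tx$frame, ann,
                      truth = list(config = config, genome = genome,
                                   reference = config@reference,
                                   discarded = discarded))
  if (!is.null(outDir)) writePairedDataset(ds, outDir)
  ds
}

#' Write a paired dataset to a directory of TSV files
#'
#' Emits `taxon.tsv`, `observed_ko.tsv`, one `predicted_<method>.tsv` per
#' method, `metadata.tsv`, `annotation.tsv` and, for synthetic data, a
#' `truth.yaml` summary of the generating parameters. Writes are
#' deterministic: identical datasets produce byte-identical files.
#'
#' @param ds a [PairedDataset-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writePairedDataset <- function(ds, dir) {
  stopifnot(methods::is(ds, "PairedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAbundanceTable(taxonTable(ds), file.path(dir, "taxon.tsv"))
  writeAbundanceTable(observedKO(ds), file.path(dir, "observed_ko.tsv"))
  for (m in names(predictedKO(ds)))
    writeAbundanceTable(predictedKO(ds)[[m]],
                        file.path(dir, paste0("predicted_", m, ".tsv")))
  writeSampleFrame(sampleData(ds), file.path(dir, "metadata.tsv"))
  writeFeatureAnnotation(featureData(ds), file.path(dir, "annotation.tsv"))
  truth <- generatorTruth(ds)
  if (length(truth)) {
    cfg <- truth$config
    yaml::write_yaml(list(
      nSamples = as.list(cfg@nSamples),
      nCases = as.list(cfg@nCases),
      concentration = as.list(cfg@concentration),
      nKOs = cfg@nKOs,
      minorConcentration = cfg@minorConcentration,
      outcomeOddsRatio = cfg@outcomeOddsRatio,
      carriage = as.list(cfg@carriage),
      noiseSD = cfg@noiseSD,
      depth = cfg@depth,
      effectKOs = as.list(cfg@effectKOs),
      ani = as.list(truth$reference@ani),
      aniThreshold = truth$reference@aniThreshold,
      blendExponent = truth$reference@blendExponent,
      perturbationSD = truth$reference@perturbationSD,
      seed = cfg@seed
    ), file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}
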