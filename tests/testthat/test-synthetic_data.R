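test_that("genome content honours category weights and sparsity", {
  taxa <- c("L_crispatus", "L_iners", "G_vaginalis", "A_vaginae",
            "P_bivia", "S_anginosus", "M_curtisii", "F_vaginae")
  cfg <- generatorConfig(seed = 2)
  g <- buildGenomeContent(cfg)
  w <- genomeWeights(g)
  expect_equal(unname(rowSums(w)), rep(1, length(taxa)), tolerance = 1e-12)
  expect_true(all(w >= 0))

  # per-category mass matches the configured category weights
  cats <- mgInferEval:::.koCategories(cfg)
  for (t in c("L_crispatus", "L_iners")) {
    per <- tapply(w[t, cats$feature_id], cats$category_l1, sum)
    expect_equal(per[colnames(cfg@categoryWeights)],
                 cfg@categoryWeights[t, ][colnames(cfg@categoryWeights)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # genetic-information-processing mass: iners-like above crispatus-like
  gip <- cats$feature_id[cats$category_l1 == "genetic_information_processing"]
  expect_lt(sum(w["L_crispatus", gip]), sum(w["L_iners", gip]))

  # determinism under the config seed
  expect_identical(w, genomeWeights(buildGenomeContent(cfg)))
})

test_that("degenerate category weights put all mass on that category", {
  taxa <- mgInferEval:::.DEFAULT_TAXA
  cw <- matrix(0, nrow = length(taxa), ncol = 8,
               dimnames = list(taxa, names(mgInferEval:::.DEFAULT_CATEGORIES)))
  cw[, "metabolism"] <- 1
  cfg <- generatorConfig(seed = 1, categoryWeights = cw,
                         carriage = stats::setNames(rep(1, 8), taxa))
  w <- genomeWeights(buildGenomeContent(cfg))
  cats <- mgInferEval:::.koCategories(cfg)
  met <- cats$feature_id[cats$category_l1 == "metabolism"]
  expect_equal(unname(rowSums(w[, met])), rep(1, length(taxa)),
               tolerance = 1e-12)
  expect_true(all(w[, setdiff(colnames(w), met)] == 0))
})

test_that("taxon table reproduces the configured case-control design", {
  cfg <- generatorConfig(seed = 4)
  tx <- sampleTaxonTable(cfg)
  fr <- tx$frame
  expect_identical(nrow(fr), 72L)
  expect_equal(as.vector(table(fr$cluster)[c("crispatus", "iners", "mixed")]),
               c(17L, 31L, 24L))
  byCl <- table(fr$cluster, fr$outcome)
  expect_equal(as.vector(byCl[c("crispatus", "iners", "mixed"), "case"]),
               c(11L, 13L, 11L))
  expect_equal(unname(rowSums(abundances(tx$table))), rep(1, 72),
               tolerance = 1e-12)
})

test_that("concentration in the tight limit collapses samples onto templates", {
  cfg <- generatorConfig(seed = 9,
                         concentration = c(crispatus = 1e7, iners = 1e7,
                                           mixed = 1e7),
                         minorConcentration = 1e7, outcomeOddsRatio = 1)
  tx <- sampleTaxonTable(cfg)
  v <- abundances(tx$table)
  for (cl in c("crispatus", "iners", "mixed")) {
    ids <- tx$frame$sample_id[tx$frame$cluster == cl]
    expect_equal(colMeans(v[ids, , drop = FALSE]),
                 cfg@templates[cl, ], tolerance = 2e-3)
    expect_lt(max(apply(v[ids, , drop = FALSE], 2, stats::sd)), 1e-3)
  }
})

test_that("observed KO table is the composition-genome projection", {
  cfg <- generatorConfig(seed = 3)
  g <- buildGenomeContent(cfg)
  w <- genomeWeights(g)
  taxa <- rownames(w)
  one <- matrix(0, 1, length(taxa), dimnames = list("s1", taxa))
  one[1, "L_iners"] <- 1
  obs1 <- computeObservedKO(abundanceTable(one, scale = "relative"), g)
  expect_equal(unname(abundances(obs1)[1, ]), unname(w["L_iners", ]),
               tolerance = 1e-12)

  half <- matrix(0, 1, length(taxa), dimnames = list("s1", taxa))
  half[1, c("L_iners", "L_crispatus")] <- 0.5
  obs2 <- computeObservedKO(abundanceTable(half, scale = "relative"), g)
  expect_equal(unname(abundances(obs2)[1, ]),
               unname((w["L_iners", ] + w["L_crispatus", ]) / 2),
               tolerance = 1e-12)

  tx <- sampleTaxonTable(cfg)
  noisy <- computeObservedKO(tx$table, g, noiseSD = 0.5, depth = 20000,
                             seed = 42)
  expect_equal(unname(rowSums(abundances(noisy))), rep(1, 72),
               tolerance = 1e-12)
})

test_that("case/control effect KOs shift case samples before renormalization", {
  cfg <- generatorConfig(seed = 6)
  g <- buildGenomeContent(cfg)
  tx <- sampleTaxonTable(cfg)
  eff <- c(K00001 = 4)
  plain <- abundances(computeObservedKO(tx$table, g))
  shifted <- abundances(computeObservedKO(tx$table, g, effectKOs = eff,
                                          frame = tx$frame))
  cases <- tx$frame$sample_id[tx$frame$outcome == "case"]
  controls <- tx$frame$sample_id[tx$frame$outcome == "control"]
  expect_equal(shifted[controls, "K00001"], plain[controls, "K00001"])
  # renormalization damps the factor slightly below 4 but well above 1
  ratio <- shifted[cases, "K00001"] / plain[cases, "K00001"]
  expect_true(all(ratio > 3 & ratio < 4))
  expect_error(computeObservedKO(tx$table, g, effectKOs = c(nope = 2),
                                 frame = tx$frame), "absent")
})

test_that("perfect reference reproduces the noise-free observed table", {
  cfg <- noiseFreeConfig(seed = 5)
  g <- buildGenomeContent(cfg)
  tx <- sampleTaxonTable(cfg)
  obs <- computeObservedKO(tx$table, g)
  for (m in c("retain_blend", "discard_renormalize")) {
    p <- computePredictedKO(tx$table, g, perfectReference(mode = m))
    expect_equal(abundances(p$table), abundances(obs), tolerance = 1e-12)
    expect_equal(unname(p$discarded), rep(0, 72))
  }
})

test_that("discard mode removes sub-threshold taxa and reports the fraction", {
  cfg <- generatorConfig(seed = 8)
  g <- buildGenomeContent(cfg)
  taxa <- rownames(genomeWeights(g))
  comp <- matrix(0.03 / (length(taxa) - 1), 1, length(taxa),
                 dimnames = list("s1", taxa))
  comp[1, "L_iners"] <- 0.97
  ref <- inersErrorReference(0.90)
  p <- computePredictedKO(abundanceTable(comp, scale = "relative"), g, ref)
  expect_equal(unname(p$discarded), 0.97, tolerance = 1e-9)
  expect_equal(sum(abundances(p$table)), 1, tolerance = 1e-9)
  # prediction carries no iners-specific signal: KOs carried only by iners
  # get zero predicted abundance
  w <- genomeWeights(g)
  onlyIners <- w["L_iners", ] > 0 &
    colSums(w[setdiff(taxa, "L_iners"), ]) == 0
  if (any(onlyIners))
    expect_true(all(abundances(p$table)[1, onlyIners] == 0))

  pure <- matrix(0, 1, length(taxa), dimnames = list("s1", taxa))
  pure[1, "L_iners"] <- 1
  expect_error(
    computePredictedKO(abundanceTable(pure, scale = "relative"), g, ref),
    "s1")
})

test_that("blend weight endpoints behave as documented", {
  cfg <- generatorConfig(seed = 10)
  g <- buildGenomeContent(cfg)
  taxa <- rownames(genomeWeights(g))
  pure <- matrix(0, 1, length(taxa), dimnames = list("s1", taxa))
  pure[1, "L_iners"] <- 1
  tab <- abundanceTable(pure, scale = "relative")

  ani <- stats::setNames(rep(1, length(taxa)), taxa)
  ani["L_iners"] <- 0
  ref <- referenceModel(ani, mode = "retain_blend")
  p1 <- computePredictedKO(tab, g, ref, seed = 77)
  p2 <- computePredictedKO(tab, g, ref, seed = 77)
  # ani = 0: only the fixed seeded perturbed row contributes
  expect_identical(abundances(p1$table), abundances(p2$table))
  expect_gt(max(abs(abundances(p1$table)[1, ] - genomeWeights(g)["L_iners", ])),
            1e-3)
  pOther <- computePredictedKO(tab, g, ref, seed = 78)
  expect_gt(max(abs(abundances(p1$table) - abundances(pOther$table))), 0)
})

test_that("generatePairedDataset is deterministic and writes byte-identical files", {
  cfg <- generatorConfig(seed = 12, nKOs = 60L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generatePairedDataset(cfg, d1)
  ds2 <- generatePairedDataset(cfg, d2)
  expect_identical(abundances(observedKO(ds1)), abundances(observedKO(ds2)))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_setequal(names(predictedKO(ds1)), c("blend", "discard"))
  expect_identical(length(sampleIDs(ds1)), 72L)
  expect_true(length(generatorTruth(ds1)) > 0)
  expect_true(all(c("taxon.tsv", "observed_ko.tsv", "predicted_blend.tsv",
                    "predicted_discard.tsv", "metadata.tsv", "annotation.tsv",
                    "truth.yaml") %in% list.files(d1)))
})

test_that("generator defaults express the dominance means and tables align", {
  ds <- generatePairedDataset(generatorConfig(seed = 20))
  fr <- sampleData(ds)
  tx <- abundances(taxonTable(ds))
  # single-dataset check at coarse tolerance; the 1000-sample calibration is
  # asserted separately
  expect_equal(mean(tx[fr$cluster == "crispatus", "L_crispatus"]), 0.87,
               tolerance = 0.1)
  for (t in c(list(observedKO(ds)), predictedKO(ds)))
    expect_identical(sampleIDs(t), fr$sample_id)
})
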