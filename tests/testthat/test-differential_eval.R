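test_that("rank-sum P matches exhaustive enumeration, ties included", {
  # tie-free instance: 2 of the 6 assignments are as extreme
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(1, 1), 1)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
  expect_error(wilcoxonRankSum(1, 2), "at least 3")

  set.seed(55)
  for (i in 1:60) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    x <- sample(1:5, m, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (all(c(x, y) == x[1])) next
    expect_equal(wilcoxonRankSum(x, y), wilcoxonOracle(x, y),
                 tolerance = 1e-9,
                 label = paste("x:", paste(x, collapse = ","),
                               "y:", paste(y, collapse = ",")))
  }
})

test_that("tie-free enumeration agrees with the classical exact test", {
  set.seed(56)
  for (i in 1:40) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    pool <- sample(1:1000, m + n)   # tie-free
    x <- pool[seq_len(m)]; y <- pool[-seq_len(m)]
    expect_equal(wilcoxonRankSum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("moderate tie-free groups use the classical exact distribution", {
  set.seed(57)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  expect_equal(wilcoxonRankSum(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("ties or large groups fall back to the corrected approximation", {
  set.seed(58)
  x <- sample(1:10, 30, replace = TRUE)   # tied data
  y <- sample(1:10, 35, replace = TRUE)
  expect_equal(wilcoxonRankSum(x, y),
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE)$p.value))
  x2 <- rnorm(60); y2 <- rnorm(55)
  expect_equal(wilcoxonRankSum(x2, y2),
               suppressWarnings(stats::wilcox.test(x2, y2, exact = FALSE,
                                                   correct = TRUE)$p.value))
})

test_that("the signed log10 transform encodes significance and direction", {
  expect_equal(transformP(0.001, 2, 1), -3)
  expect_equal(transformP(1, 5, 1), 0)
  expect_equal(transformP(0.05, 1, 2), -log10(0.05), tolerance = 1e-6)
  expect_equal(transformP(0.05, 1, 2), 1.30103, tolerance = 1e-5)
  expect_equal(transformP(0.5, 3, 3), 0)   # sign(0) convention
  expect_error(transformP(0, 1, 2), "\\(0, 1\\]")
  expect_error(transformP(1.2, 1, 2), "\\(0, 1\\]")
  # finite even at the underflow floor
  expect_true(is.finite(transformP(1e-320, 2, 1)))

  # odd under swapping case/control means; magnitude monotone in P
  set.seed(8)
  p <- runif(50, 1e-6, 1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(transformP(p, a, b), -transformP(p, b, a))
  ord <- order(p)
  expect_true(all(diff(abs(transformP(p[ord], 2, 1))) <= 0))
})

test_that("identical tables give Pt concordance 1 in every stratum", {
  ds <- generatePairedDataset(noiseFreeConfig(seed = 19, nKOs = 60L))
  r <- restrictToSharedFeatures(observedKO(ds), predictedKO(ds)$blend)
  out <- pvalueConcordance(r$observed, r$predicted$predicted, sampleData(ds),
                           annotation = featureData(ds))
  conc <- out$concordance
  expect_true(all(conc$rho[!is.na(conc$rho)] == 1))
  expect_true(all(c("overall", "cluster", "category") %in% conc$stratum_type))
  # records carry the transform's bookkeeping
  rec <- out$records
  expect_true(all(rec$P > 0 & rec$P <= 1))
  expect_equal(rec$sign, sign(rec$mean_case - rec$mean_control))
  expect_equal(rec$Pt, log10(rec$P) * rec$sign)
})

test_that("strata lacking cases or controls are flagged, not dropped", {
  m <- mat2(abs(rnorm(40)) + 0.1, paste0("s", 1:8), paste0("K", 1:5))
  tab <- abundanceTable(m)
  fr <- sampleFrame(paste0("s", 1:8),
                    c(rep("case", 4), rep("control", 4)),
                    c(rep("good", 4), rep("allcontrol", 4)))
  out <- pvalueConcordance(tab, tab, fr)
  bad <- out$concordance[out$concordance$stratum == "allcontrol", ]
  expect_true(is.na(bad$rho))
  expect_match(bad$reason, "lacks cases or controls")
  good <- out$concordance[out$concordance$stratum == "good", ]
  expect_true(is.na(good$rho) || abs(good$rho) <= 1)
})

test_that("category strata reuse the overall Pt vectors", {
  ds <- generatePairedDataset(generatorConfig(seed = 21, nKOs = 60L))
  r <- restrictToSharedFeatures(observedKO(ds), predictedKO(ds)$blend)
  ann <- featureData(ds)
  out <- pvalueConcordance(r$observed, r$predicted$predicted, sampleData(ds),
                           annotation = ann)
  rec <- out$records
  overallObs <- rec[rec$stratum == "overall" & rec$dataset == "observed", ]
  overallPred <- rec[rec$stratum == "overall" & rec$dataset == "predicted", ]
  cat <- ann$category_l1[match(overallObs$feature_id, ann$feature_id)]
  for (cl in unique(cat)) {
    i <- cat == cl
    if (sum(i) < 3) next
    expected <- spearmanRho(overallObs$Pt[i], overallPred$Pt[i])
    got <- out$concordance$rho[out$concordance$stratum == cl &
                               out$concordance$stratum_type == "category"]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("observed P values are calibrated under the generator's null", {
  # Calibration holds where the test's null does: within one cluster, whose
  # case and control samples are exchangeable under outcomeOddsRatio = 1.
  # (Across clusters the design stratifies case assignment, which makes the
  # unstratified rank-sum conservative; and within one dataset the KO P
  # values are correlated through shared compositional factors. So the
  # honest check is marginal: one KO's within-cluster P value across many
  # independently generated datasets is uniform.)
  pvals <- vapply(1:500, function(s) {
    cfg <- generatorConfig(seed = s, outcomeOddsRatio = 1, depth = Inf,
                           nKOs = 10L)
    g <- buildGenomeContent(cfg)
    tx <- sampleTaxonTable(cfg)
    v <- abundances(computeObservedKO(tx$table, g, noiseSD = cfg@noiseSD,
                                      seed = s))
    fr <- tx$frame
    i <- fr$cluster == "iners"
    case <- fr$outcome == "case"
    wilcoxonRankSum(v[i & case, 1], v[i & !case, 1])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("summarizePConcordance flags undefined rows and keeps methods apart", {
  conc <- data.frame(stratum = c("overall", "overall", "c1"),
                     stratum_type = c("overall", "overall", "cluster"),
                     method = c("m1", "m2", "m1"),
                     rho = c(0.4, NA, 0.2), n_kos = c(10L, 10L, 10L),
                     reason = c("", "constant Pt vector", ""))
  s <- summarizePConcordance(conc)
  # ordered by stratum type: the cluster row first, then the two methods
  expect_identical(s$defined, c(TRUE, TRUE, FALSE))
  expect_identical(nrow(s[s$stratum == "overall", ]), 2L)
})
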