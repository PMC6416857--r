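test_that("good/poor classification uses inclusive printed boundaries", {
  expect_equal(classifyValue(c(0.70, 0.699, 1.0, NA), "dsc"),
               c("good", "poor", "good", "poor"))
  expect_equal(classifyValue(c(2.0, 2.01, 0), "msd"),
               c("good", "poor", "good"))
  th <- qualityThresholds(dscGoodMin = 0.5, msdGoodMax = 3)
  expect_equal(classifyValue(0.6, "dsc", th), "good")
  expect_error(qualityThresholds(dscGoodMin = 1.2), "0, 1")
})

test_that("confusion counts and rates match hand tallies", {
  p <- c("good", "good", "poor", "poor", "good")
  r <- c("good", "poor", "poor", "good", "good")
  cs <- confusionFromLabels(p, r)
  expect_equal(confusionCounts(cs), c(tp = 2L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(accuracy(cs), 3 / 5)
  expect_equal(tpr(cs), 2 / 3)
  expect_equal(fpr(cs), 1 / 2)
  expect_equal(accuracy(cs) * 5, cs@tp + cs@tn)

  all_agree <- confusionFromLabels(p, p)
  expect_equal(confusionCounts(all_agree)[["fp"]], 0L)
  expect_equal(accuracy(all_agree), 1.0)

  # high-quality cohort: 898 of 900 good correctly passed, 2 false negatives
  cs <- confusionStats(tp = 898, fp = 0, tn = 0, fn = 2)
  expect_equal(accuracy(cs), 0.998, tolerance = 5e-4)
  expect_equal(tpr(cs), 898 / 900)
  expect_true(is.na(fpr(cs)))

  expect_error(confusionFromLabels(p, r[-1]), "equal length")
  expect_error(confusionFromLabels("yes", "good"), "good")

  # random labels against a counting oracle
  set.seed(2)
  p <- sample(c("good", "poor"), 50, replace = TRUE)
  r <- sample(c("good", "poor"), 50, replace = TRUE)
  cs <- confusionFromLabels(p, r)
  expect_equal(unname(confusionCounts(cs)),
               c(sum(p == "good" & r == "good"),
                 sum(p == "good" & r == "poor"),
                 sum(p == "poor" & r == "poor"),
                 sum(p == "poor" & r == "good")))
})

test_that("correctly-identified rates reproduce printed arithmetic", {
  expect_equal(correctlyIdentifiedRate(166, 171), 97.1)
  expect_equal(correctlyIdentifiedRate(443, 589), 75.2)
  expect_equal(correctlyIdentifiedRate(35, 35), 100.0)
  expect_error(correctlyIdentifiedRate(5, 0), "at least 1")
  expect_error(correctlyIdentifiedRate(6, 5), "nTotal")
})

test_that("MAE drops undefined pairs and matches direct summation", {
  expect_equal(as.numeric(maePrediction(c(0.8, 0.6), c(0.9, 0.5))), 0.1)
  expect_equal(as.numeric(maePrediction(1:5, 1:5)), 0)
  m <- maePrediction(c(0.5, NA, 0.2), c(0.4, 0.9, NA))
  expect_equal(as.numeric(m), 0.1, tolerance = 1e-12)
  expect_equal(attr(m, "nDropped"), 2L)
  set.seed(4)
  p <- runif(40); r <- runif(40)
  expect_equal(as.numeric(maePrediction(p, r)), sum(abs(p - r)) / 40)
  expect_error(maePrediction(NA, 1), "no pair")
})

test_that("correlations match closed forms and handle ties", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(pearsonR(x, x)$r, 1.0)
  expect_equal(pearsonR(x, -x + 2)$r, -1.0)
  set.seed(9)
  p <- runif(25); r <- p + rnorm(25, 0, 0.1)
  ref <- sum((p - mean(p)) * (r - mean(r))) /
    sqrt(sum((p - mean(p))^2) * sum((r - mean(r))^2))
  expect_equal(pearsonR(p, r)$r, ref, tolerance = 1e-12)
  expect_lt(pearsonR(p, r)$p, 1)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "variance")

  expect_equal(spearmanRho(1:6, (1:6)^2), 1.0)
  expect_equal(spearmanRho(1:6, rev(1:6)), -1.0)
  # tie handling: average ranks, checked against a direct rank computation
  p <- c(1, 2, 2, 3, 5, 5)
  s <- c(0, 1, 1, 1, 2, 2)
  rp <- rank(p); rs <- rank(s)
  ref <- sum((rp - mean(rp)) * (rs - mean(rs))) /
    sqrt(sum((rp - mean(rp))^2) * sum((rs - mean(rs))^2))
  expect_equal(spearmanRho(p, s), ref, tolerance = 1e-12)
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})

test_that("error-vs-quality profile bins absolute errors", {
  p <- c(0.95, 0.85, 0.55, 0.35)
  r <- c(0.9, 0.9, 0.5, 0.2)
  prof <- errorVsQualityProfile(p, r, breaks = c(0, 0.4, 0.7, 1))
  expect_equal(prof$n, c(1L, 1L, 2L))
  expect_equal(prof$mae, c(0.15, 0.05, mean(c(0.05, 0.05))))
  # single bin equals the global MAE
  one <- errorVsQualityProfile(p, r, breaks = c(0, 1))
  expect_equal(one$mae, as.numeric(maePrediction(p, r)))
  # perfect predictions give zero everywhere
  prof0 <- errorVsQualityProfile(r, r, breaks = c(0, 0.5, 1))
  expect_true(all(prof0$mae[prof0$n > 0] == 0))
})

test_that("reference-subset experiment is reproducible and consistent", {
  spec0 <- smallPhantomSpec(1)
  refs <- generateCohort(4, spec0, seed = 100, idPrefix = "ref")
  tests <- lapply(1:6, function(i) {
    gt <- generatePhantom({s <- spec0; s$seed <- 200L + i; s},
                          id = sprintf("t%02d", i))
    deg <- degradeLabelmap(atlasLabels(gt),
                           degradationSpec("boundary_erode", (i - 1) %% 3,
                                           seed = 300L + i))
    rcaTestCase(atlasId(gt), atlasImage(gt), deg,
                gtLabels = atlasLabels(gt))
  })
  cfg <- registrationConfig("translation_only")
  exp1 <- referenceSubsetExperiment(refs, tests, sizes = c(2, 4),
                                    runs = 2, seed = 7, regConfig = cfg,
                                    nested = TRUE)
  exp2 <- referenceSubsetExperiment(refs, tests, sizes = c(2, 4),
                                    runs = 2, seed = 7, regConfig = cfg,
                                    nested = TRUE)
  expect_equal(exp1$table, exp2$table)

  # the full-size subset equals the full-set run exactly, in every run
  full <- rcaBatch(tests, refs, cfg)
  fullDsc <- full$summary$predicted_dsc[full$summary$class == "WH"]
  for (run in 1:2) {
    pc <- exp1$perCase[exp1$perCase$size == 4 & exp1$perCase$run == run, ]
    expect_equal(pc$predicted_wh_dsc, fullDsc, tolerance = 1e-12)
  }
  # full size has zero across-run variance
  s4 <- exp1$summary[exp1$summary$size == 4, ]
  expect_equal(s4$min, s4$max)
  expect_true(all(exp1$summary$min <= exp1$summary$mean + 1e-12))
  expect_true(all(exp1$summary$mean <= exp1$summary$max + 1e-12))

  # nested subsets: per-case predicted DSC non-decreasing with size
  for (run in 1:2) {
    p2 <- exp1$perCase[exp1$perCase$size == 2 & exp1$perCase$run == run, ]
    p4 <- exp1$perCase[exp1$perCase$size == 4 & exp1$perCase$run == run, ]
    expect_true(all(p4$predicted_wh_dsc >= p2$predicted_wh_dsc - 1e-12))
  }
  expect_error(referenceSubsetExperiment(refs, tests, sizes = 9,
                                         regConfig = cfg),
               "exceeds")
})
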