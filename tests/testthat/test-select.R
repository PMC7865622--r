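test_that("spearmanCor recovers exact monotone relationships", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(unname(spearmanCor(x, exp(x))["rho"]), 1)
  expect_equal(unname(spearmanCor(x, -x^3)["rho"]), -1)
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  got <- spearmanCor(a, b)
  expect_equal(unname(got["rho"]), unname(ct$estimate))
  expect_equal(unname(got["p"]), ct$p.value)
  expect_error(spearmanCor(1:3, 1:3), "at least 5")
  expect_error(spearmanCor(rep(1, 6), 1:6), "constant")
  expect_error(spearmanCor(1:6, 1:5), "lengths differ")
})

test_that("overlapFeatures intersects flag sets and checks the universe", {
  fa <- c(a = TRUE, b = TRUE, c = FALSE, d = TRUE)
  fc <- c(a = TRUE, b = FALSE, c = TRUE, d = TRUE)
  expect_identical(overlapFeatures(fa, fc), c("a", "d"))
  # order of the second argument must not matter
  expect_identical(overlapFeatures(fa, fc[c(4, 2, 1, 3)]), c("a", "d"))
  expect_error(overlapFeatures(fa, fc[1:3]), "mismatched")
  expect_error(overlapFeatures(unname(fa), fc), "mismatched")
})

test_that("the reference flag fixture reproduces the published overlap", {
  flags <- referenceSignificanceFlags()
  expect_equal(nrow(flags), 33L)
  # rows follow the published table's sensor order; same universe by name
  expect_setequal(flags$feature, featureGrid())
  sel <- overlapFeatures(
    stats::setNames(flags$sig_fatigue, flags$feature),
    stats::setNames(flags$sig_complete, flags$feature))
  expect_length(sel, 16L)
  stat <- flags$statistic[match(sel, flags$feature)]
  expect_equal(sum(stat == "mean"), 6L)
  expect_equal(sum(stat == "sd"), 5L)
  expect_equal(sum(stat == "aad"), 5L)
})

test_that("screenFeatures flags p < alpha and tolerates constant features", {
  fm <- featureMatrixFixture()
  sc <- screenFeatures(fm, subset = "complete", alpha = 0.1)
  expect_equal(nrow(sc), 33L)
  expect_identical(sc$significant, !is.na(sc$p) & sc$p < 0.1)
  # a tighter allowance can only shrink the significant set
  sc01 <- screenFeatures(fm, subset = "complete", alpha = 0.01)
  expect_true(all(sc$significant[sc01$significant]))
  # constant feature: flagged insignificant, not an error
  fmC <- fm
  a <- SummarizedExperiment::assay(fmC, "features")
  a["mag_x_mean", ] <- 7
  SummarizedExperiment::assay(fmC, "features") <- a
  scC <- screenFeatures(fmC, subset = "complete")
  row <- scC[scC$feature == "mag_x_mean", ]
  expect_true(is.na(row$rho))
  expect_false(row$significant)
})

test_that("selectFeatures applies the dual-screen overlap rule", {
  fm <- featureMatrixFixture()
  sel <- selectFeatures(fm)
  expect_s4_class(sel, "SelectionResult")
  expect_equal(significanceAllowance(sel), 0.1)
  tb <- selectionTable(sel)
  expect_equal(nrow(tb), 33L)
  expect_identical(tb$selected, tb$sig_fatigue & tb$sig_complete)
  expect_identical(selectedFeatures(sel), tb$feature[tb$selected])
  expect_gt(length(selectedFeatures(sel)), 0L)
  # fatigue subset of the fixture cohort is non-trivial
  cd <- SummarizedExperiment::colData(fm)
  expect_gt(sum(cd$is_fatigued), 5L)
})

test_that("reference set-change tables reproduce their printed averages", {
  ct <- referenceSetChanges("completion_time")
  en <- referenceSetChanges("endurance")
  for (tab in list(ct, en))
    for (i in which(!is.na(tab$avg_printed))) {
      avg <- averageSetChange(as.numeric(tab[i, c("set2", "set3",
                                                  "set4", "set5")]))
      # the printed average is the recomputed one at 1-decimal precision
      expect_lt(abs(avg - tab$avg_printed[i]), 0.05 + 1e-9)
    }
})
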