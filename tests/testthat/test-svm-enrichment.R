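test_that("a well-separated planted cluster is carved out by the classifier", {
  igrs <- plantedClusterIgrs(nPos = 30L, nNeg = 300L, seed = 3L)
  model <- trainClassifier(igrs)
  expect_s4_class(model, "IgrClassifier")
  expect_equal(model@gamma, 0.5, tolerance = 1e-9)
  d <- decisionValues(model, igrs)
  pos <- lengths(rnaFamilies(igrs)) > 0
  expect_gte(mean(d[pos] > 0), 0.95)
  expect_lte(mean(d[!pos] > 0), 0.15)
})

test_that("training preconditions are enforced", {
  few <- plantedClusterIgrs(nPos = 3L, nNeg = 50L)
  expect_error(trainClassifier(few), "3 IGRs carry a known RNA family")
  ## degenerate feature: all IGRs identical in both features
  flat <- makeFeatureIgrs(rep(50, 20), rep(100L, 20),
                          labeled = rep(c(TRUE, FALSE), 10))
  expect_error(trainClassifier(flat), "zero variance")
  expect_error(trainClassifier(plantedClusterIgrs(), C = -1), "positive")
})

test_that("the decision function matches an independent refit of the SVM", {
  igrs <- plantedClusterIgrs(seed = 5L)
  model <- trainClassifier(igrs, C = 2.0, w = 1.5)
  ## independent route: e1071 with explicit standardization, in the same
  ## deterministic row order used for training
  ord <- order(as.character(GenomicRanges::seqnames(igrRanges(igrs))),
               GenomicRanges::start(igrRanges(igrs)))
  sorted <- igrs[ord]
  feat <- cbind(gcPercent(sorted), igrLength(sorted))
  z <- scale(feat)
  pos <- lengths(rnaFamilies(sorted)) > 0
  y <- factor(ifelse(pos, "rna", "background"),
              levels = c("rna", "background"))
  fit <- e1071::svm(z, y, type = "C-classification", kernel = "radial",
                    cost = 2.0, gamma = 0.5, scale = FALSE,
                    class.weights = c(rna = 1.5 * sum(!pos) / sum(pos),
                                      background = 1))
  pred <- attr(predict(fit, z, decision.values = TRUE),
               "decision.values")
  sign <- if (identical(colnames(pred), "background/rna")) -1 else 1
  expect_equal(decisionValues(model, sorted), sign * as.numeric(pred),
               tolerance = 1e-8)
})

test_that("training and scoring are deterministic and scale-invariant", {
  igrs <- plantedClusterIgrs(seed = 9L)
  m1 <- trainClassifier(igrs)
  m2 <- trainClassifier(igrs)
  expect_identical(decisionValues(m1, igrs), decisionValues(m2, igrs))
  ## multiplying all lengths by 10 changes no selection decision
  df <- as.data.frame(igrs)
  scaled <- makeFeatureIgrs(df$gc_percent, df$length * 10L,
                            labeled = lengths(rnaFamilies(igrs)) > 0)
  m10 <- trainClassifier(scaled)
  expect_identical(decisionValues(m10, scaled) > 0,
                   decisionValues(m1, igrs) > 0)
})

test_that("candidate selection excludes known-RNA IGRs and distant points", {
  igrs <- plantedClusterIgrs(seed = 13L)
  model <- trainClassifier(igrs)
  centroidGc <- mean(gcPercent(igrs)[lengths(rnaFamilies(igrs)) > 0])
  centroidLen <- round(mean(igrLength(igrs)[
    lengths(rnaFamilies(igrs)) > 0]))
  probes <- makeFeatureIgrs(c(centroidGc, centroidGc, 10),
                            c(centroidLen, centroidLen, 35L),
                            labeled = c(FALSE, TRUE, FALSE))
  sel <- selectCandidates(model, probes)
  s <- unname(isSelected(sel))
  expect_true(s[1])    # unlabeled IGR at the positive centroid
  expect_false(s[2])   # a known RNA there is never re-reported
  expect_false(s[3])   # short, AT-rich background point
  expect_identical(unname(decisionValue(sel)),
                   decisionValues(model, probes))
  expect_true(all(decisionValue(sel)[s] > 0))
})

test_that("the decision grid is consistent with pointwise scoring", {
  igrs <- plantedClusterIgrs(seed = 17L)
  model <- trainClassifier(igrs)
  g2 <- decisionGrid(model, c(30, 60), c(100, 300), resolution = 2L)
  expect_identical(dim(g2), c(2L, 2L))
  grid <- decisionGrid(model, c(30, 60), c(100, 300), resolution = 7L)
  gc <- attr(grid, "gc"); len <- attr(grid, "length")
  for (i in c(1L, 4L, 7L))
    for (j in c(2L, 6L))
      expect_equal(grid[i, j],
                   decisionValues(model, c(gc[i], len[j])))
  ## sign pattern reproduces selection of unlabeled IGRs on grid nodes;
  ## node coordinates are chosen so gc * len / 100 is integral and the
  ## synthetic IGRs realize the node features exactly
  exact <- decisionGrid(model, c(20, 70), c(100, 300), resolution = 11L)
  nodes <- expand.grid(gc = attr(exact, "gc"),
                       len = attr(exact, "length"))
  nodeIgrs <- makeFeatureIgrs(nodes$gc, as.integer(nodes$len))
  expect_equal(gcPercent(nodeIgrs), nodes$gc, ignore_attr = TRUE)
  sel <- selectCandidates(model, nodeIgrs)
  expect_identical(unname(isSelected(sel)), as.vector(exact) > 0)
})

test_that("JSON serialization preserves the decision function exactly", {
  igrs <- plantedClusterIgrs(seed = 21L)
  model <- trainClassifier(igrs, w = 2.0)
  path <- withr::local_tempfile(fileext = ".json")
  writeClassifierJSON(model, path)
  back <- readClassifierJSON(path)
  expect_equal(decisionValues(back, igrs), decisionValues(model, igrs),
               tolerance = 1e-12)
  expect_identical(back@nPositive, model@nPositive)
  expect_equal(back@center, model@center)
})

test_that("raising the positive weight does not shrink the selected region", {
  grid <- expand.grid(gc = seq(20, 70, by = 2.5),
                      len = seq(40, 400, by = 20))
  pts <- as.matrix(grid)
  violations <- 0L
  for (seed in 1:10) {
    igrs <- plantedClusterIgrs(seed = seed)
    nLow <- sum(decisionValues(trainClassifier(igrs, w = 1), pts) > 0)
    nHigh <- sum(decisionValues(trainClassifier(igrs, w = 2), pts) > 0)
    if (nHigh < nLow) violations <- violations + 1L
  }
  ## retraining an RBF-SVM is not formally monotone in w; demand the
  ## region grows in at least 9 of 10 replicates
  expect_lte(violations, 1L)
})
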