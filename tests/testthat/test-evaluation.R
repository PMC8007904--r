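test_that("metrics formulas match the definitions on canonical cases", {
  expect_equal(computeMetrics(c(tp = 10, tn = 40, fp = 0, fn = 0)),
               c(precision = 1, recall = 1, mcc = 1))
  expect_equal(computeMetrics(c(tp = 0, tn = 0, fp = 5, fn = 5))[["mcc"]], -1)
  expect_error(computeMetrics(c(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
  # degenerate margins fall back to 0
  expect_equal(computeMetrics(c(tp = 0, tn = 10, fp = 0, fn = 0)),
               c(precision = 0, recall = 0, mcc = 0))
})

test_that("MCC equals the Pearson correlation of the 0/1 label vectors", {
  set.seed(500)
  for (i in 1:500) {
    cm <- c(tp = rpois(1, 8), tn = rpois(1, 20),
            fp = rpois(1, 5), fn = rpois(1, 5))
    pred <- rep(c(1, 0, 1, 0), cm)
    act <- rep(c(1, 0, 0, 1), cm)
    if (length(unique(pred)) < 2 || length(unique(act)) < 2) next
    m <- computeMetrics(cm)
    expect_equal(m[["mcc"]], cor(pred, act), tolerance = 1e-12)
    expect_equal(m[["precision"]], cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]))
    expect_equal(m[["recall"]], cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]))
  }
})

test_that("inverting predictions flips the MCC sign", {
  set.seed(77)
  for (i in 1:50) {
    cm <- c(tp = rpois(1, 6) + 1, tn = rpois(1, 12) + 1,
            fp = rpois(1, 4) + 1, fn = rpois(1, 4) + 1)
    inv <- c(tp = cm[["fn"]], tn = cm[["fp"]],
             fp = cm[["tn"]], fn = cm[["tp"]])
    expect_equal(computeMetrics(cm)[["mcc"]], -computeMetrics(inv)[["mcc"]])
  }
})

test_that("snap sampling keeps all positives and the exact 1:4 negatives", {
  tab <- randomTable(n = 1200, seed = 2, posRate = 175 / 1200)
  nPos <- sum(intervalClasses(tab) == 1L)
  part <- snapSample(tab, ratio = 4, seed = 1)
  expect_equal(length(part$positives), nPos)
  expect_equal(length(part$negatives), 4L * nPos)
  expect_setequal(part$snap, c(part$positives, part$negatives))
  # partition conservation, stratified 80/20 with floor rounding
  expect_setequal(c(part$training, part$validation), part$snap)
  expect_length(intersect(part$training, part$validation), 0L)
  expect_equal(sum(intervalClasses(tab)[part$training] == 1L),
               floor(0.8 * nPos))
  expect_equal(sum(intervalClasses(tab)[part$training] == 0L),
               floor(0.8 * length(part$negatives)))
})

test_that("snap sampling exhausts scarce negatives with a warning", {
  tab <- randomTable(n = 30, seed = 3, posRate = 0.4)
  nPos <- sum(intervalClasses(tab) == 1L)
  expect_warning(part <- snapSample(tab, ratio = 4, seed = 1), "available")
  expect_equal(length(part$negatives), 30L - nPos)
  noPos <- randomTable(n = 30, seed = 3, posRate = 0)
  expect_error(snapSample(noPos, seed = 1), "no positive")
})

test_that("different seeds resample negatives but never positives", {
  tab <- randomTable(n = 800, seed = 4, posRate = 0.1)
  a <- snapSample(tab, seed = 1)
  b <- snapSample(tab, seed = 2)
  expect_identical(a$positives, b$positives)
  expect_false(identical(a$negatives, b$negatives))
  expect_identical(a$negatives, snapSample(tab, seed = 1)$negatives)
})

test_that("runOnce reports coherent metrics across the four subsets", {
  tab <- randomTable(n = 600, seed = 5, posRate = 0.15, perfect = TRUE)
  r <- runOnce(tab, seed = 3)
  expect_s3_class(r, "RunResult")
  expect_setequal(r$metrics$subset,
                  c("complete", "snap", "training", "validation"))
  # a perfectly predictive unit gives MCC 1 everywhere
  expect_equal(r$metrics$mcc, rep(1, 4))
  expect_equal(r$primaryGroup, "U2")
  # confusion totals match subset sizes
  expect_equal(sum(r$confusion$complete), length(tab))
  expect_equal(sum(r$confusion$snap), length(r$partition$snap))
})

test_that("class-independent codes give near-zero MCC", {
  tab <- randomTable(n = 4000, seed = 6, posRate = 0.05)
  r <- runOnce(tab, seed = 1)
  expect_lt(abs(r$metrics$mcc[r$metrics$subset == "complete"]), 0.1)
})

test_that("multi-seed aggregation yields zero SEM on deterministic metrics", {
  tab <- randomTable(n = 400, seed = 7, posRate = 0.2, perfect = TRUE)
  ms <- runMultiSeed(tab, nSeeds = 5, seed = 10)
  expect_equal(ms$summary$mcc_mean, rep(1, 4))
  expect_equal(ms$summary$mcc_sem, rep(0, 4))
  expect_length(ms$runs, 5L)
  # reproducible from the master seed
  ms2 <- runMultiSeed(tab, nSeeds = 5, seed = 10)
  expect_identical(ms$seeds, ms2$seeds)
})

test_that("few-seed and many-seed means agree on signal-free data", {
  tab <- randomTable(n = 1500, seed = 8, posRate = 0.1)
  m2 <- runMultiSeed(tab, nSeeds = 3, seed = 1)
  m10 <- runMultiSeed(tab, nSeeds = 10, seed = 2)
  i <- which(m10$summary$subset == "complete")
  sem <- sqrt(m2$summary$mcc_sem[i]^2 + m10$summary$mcc_sem[i]^2) + 1e-6
  expect_lt(abs(m2$summary$mcc_mean[i] - m10$summary$mcc_mean[i]), 3 * sem + 0.05)
})

test_that("cross-correlograms show the expected peaks", {
  tr <- sort(runif(200, 0, 100))
  auto <- crossCorrelogram(tr, tr, binMs = 1)
  expect_gte(auto$count[auto$lag_ms == 0.5 | auto$lag_ms == -0.5][1], 0)
  expect_gte(sum(auto$count[abs(auto$lag_ms) < 1]), length(tr))
  shifted <- crossCorrelogram(tr, tr + 0.005, binMs = 1)
  expect_equal(shifted$lag_ms[which.max(shifted$count)], 5.5, tolerance = 1)
  expect_warning(empty <- crossCorrelogram(numeric(0), tr), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("independent Poisson trains give a flat correlogram", {
  set.seed(9)
  a <- sort(runif(400, 0, 200))
  b <- sort(runif(400, 0, 200))
  h <- crossCorrelogram(a, b, binMs = 1, windowMs = 50)
  expect_true(max(h$count) <= mean(h$count) + 4 * sqrt(mean(h$count)))
})
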