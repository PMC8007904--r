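test_that("a perfect predictor yields a one-split tree with importance 100", {
  tab <- randomTable(n = 120, p = 3, seed = 1, perfect = TRUE)
  m <- fitTree(tab)
  expect_equal(sum(m@trees[[1]]$is_leaf == 0L), 1L)   # one internal node
  imp <- variableImportance(m)
  expect_equal(unname(imp["U2"]), 100)
  expect_equal(unname(imp[c("U3", "U4")]), c(0, 0))
  expect_equal(primaryGroup(m), "U2")
  expect_equal(predict(m, tab), intervalClasses(tab))
})

test_that("a tiny separable table is fit with zero training error", {
  tab <- new("IntervalTable", timestamps = (1:4) * 0.05,
             codes = matrix(c("A", "0", "A", "0"), 4, 1,
                            dimnames = list(NULL, "U2")),
             fired = c(1L, 0L, 1L, 0L), units = "U2", target = "U1",
             window = 50, bin = 10)
  m <- fitTree(tab)
  expect_equal(predict(m, tab), c(1L, 0L, 1L, 0L))
})

test_that("the chosen root has maximal gain ratio among admissible attributes", {
  # exhaustive oracle over random 8-row, 2-attribute tables
  set.seed(11)
  checked <- 0
  for (i in 1:60) {
    codes <- matrix(sample(c("0", "A", "B"), 16, replace = TRUE), 8, 2,
                    dimnames = list(NULL, c("U2", "U3")))
    fired <- sample(c(0L, 1L), 8, replace = TRUE)
    if (length(unique(fired)) < 2) next
    tab <- new("IntervalTable", timestamps = (1:8) * 0.05, codes = codes,
               fired = fired, units = c("U2", "U3"), target = "U1",
               window = 50, bin = 10)
    m <- suppressWarnings(fitTree(tab))
    tr <- m@trees[[1]]
    if (all(tr$is_leaf == 1L)) next
    rootAttr <- m@attributes[tr$attr[1]]
    # oracle: valid candidates need >= 2 categories with >= 2 cases and
    # positive gain; admissible ones reach the mean gain; root maximizes
    # the gain ratio among them (ties toward earlier columns)
    stats <- lapply(1:2, function(j) oracleGainRatio(codes[, j], fired))
    valid <- vapply(1:2, function(j) {
      cnt <- table(codes[, j])
      sum(cnt >= 2) >= 2 && length(cnt) >= 2 && stats[[j]]["gain"] > 1e-12
    }, logical(1))
    gains <- vapply(stats, `[`, numeric(1), "gain")
    ratios <- vapply(stats, `[`, numeric(1), "ratio")
    adm <- valid & gains >= mean(gains[valid]) - 1e-9
    best <- which(adm)[which.max(ratios[adm])]
    expect_equal(rootAttr, c("U2", "U3")[best])
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("leaf classes minimise expected cost under the cost matrix", {
  # 2 positives vs 5 negatives and no informative attribute: predicting 0
  # costs 2 * 3.5 = 7, predicting 1 costs 5 * 1 = 5, so the leaf says 1
  tab <- new("IntervalTable", timestamps = (1:7) * 0.05,
             codes = matrix("0", 7, 1, dimnames = list(NULL, "U2")),
             fired = c(1L, 1L, 0L, 0L, 0L, 0L, 0L), units = "U2",
             target = "U1", window = 50, bin = 10)
  m <- fitTree(tab, costs = costMatrix(3.5, 1))
  expect_equal(unique(predict(m, tab)), 1L)
  # with symmetric costs the same leaf says 0
  m0 <- fitTree(tab, costs = costMatrix(1, 1))
  expect_equal(unique(predict(m0, tab)), 0L)
})

test_that("usage importance equals the case fraction routed through each split", {
  # root splits U2 (all 100 cases); only the 40-case U2=A branch needs U3,
  # whose codes are balanced and uninformative inside the pure U2=0 branch
  codes <- cbind(U2 = c(rep("0", 60), rep("A", 40)),
                 U3 = c(rep(c("A", "B"), 30), rep("A", 20), rep("B", 20)))
  fired <- c(rep(0L, 60), rep(1L, 20), rep(0L, 20))
  tab <- new("IntervalTable", timestamps = (1:100) * 0.05, codes = codes,
             fired = fired, units = c("U2", "U3"), target = "U1",
             window = 50, bin = 10)
  m <- fitTree(tab)
  imp <- variableImportance(m)
  expect_equal(unname(imp["U2"]), 100)
  expect_equal(unname(imp["U3"]), 40)
  # oracle: route every case through the tree and count encounters
  rules <- extractRules(m)
  expect_equal(predict(m, tab), fired)
})

test_that("single-class input gives a degenerate single-leaf model with warning", {
  tab <- randomTable(n = 30, seed = 3, posRate = 0)
  expect_warning(m <- fitTree(tab), "single-class")
  expect_true(all(m@trees[[1]]$is_leaf == 1L))
  expect_equal(primaryGroup(m), character(0))
  expect_equal(unique(predict(m, tab)), 0L)
  rules <- extractRules(m)
  expect_equal(nrow(rules), 1L)
  expect_equal(rules$rule, "TRUE")
})

test_that("rule extraction reproduces predictions exactly", {
  tab <- randomTable(n = 300, p = 3, seed = 5, posRate = 0.4)
  # plant some structure so the tree is non-trivial
  tab@codes[tab@fired == 1L, 2][1:60] <- "A"
  m <- fitTree(tab)
  rules <- extractRules(m)
  expect_gt(nrow(rules), 1L)
  set.seed(99)
  newCodes <- matrix(sample(c("0", "A", "B", "C", "AB", "BBD"), 3000,
                            replace = TRUE), 1000, 3,
                     dimnames = list(NULL, unitIds(tab)))
  got <- applyRules(rules, newCodes)
  pred <- as.integer(predict(m, newCodes))
  # rules are exact wherever a path matches; rows with categories unseen at
  # some node fall back inside predict() and match no rule
  expect_gt(mean(!is.na(got)), 0.5)
  expect_equal(got[!is.na(got)], pred[!is.na(got)])
  # on the training rows every path matches
  expect_equal(applyRules(rules, tab), as.integer(predict(m, tab)))
  expect_equal(sum(rules$coverage), length(tab))
})

test_that("rule extraction refuses boosted committees", {
  tab <- randomTable(n = 300, seed = 6, posRate = 0.4)
  tab@codes[tab@fired == 1L, 1][1:40] <- "A"   # partial signal, nonzero error
  m <- fitTree(tab, config = fitConfig(trials = 5))
  expect_gt(length(m@trees), 1L)
  expect_error(extractRules(m), "single-tree")
})

test_that("unseen categories route through fallback branches without error", {
  tab <- randomTable(n = 200, seed = 7, perfect = TRUE)
  m <- fitTree(tab)
  newCodes <- matrix("ZZZ-unseen", 5, 3,
                     dimnames = list(NULL, unitIds(tab)))
  p <- predict(m, newCodes)
  expect_true(all(p %in% c(0L, 1L)))
  expect_error(predict(m, newCodes[, 1:2, drop = FALSE]), "U4")
})

test_that("fitting is deterministic and a trials=1 committee equals its tree", {
  tab <- randomTable(n = 250, seed = 8, posRate = 0.35)
  m1 <- fitTree(tab)
  m2 <- fitTree(tab)
  expect_identical(m1@trees, m2@trees)
  expect_length(m1@trees, 1L)
  tr <- m1@trees[[1]]
  lev <- m1@levels
  x <- connectree:::.encodeMatrix(intervalCodes(tab), lev)
  raw <- connectree:::cpp_predict_tree(x, tr$is_leaf, tr$attr, tr$cls,
                                       tr$fallback, tr$branch_node,
                                       tr$branch_level, tr$branch_child)
  expect_equal(as.integer(predict(m1, tab)), as.integer(raw))
})

test_that("pruning never increases the leaf count", {
  for (seed in c(2, 4, 6)) {
    tab <- randomTable(n = 400, p = 4, seed = seed, posRate = 0.3)
    codes <- intervalCodes(tab)
    lev <- connectree:::.codeLevels(codes)
    x <- connectree:::.encodeMatrix(codes, lev)
    nlev <- vapply(lev, length, integer(1))
    y <- intervalClasses(tab)
    w <- rep(1, length(y))
    pruned <- connectree:::cpp_fit_tree(x, y, w, nlev, 3.5, 1, 2L, 0.25,
                                        TRUE, FALSE)
    grown <- connectree:::cpp_fit_tree(x, y, w, nlev, 3.5, 1, 2L, 0.25,
                                       FALSE, FALSE)
    expect_lte(sum(pruned$is_leaf), sum(grown$is_leaf))
  }
})

test_that("raising the false-negative cost weakly increases training recall", {
  set.seed(21)
  tab <- randomTable(n = 400, p = 3, seed = 13, posRate = 0.3)
  tab@codes[tab@fired == 1L, 1][1:40] <- "A"   # partial signal
  recalls <- vapply(c(1, 2, 3.5, 6, 10), function(fn) {
    m <- fitTree(tab, costs = costMatrix(fn, 1))
    cm <- confusionMatrix(predict(m, tab), intervalClasses(tab))
    computeMetrics(cm)[["recall"]]
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-9))
})

test_that("models serialize to JSON and back without changing predictions", {
  tab <- randomTable(n = 150, p = 3, seed = 9, posRate = 0.4)
  tab@codes[tab@fired == 1L, 1][1:30] <- "A"
  m <- fitTree(tab)
  f <- tempfile(fileext = ".json")
  writeTreeModel(m, f)
  back <- readTreeModel(f)
  expect_equal(back@attributes, m@attributes)
  expect_equal(back@importance, m@importance)
  expect_equal(predict(back, tab), predict(m, tab))
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), bad)
  expect_error(readTreeModel(bad), "not a connectree")
})
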