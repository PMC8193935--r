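cFac <- function(n) {
    if (n > 2) 2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
    else if (n == 2) 1 else 0
}

test_that("trees use all rows when the table is smaller than psi", {
    tab <- makeToyTable(n = 10, p = 3, seed = 1)
    forest <- fitIsolationForest(tab, psi = 256, nTrees = 20, seed = 2)
    expect_true(all(vapply(forest@trees, function(tr) tr$size[1],
                           numeric(1)) == 10))
    expect_equal(forest@cn, cFac(10))
})

test_that("fitting is deterministic given the seed and rejects bad input", {
    tab <- makeToyTable(n = 40, p = 4, seed = 3)
    f1 <- fitIsolationForest(tab, psi = 16, nTrees = 15, seed = 7)
    f2 <- fitIsolationForest(tab, psi = 16, nTrees = 15, seed = 7)
    expect_identical(f1@trees, f2@trees)
    expect_identical(scoreOutliers(f1, tab), scoreOutliers(f2, tab))
    expect_error(fitIsolationForest(tab, psi = 1), "psi")
    expect_error(fitIsolationForest(tab[, integer(0)], psi = 8), "empty")
})

test_that("scores lie in (0, 1] and identical points score identically", {
    tab <- makeToyTable(n = 60, p = 3, seed = 4)
    m <- featureMatrix(tab)
    m[2, ] <- m[1, ]  # twin of row 1
    twin <- BrainFeatureSet(m, subjectIds(tab), genders(tab), ages(tab),
                            groups(tab), cohorts(tab))
    forest <- fitIsolationForest(twin, psi = 32, nTrees = 40, seed = 5)
    s <- scoreOutliers(forest, twin)
    expect_true(all(s > 0 & s <= 1))
    expect_equal(unname(s[1]), unname(s[2]), tolerance = 1e-15)
})

test_that("a gross outlier receives the maximum anomaly score", {
    set.seed(6)
    m <- matrix(rnorm(801 * 5), 801, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    m[801, ] <- 20
    tab <- BrainFeatureSet(m, sprintf("s%03d", 1:801), "F",
                           rep(70, 801), rep_len(c("AD", "CN"), 801), "X")
    forest <- fitIsolationForest(tab, psi = 256, nTrees = 100, seed = 8)
    s <- scoreOutliers(forest, tab)
    expect_equal(unname(which.max(s)), 801)
})

test_that("path lengths and scores match a hand-traced tree", {
    # 1-D tree: root splits at 0.5; left leaf holds 2 points; right child
    # splits at 1.5 into two singletons
    tree <- data.frame(feature = c(1L, NA, 1L, NA, NA),
                       value = c(0.5, NA, 1.5, NA, NA),
                       left = c(2L, NA, 4L, NA, NA),
                       right = c(3L, NA, 5L, NA, NA),
                       size = c(4L, 2L, 2L, 1L, 1L))
    forest <- new("IsolationForest", trees = list(tree), psi = 4L,
                  heightLimit = 8L, nTrees = 1L, cn = cFac(4),
                  featureNames = "f1", cutoff = numeric(0))
    pts <- matrix(c(0, 0.2, 1, 2), 4, 1, dimnames = list(NULL, "f1"))
    tab <- BrainFeatureSet(pts, c("a", "b", "c", "d"), "M", rep(70, 4),
                           rep_len(c("AD", "CN"), 4), "X")
    s <- scoreOutliers(forest, tab)
    # hand trace: points a,b end in the 2-point leaf at depth 1
    # (h = 1 + c(2) = 2); points c,d are singletons at depth 2 (h = 2)
    expect_equal(unname(s), 2^(-c(2, 2, 2, 2) / cFac(4)), tolerance = 1e-15)
    # and a point beyond the right split still lands in a singleton: h = 2
    expect_equal(unname(s["d"]), 2^(-2 / cFac(4)), tolerance = 1e-15)
})

test_that("Tukey cutoff is Q3 + 3*IQR under the interpolation convention", {
    expect_equal(tukeyCutoff(c(0.4, 0.4, 0.6, 0.6)), 1.2)
    expect_equal(tukeyCutoff(rep(0.37, 10)), 0.37)
    expect_error(tukeyCutoff(c(1, 2, 3)), "at least 4")

    set.seed(10)
    s <- runif(20)
    q1 <- interpQuantile(s, 0.25)
    q3 <- interpQuantile(s, 0.75)
    expect_equal(tukeyCutoff(s), q3 + 3 * (q3 - q1), tolerance = 1e-12)
})

test_that("filterOutliers removes only strictly-above-cutoff rows", {
    tab <- makeToyTable(n = 6, p = 2, seed = 11)
    scores <- c(0.1, 0.5, 0.5, 0.4, 0.9, 0.2)
    parts <- filterOutliers(tab, scores, 0.5)
    expect_identical(subjectIds(parts$removed), subjectIds(tab)[5])
    expect_setequal(c(subjectIds(parts$kept), subjectIds(parts$removed)),
                    subjectIds(tab))
    none <- filterOutliers(tab, scores, 1)
    expect_equal(ncol(none$removed), 0)
    expect_error(filterOutliers(tab, scores[-1], 0.5), "length")
})

test_that("planted outliers are recalled on the contamination fixture", {
    gen <- generateCohort(contaminationConfig(seed = 12))
    z <- applyStandardizer(fitStandardizer(gen$table), gen$table)
    forest <- fitIsolationForest(z, psi = 128, nTrees = 50, seed = 13)
    forest <- calibrateCutoff(forest, z)
    flagged <- subjectIds(z)[scoreOutliers(forest, z) > forest@cutoff]
    expect_gte(length(intersect(flagged, gen$truth$outliers)), 18)
})

test_that("the fitted model is untouched by scoring test data", {
    train <- makeToyTable(n = 50, p = 3, seed = 14)
    test <- makeToyTable(n = 20, p = 3, seed = 15)
    forest <- calibrateCutoff(fitIsolationForest(train, psi = 32,
                                                 nTrees = 25, seed = 16),
                              train)
    snapshot <- forest
    invisible(scoreOutliers(forest, test))
    expect_identical(forest, snapshot)
})

test_that("scores increase as a point moves away from the bulk", {
    set.seed(17)
    base <- matrix(rnorm(200 * 3), 200, 3,
                   dimnames = list(NULL, paste0("f", 1:3)))
    offsets <- c(2, 4, 8, 16)
    meanScores <- sapply(seq_len(10), function(sd_i) {
        sapply(offsets, function(k) {
            m <- rbind(base, rep(k, 3))
            tab <- BrainFeatureSet(m, sprintf("s%03d", seq_len(201)), "M",
                                   rep(70, 201), rep_len(c("AD", "CN"), 201),
                                   "X")
            forest <- fitIsolationForest(tab, psi = 64, nTrees = 30,
                                         seed = 100 + sd_i)
            unname(scoreOutliers(forest, tab)[201])
        })
    })
    trend <- rowMeans(meanScores)
    expect_true(all(diff(trend) >= 0))
})

test_that("score distribution on clean data is right-skewed", {
    gen <- generateCohort(smallConfig(seed = 18, nAD = 150, nCN = 350))
    z <- applyStandardizer(fitStandardizer(gen$table), gen$table)
    forest <- fitIsolationForest(z, psi = 128, nTrees = 50, seed = 19)
    s <- scoreOutliers(forest, z)
    skew <- mean((s - mean(s))^3) / sd(s)^3
    expect_gt(skew, 0)
})
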