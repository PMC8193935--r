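test_that("metrics reproduce the published worked example and definitions", {
    m <- computeMetrics(TP = 30, TN = 104, FP = 3, FN = 4)
    expect_equal(round(m$accuracy, 2), 95.04)
    expect_equal(m$recall, 100 * 30 / 34, tolerance = 1e-12)
    expect_equal(m$precision, 100 * 30 / 33, tolerance = 1e-12)
    # named-vector form
    m2 <- computeMetrics(c(TP = 30, TN = 104, FP = 3, FN = 4))
    expect_equal(m2, m)

    w <- capture_warnings(m3 <- computeMetrics(TP = 0, TN = 50, FP = 0,
                                               FN = 0))
    expect_match(w, "recall undefined", all = FALSE)
    expect_match(w, "precision undefined", all = FALSE)
    expect_equal(m3$accuracy, 100)
    expect_true(is.nan(m3$recall))
    expect_error(computeMetrics(TP = -1, TN = 1, FP = 1, FN = 1),
                 "negative")

    set.seed(1)
    for (i in 1:5) {
        cc <- sample(1:50, 4)
        m4 <- computeMetrics(TP = cc[1], TN = cc[2], FP = cc[3], FN = cc[4])
        expect_equal(m4$accuracy, 100 * (cc[1] + cc[2]) / sum(cc))
        expect_equal(m4$recall, 100 * cc[1] / (cc[1] + cc[4]))
        expect_equal(m4$precision, 100 * cc[1] / (cc[1] + cc[3]))
    }
})

test_that("fold accuracy tracks the planted effect size", {
    # zero effect: accuracy near the majority rate
    genNull <- generateCohort(smallConfig(seed = 2, acceleration = 0,
                                          nAD = 120, nCN = 280))
    isTest <- rep_len(c(TRUE, FALSE, FALSE, FALSE), 400)
    frNull <- runFold(genNull$table[, !isTest], genNull$table[, isTest],
                      fastCfg(seed = 3))
    expect_lt(frNull$metrics$accuracy, 85)
    expect_gt(frNull$metrics$accuracy, 50)

    # huge effect: near-perfect accuracy
    cfgBig <- smallConfig(seed = 4, acceleration = 40, nAD = 120, nCN = 280)
    genBig <- generateCohort(cfgBig)
    # a 40-year planted shift can separate the classes perfectly, in which
    # case the classifier legitimately warns and falls back to ridge
    frBig <- suppressWarnings(
        runFold(genBig$table[, !isTest], genBig$table[, isTest],
                fastCfg(seed = 5)))
    expect_gte(frBig$metrics$accuracy, 95)

    # structural contracts
    expect_true(all(frBig$support %in% frBig$selected))
    expect_true(all(frBig$selected %in% featureNames(genBig$table)))
    cc <- frBig$confusion
    expect_equal(sum(cc), sum(!frBig$predictions$flagged))
    expect_error(runFold(genBig$table, genBig$table[, isTest]), "overlap")
})

test_that("fitted fold models ignore every aspect of the test partition", {
    gen <- generateCohort(smallConfig(seed = 6))
    isTest <- rep_len(c(TRUE, FALSE, FALSE), 300)
    train <- gen$table[, !isTest]
    test <- gen$table[, isTest]
    cfg <- fastCfg(seed = 7)
    fr1 <- runFold(train, test, cfg)

    # perturb test features, ages and labels
    m <- featureMatrix(test) * 3 + 11
    test2 <- BrainFeatureSet(m, subjectIds(test), genders(test),
                             ages(test) + 5,
                             ifelse(groups(test) == "AD", "CN", "AD"),
                             cohorts(test))
    fr2 <- runFold(train, test2, cfg)
    expect_identical(fr1$models, fr2$models)
    expect_identical(fr1$selected, fr2$selected)
    expect_identical(fr1$removedTrain, fr2$removedTrain)
})

test_that("repeated CV is deterministic and partitions subjects per repeat", {
    gen <- generateCohort(smallConfig(seed = 8, nAD = 60, nCN = 140,
                                      nNoise = 6))
    cfg <- fastCfg(seed = 9)
    cv1 <- repeatedCV(gen$table, folds = 4, repeats = 2, cfg)
    cv2 <- repeatedCV(gen$table, folds = 4, repeats = 2, cfg)
    expect_identical(cv1$perRepeat, cv2$perRepeat)
    expect_identical(cv1$selections, cv2$selections)

    # each subject appears in exactly one test fold per repeat
    for (r in 1:2) {
        p <- cv1$predictions[cv1$predictions$rep == r, ]
        expect_setequal(p$subject_id, subjectIds(gen$table))
        expect_equal(anyDuplicated(p$subject_id), 0)
    }
    expect_equal(cv1$nFoldsTotal, 8)
    expect_equal(nrow(cv1$perRepeat), 2)
    tiny <- gen$table[, c(which(groups(gen$table) == "AD")[1:5],
                          which(groups(gen$table) == "CN")[1:5])]
    expect_error(repeatedCV(tiny, folds = 8, repeats = 1, cfg),
                 "fewer members")
})

test_that("holdout splits are stratified and produce explainability output", {
    labels <- rep(c("AD", "CN"), each = 5)
    isTrain <- ApparentAge:::stratifiedHoldoutIdx(labels, 0.5, seed = 10)
    expect_equal(sum(isTrain), 5)
    expect_true(sum(isTrain[labels == "AD"]) %in% 2:3)
    expect_true(sum(isTrain[labels == "CN"]) %in% 2:3)

    gen <- generateCohort(smallConfig(seed = 11))
    h <- holdout(gen$table, trainFrac = 0.8, cfg = fastCfg(seed = 12))
    expect_equal(length(h$trainIds), 240)
    expect_equal(nrow(h$fold$predictions), 60)
    expect_false(any(h$fold$predictions$subject_id %in% h$trainIds))
    # quartile context from training rows only, both groups present
    expect_setequal(unique(h$context$group), c("AD", "CN"))
    expect_setequal(unique(h$context$feature), h$fold$support)
    # every evaluated test subject has a report consistent with predict()
    for (rep in h$testReports)
        expect_identical(scoreDecision(rep), rep@decision)
})

test_that("cross-cohort splits train and test on the requested cohorts", {
    gen <- generateCohort(smallConfig(seed = 13))
    fr <- crossCohort(gen$table, "synthA", "synthB", fastCfg(seed = 14))
    idsB <- subjectIds(gen$table)[cohorts(gen$table) == "synthB"]
    expect_setequal(fr$predictions$subject_id, idsB)
    expect_gt(fr$metrics$accuracy, 70)
    expect_error(crossCohort(gen$table, "synthA", "synthA", fastCfg()),
                 "overlap")
    expect_error(crossCohort(gen$table, "synthA", "nosuch", fastCfg()),
                 "absent")
})

test_that("selection frequencies aggregate folds and hemispheres", {
    cv <- list(selections = list(c("LH_Hippo", "RH_Hippo"),
                                 c("LH_Hippo", "LH_Ent"),
                                 c("LH_Hippo", "LH_Ent"),
                                 "LH_Hippo"),
               nFoldsTotal = 4)
    rep <- selectionFrequencyReport(cv)
    bf <- rep$byFeature
    expect_equal(bf$pct[bf$feature == "LH_Hippo"], 100)
    expect_equal(bf$pct[bf$feature == "LH_Ent"], 50)
    expect_false("RH_Ent" %in% bf$feature)  # never selected: omitted
    br <- rep$byRoi
    expect_equal(br$pctEither[br$roi == "Hippo"], 100)
    expect_equal(br$pctRH[br$roi == "Hippo"], 25)
    expect_equal(br$pctEither[br$roi == "Ent"], 50)
})

test_that("the final model serializes to JSON and round-trips bit-exactly", {
    gen <- generateCohort(smallConfig(seed = 15, nNoise = 5))
    pipe <- fitFinalModel(gen$table, fastCfg(seed = 16))
    preds <- predictPipeline(pipe, gen$table)
    expect_equal(nrow(preds), 300)
    expect_true(all(preds$label %in% c("AD", "CN")))

    path <- withr::local_tempfile(fileext = ".json")
    writeModelJSON(pipe, path)
    pipe2 <- readModelJSON(path)
    preds2 <- predictPipeline(pipe2, gen$table)
    expect_identical(preds$aba, preds2$aba)
    expect_identical(preds$probability, preds2$probability)
    expect_identical(preds$label, preds2$label)
    expect_identical(preds$flagged, preds2$flagged)

    # final-model F1 overlaps the informative truth
    expect_gt(length(intersect(pipe$aba@offered, gen$truth$informative)), 0)

    # individual model serialization round-trips
    for (obj in list(pipe$standardizer, pipe$aba, pipe$classifier,
                     pipe$forest, pipe$selection)) {
        writeModelJSON(obj, path)
        expect_equal(readModelJSON(path), obj)
    }
})
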