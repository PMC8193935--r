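# Leakage-safe pipeline orchestration: per-fold execution (standardize ->
# outlier-filter -> rank -> FFS -> CN-only LASSO -> logistic), repeated
# stratified cross-validation, holdout, cross-cohort validation and the
# final deployment model. Every stage is fitted on training rows only and
# applied unchanged to the test rows.

#' Pipeline configuration
#'
#' @param method "M6" (full pipeline with biased forward feature selection)
#'   or "M5" (no wrapper: the LASSO is offered all features). The M4 variant
#'   of the study design is M5 run on a restricted training cohort; use
#'   [crossCohort()] or subset the table by cohort.
#' @param outlier list: enabled, psi, heightLimit, nTrees, excludeTest
#'   (flagged test records are excluded from metrics and listed separately).
#' @param ffs list: innerFolds, epsilon, topK, penalty (fixed LASSO penalty
#'   used inside the wrapper).
#' @param abaPenalty "auto" (cross-validated MAE) or a fixed penalty for the
#'   per-fold ABA model.
#' @param abaCvFolds folds for the "auto" penalty search.
#' @param keepModels keep every fold's fitted sub-models in the result
#'   (needed for leakage audits; off by default to save memory).
#' @param seed master integer seed; all per-stage randomness is derived from
#'   it deterministically.
#' @return a config list.
#' @export
pipelineConfig <- function(method = "M6",
                           outlier = list(enabled = TRUE, psi = 256,
                                          heightLimit = 8, nTrees = 100,
                                          excludeTest = TRUE),
                           ffs = list(innerFolds = 5, epsilon = NULL,
                                      topK = Inf, penalty = 0.1),
                           abaPenalty = "auto", abaCvFolds = 5,
                           keepModels = FALSE, seed = 1) {
    stopifnot(method %in% c("M5", "M6"))
    defO <- list(enabled = TRUE, psi = 256, heightLimit = 8, nTrees = 100,
                 excludeTest = TRUE)
    defF <- list(innerFolds = 5, epsilon = NULL, topK = Inf, penalty = 0.1)
    outlier <- utils::modifyList(defO, outlier)
    ffs <- utils::modifyList(defF, ffs)
    list(method = method, outlier = outlier, ffs = ffs,
         abaPenalty = abaPenalty, abaCvFolds = abaCvFolds,
         keepModels = keepModels, seed = as.integer(seed))
}

confusionCounts <- function(predicted, truth) {
    c(TP = sum(predicted == "AD" & truth == "AD"),
      TN = sum(predicted == "CN" & truth == "CN"),
      FP = sum(predicted == "AD" & truth == "CN"),
      FN = sum(predicted == "CN" & truth == "AD"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, AD recall (sensitivity) and AD precision, in percent, with AD
#' as the positive class. Undefined ratios (zero denominators) are returned
#' as NaN with a warning.
#'
#' @param TP,TN,FP,FN confusion counts; alternatively pass a named vector as
#'   \code{TP}.
#' @return list with elements accuracy, recall, precision (percent).
#' @export
computeMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
    if (length(TP) == 4 && !is.null(names(TP))) {
        cc <- TP
        TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
    }
    counts <- c(TP, TN, FP, FN)
    if (any(counts < 0)) stop("negative confusion counts")
    total <- sum(counts)
    if (total == 0) stop("empty confusion matrix")
    acc <- 100 * (TP + TN) / total
    if (TP + FN == 0) {
        warning("no AD subjects: recall undefined")
        rec <- NaN
    } else rec <- 100 * TP / (TP + FN)
    if (TP + FP == 0) {
        warning("no AD predictions: precision undefined")
        prec <- NaN
    } else prec <- 100 * TP / (TP + FP)
    list(accuracy = acc, recall = rec, precision = prec)
}

#' Run one train/test fold of the full pipeline
#'
#' Executes, with every model fitted on the training partition only:
#' z-score standardization; isolation-forest outlier scoring with the Tukey
#' cutoff (fitted on training scores, applied to both partitions);
#' point-biserial ranking and biased forward feature selection (method
#' "M6"); the CN-only LASSO Apparent Brain Age regression; and the logistic
#' classifier on (age, ABA). Flagged test records are excluded from the
#' confusion counts by default and listed separately.
#'
#' @param train,test disjoint [BrainFeatureSet-class] partitions.
#' @param cfg a [pipelineConfig()] list.
#' @return a FoldResult list: \code{predictions} (per test subject:
#'   subject_id, group, age, aba, ads, label, probability, flagged),
#'   \code{confusion}, \code{metrics}, \code{regression} (per-group MAE/r on
#'   evaluated test rows), \code{selected} (F1), \code{support} (F2),
#'   \code{models} (fitted sub-models), \code{removedTrain} and
#'   \code{flaggedTest} subject ids.
#' @export
runFold <- function(train, test, cfg = pipelineConfig()) {
    if (length(intersect(subjectIds(train), subjectIds(test))) > 0)
        stop("train and test partitions overlap")
    std <- fitStandardizer(train)
    trainZ <- applyStandardizer(std, train)
    testZ <- applyStandardizer(std, test)
    removedTrain <- character(0)
    flaggedTest <- character(0)
    forest <- NULL
    if (isTRUE(cfg$outlier$enabled)) {
        forest <- fitIsolationForest(trainZ, psi = cfg$outlier$psi,
                                     heightLimit = cfg$outlier$heightLimit,
                                     nTrees = cfg$outlier$nTrees,
                                     seed = childSeed(cfg$seed, 11))
        forest <- calibrateCutoff(forest, trainZ)
        trainScores <- scoreOutliers(forest, trainZ)
        parts <- filterOutliers(trainZ, trainScores, forest@cutoff)
        removedTrain <- subjectIds(parts$removed)
        trainZ <- parts$kept
        testScores <- scoreOutliers(forest, testZ)
        flaggedTest <- subjectIds(testZ)[testScores > forest@cutoff]
    }
    ranking <- rankFeatures(trainZ)
    sel <- NULL
    if (cfg$method == "M6") {
        sel <- forwardSelect(trainZ, ranking,
                             innerFolds = cfg$ffs$innerFolds,
                             epsilon = cfg$ffs$epsilon, topK = cfg$ffs$topK,
                             penalty = cfg$ffs$penalty,
                             seed = childSeed(cfg$seed, 12))
        f1 <- selected(sel)
    } else {
        f1 <- featureNames(trainZ)
    }
    cn <- subsetSubjects(trainZ, groups(trainZ) == "CN")
    aba <- fitAba(cn, offered = f1, penalty = cfg$abaPenalty,
                  cvFolds = cfg$abaCvFolds, seed = childSeed(cfg$seed, 13))
    trainPreds <- predictAba(aba, trainZ)
    clf <- fitClassifier(trainPreds)
    testPreds <- predictAba(aba, testZ)
    dec <- predictDiagnosis(clf, testPreds$age, testPreds$aba)
    preds <- cbind(testPreds,
                   label = dec$label, probability = dec$probability,
                   flagged = testPreds$subject_id %in% flaggedTest)
    evaluated <- if (isTRUE(cfg$outlier$excludeTest)) !preds$flagged
                 else rep(TRUE, nrow(preds))
    cc <- confusionCounts(preds$label[evaluated], preds$group[evaluated])
    reg <- lapply(c(CN = "CN", AD = "AD"), function(grp) {
        p <- preds[evaluated & preds$group == grp, , drop = FALSE]
        if (nrow(p) < 2) return(list(mae = NA_real_, r = NA_real_))
        regressionMetrics(p, grp)
    })
    metrics <- if (sum(cc) > 0) suppressWarnings(computeMetrics(cc))
               else list(accuracy = NaN, recall = NaN, precision = NaN)
    models <- list(standardizer = std, forest = forest, ranking = ranking,
                   selection = sel, aba = aba, classifier = clf)
    list(predictions = preds, confusion = cc,
         metrics = metrics,
         regression = reg, selected = f1,
         support = names(aba@coefficients), models = models,
         removedTrain = removedTrain, flaggedTest = flaggedTest)
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat, subjects are assigned to stratified folds (stratification by
#' diagnosis label); each fold runs the full leakage-safe pipeline via
#' [runFold()]. Test predictions are pooled within a repeat to form one
#' confusion matrix and one set of regression metrics; means and SDs are
#' then taken across repeats. Selection counts over all folds of all repeats
#' feed [selectionFrequencyReport()].
#'
#' @param table a [BrainFeatureSet-class] (typically one gender group).
#' @param folds,repeats cross-validation geometry (the study design uses 10
#'   and 10).
#' @param cfg a [pipelineConfig()] list; \code{cfg$seed} drives the fold
#'   assignment and all per-fold randomness.
#' @return a CvResult list: \code{perRepeat} data.frame, \code{summary}
#'   (mean/sd of accuracy, recall, precision; pooled regression metrics),
#'   \code{selections} (list of F1 per fold), \code{nFoldsTotal},
#'   \code{predictions} (per-subject test predictions with rep/fold ids),
#'   \code{models} (per-fold sub-models when \code{cfg$keepModels}).
#' @export
repeatedCV <- function(table, folds = 10, repeats = 10,
                       cfg = pipelineConfig()) {
    g <- groups(table)
    if (length(unique(g)) != 2) stop("both classes must be present")
    perRepeat <- vector("list", repeats)
    allPreds <- vector("list", repeats)
    selections <- list()
    allModels <- list()
    for (r in seq_len(repeats)) {
        fold <- stratifiedFolds(g, folds, childSeed(cfg$seed, 7000 + r))
        predsList <- vector("list", folds)
        for (k in seq_len(folds)) {
            cfgFold <- cfg
            cfgFold$seed <- childSeed(cfg$seed, r * 100 + k)
            fr <- runFold(subsetSubjects(table, fold != k),
                          subsetSubjects(table, fold == k), cfgFold)
            p <- fr$predictions
            p$fold <- k
            p$rep <- r
            predsList[[k]] <- p
            selections[[length(selections) + 1]] <- fr$selected
            if (isTRUE(cfg$keepModels))
                allModels[[sprintf("r%d_f%d", r, k)]] <- fr$models
        }
        preds <- do.call(rbind, predsList)
        allPreds[[r]] <- preds
        ev <- if (isTRUE(cfg$outlier$excludeTest)) !preds$flagged
              else rep(TRUE, nrow(preds))
        cc <- confusionCounts(preds$label[ev], preds$group[ev])
        m <- if (sum(cc) > 0) suppressWarnings(computeMetrics(cc))
             else list(accuracy = NaN, recall = NaN, precision = NaN)
        reg <- lapply(c(CN = "CN", AD = "AD"), function(grp) {
            p <- preds[ev & preds$group == grp, , drop = FALSE]
            if (nrow(p) < 2) return(list(mae = NA_real_, r = NA_real_))
            regressionMetrics(p, grp)
        })
        perRepeat[[r]] <- data.frame(
            rep = r, accuracy = m$accuracy, recall = m$recall,
            precision = m$precision, maeCN = reg$CN$mae, maeAD = reg$AD$mae,
            rCN = reg$CN$r, rAD = reg$AD$r,
            nExcluded = sum(!ev))
    }
    pr <- do.call(rbind, perRepeat)
    summ <- list(
        accuracy = c(mean = mean(pr$accuracy), sd = sd(pr$accuracy)),
        recall = c(mean = mean(pr$recall), sd = sd(pr$recall)),
        precision = c(mean = mean(pr$precision), sd = sd(pr$precision)),
        maeCN = c(mean = mean(pr$maeCN), sd = sd(pr$maeCN)),
        maeAD = c(mean = mean(pr$maeAD), sd = sd(pr$maeAD)),
        rCN = c(mean = mean(pr$rCN), sd = sd(pr$rCN)),
        rAD = c(mean = mean(pr$rAD), sd = sd(pr$rAD)))
    out <- list(perRepeat = pr, summary = summ, selections = selections,
                nFoldsTotal = folds * repeats,
                predictions = do.call(rbind, allPreds))
    if (isTRUE(cfg$keepModels)) out$models <- allModels
    out
}

# per-class training sizes for a stratified holdout split
stratifiedHoldoutIdx <- function(labels, trainFrac, seed) {
    n <- length(labels)
    targetTotal <- round(n * trainFrac)
    classes <- unique(labels)
    nc <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    base <- floor(nc * trainFrac)
    rem <- targetTotal - sum(base)
    if (rem > 0) {
        frac <- nc * trainFrac - base
        base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1
    }
    withSeed(seed, {
        train <- logical(n)
        for (i in seq_along(classes)) {
            idx <- which(labels == classes[i])
            train[sample(idx, base[i])] <- TRUE
        }
        train
    })
}

#' Single stratified holdout evaluation with explainability reports
#'
#' Splits the table into stratified training and test partitions (the study
#' design uses 80-20%), runs [runFold()], and additionally computes the
#' per-subject feature-score reports for the evaluated test subjects
#' together with the AD/CN quartile context derived from the training
#' subjects only.
#'
#' @param table a [BrainFeatureSet-class].
#' @param trainFrac training fraction.
#' @param cfg a [pipelineConfig()] list.
#' @return list: \code{fold} (the [runFold()] result), \code{testReports}
#'   (list of [FeatureScoreReport-class]), \code{context} (training quartile
#'   table from [quartileContext()]), \code{trainIds}.
#' @export
holdout <- function(table, trainFrac = 0.8, cfg = pipelineConfig()) {
    g <- groups(table)
    if (length(unique(g)) != 2) stop("both classes must be present")
    isTrain <- stratifiedHoldoutIdx(g, trainFrac,
                                    childSeed(cfg$seed, 4242))
    train <- subsetSubjects(table, isTrain)
    test <- subsetSubjects(table, !isTrain)
    fr <- runFold(train, test, cfg)
    z <- applyStandardizer(fr$models$standardizer, table)
    keptTrainIds <- setdiff(subjectIds(train), fr$removedTrain)
    zTrain <- subsetSubjects(z, subjectIds(z) %in% keptTrainIds)
    trainReports <- featureScores(fr$models$classifier, fr$models$aba,
                                  zTrain)
    context <- quartileContext(trainReports, groups(zTrain))
    evalIds <- fr$predictions$subject_id[!fr$predictions$flagged]
    zTest <- subsetSubjects(z, subjectIds(z) %in% evalIds)
    testReports <- featureScores(fr$models$classifier, fr$models$aba, zTest)
    list(fold = fr, testReports = testReports, context = context,
         trainIds = subjectIds(train))
}

#' Train on one set of cohorts, test on another
#'
#' Runs the full pipeline with a cohort-defined split (e.g. train on ADNI,
#' test on AIBL). Mixed-gender evaluation is supported: the partitions are
#' taken as given.
#'
#' @param table a [BrainFeatureSet-class].
#' @param trainCohorts,testCohorts disjoint sets of cohort tags present in
#'   the table.
#' @param cfg a [pipelineConfig()] list.
#' @return a FoldResult list, as [runFold()].
#' @export
crossCohort <- function(table, trainCohorts, testCohorts,
                        cfg = pipelineConfig()) {
    if (length(intersect(trainCohorts, testCohorts)) > 0)
        stop("train and test cohort sets overlap")
    have <- unique(cohorts(table))
    missing_tags <- setdiff(c(trainCohorts, testCohorts), have)
    if (length(missing_tags) > 0)
        stop("cohort tag(s) absent from table: ",
             paste(missing_tags, collapse = ", "))
    train <- subsetSubjects(table, cohorts(table) %in% trainCohorts)
    test <- subsetSubjects(table, cohorts(table) %in% testCohorts)
    if (ncol(train) == 0 || ncol(test) == 0)
        stop("empty train or test side")
    runFold(train, test, cfg)
}

#' Selection-frequency table over all cross-validation folds
#'
#' For every feature that entered the wrapper subset F1 in at least one
#' fold, the percentage of folds (over all repeats) in which it was
#' selected. When feature names carry an LH_/RH_ hemisphere prefix, a
#' per-ROI summary is added: percentage of folds in which either hemisphere
#' of the ROI was selected, plus the per-hemisphere percentages.
#'
#' @param cv a [repeatedCV()] result (run with method "M6").
#' @return list: \code{byFeature} data.frame (feature, nSelected, pct),
#'   \code{byRoi} data.frame (roi, pctEither, pctLH, pctRH) or NULL when
#'   names encode no hemisphere.
#' @export
selectionFrequencyReport <- function(cv) {
    sels <- cv$selections
    if (length(sels) == 0) stop("no selections recorded; run with method M6")
    nf <- cv$nFoldsTotal
    counts <- table(unlist(sels))
    byFeature <- data.frame(feature = names(counts),
                            nSelected = as.integer(counts),
                            pct = 100 * as.integer(counts) / nf,
                            stringsAsFactors = FALSE)
    byFeature <- byFeature[order(-byFeature$pct, byFeature$feature), ]
    rownames(byFeature) <- NULL
    byRoi <- NULL
    if (all(grepl("^(LH|RH)_", byFeature$feature))) {
        stems <- unique(sub("^(LH|RH)_", "", byFeature$feature))
        byRoi <- do.call(rbind, lapply(stems, function(stem) {
            lh <- paste0("LH_", stem)
            rh <- paste0("RH_", stem)
            either <- vapply(sels, function(s) any(c(lh, rh) %in% s),
                             logical(1))
            data.frame(roi = stem,
                       pctEither = 100 * mean(either),
                       pctLH = 100 * mean(vapply(sels, function(s)
                           lh %in% s, logical(1))),
                       pctRH = 100 * mean(vapply(sels, function(s)
                           rh %in% s, logical(1))),
                       stringsAsFactors = FALSE)
        }))
        byRoi <- byRoi[order(-byRoi$pctEither, byRoi$roi), ]
        rownames(byRoi) <- NULL
    }
    list(byFeature = byFeature, byRoi = byRoi)
}

#' Fit the final deployment pipeline on all available data
#'
#' All stages are fitted on the full table (standardizer, isolation forest
#' with Tukey cutoff, ranking, forward selection for method "M6", CN-only
#' LASSO, logistic classifier). The bundle can be serialized with
#' [writeModelJSON()] and applied to new tables with [predictPipeline()].
#'
#' @param table a [BrainFeatureSet-class].
#' @param cfg a [pipelineConfig()] list.
#' @return an \code{AbaPipeline} list of fitted sub-models.
#' @export
fitFinalModel <- function(table, cfg = pipelineConfig()) {
    std <- fitStandardizer(table)
    z <- applyStandardizer(std, table)
    forest <- NULL
    if (isTRUE(cfg$outlier$enabled)) {
        forest <- fitIsolationForest(z, psi = cfg$outlier$psi,
                                     heightLimit = cfg$outlier$heightLimit,
                                     nTrees = cfg$outlier$nTrees,
                                     seed = childSeed(cfg$seed, 11))
        forest <- calibrateCutoff(forest, z)
        sc <- scoreOutliers(forest, z)
        z <- filterOutliers(z, sc, forest@cutoff)$kept
    }
    ranking <- rankFeatures(z)
    sel <- NULL
    if (cfg$method == "M6") {
        sel <- forwardSelect(z, ranking, innerFolds = cfg$ffs$innerFolds,
                             epsilon = cfg$ffs$epsilon, topK = cfg$ffs$topK,
                             penalty = cfg$ffs$penalty,
                             seed = childSeed(cfg$seed, 12))
        f1 <- selected(sel)
    } else f1 <- featureNames(z)
    cn <- subsetSubjects(z, groups(z) == "CN")
    aba <- fitAba(cn, offered = f1, penalty = cfg$abaPenalty,
                  cvFolds = cfg$abaCvFolds, seed = childSeed(cfg$seed, 13))
    clf <- fitClassifier(predictAba(aba, z))
    structure(list(standardizer = std, forest = forest, ranking = ranking,
                   selection = sel, aba = aba, classifier = clf,
                   method = cfg$method),
              class = "AbaPipeline")
}

#' Apply a fitted pipeline to a table
#'
#' Standardizes with the stored training moments, flags outliers with the
#' stored forest and cutoff, predicts ABA/ADS and the diagnosis.
#'
#' @param pipeline an \code{AbaPipeline} from [fitFinalModel()].
#' @param table a [BrainFeatureSet-class] with matching feature names.
#' @return data.frame: subject_id, group, age, aba, ads, label, probability,
#'   flagged.
#' @export
predictPipeline <- function(pipeline, table) {
    z <- applyStandardizer(pipeline$standardizer, table)
    flagged <- rep(FALSE, ncol(table))
    if (!is.null(pipeline$forest))
        flagged <- scoreOutliers(pipeline$forest, z) >
            pipeline$forest@cutoff
    preds <- predictAba(pipeline$aba, z)
    dec <- predictDiagnosis(pipeline$classifier, preds$age, preds$aba)
    cbind(preds, label = dec$label, probability = dec$probability,
          flagged = as.logical(flagged))
}
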