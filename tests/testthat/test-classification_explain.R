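test_that("a separable cohort is classified perfectly via the ridge fallback", {
    set.seed(1)
    n <- 200
    age <- runif(n, 60, 85)
    grp <- rep_len(c("AD", "CN"), n)
    aba <- age + ifelse(grp == "AD", 10, 0)
    preds <- data.frame(age = age, aba = aba, group = grp)
    expect_warning(clf <- fitClassifier(preds), "separation")
    expect_true(clf@ridge)
    dec <- predictDiagnosis(clf, age, aba)
    expect_equal(mean(dec$label == grp), 1)
})

test_that("shuffled labels give accuracy near the majority rate", {
    set.seed(2)
    n <- 400
    age <- runif(n, 60, 85)
    aba <- age + rnorm(n, 0, 3)
    grp <- sample(rep(c("AD", "CN"), c(120, 280)))
    clf <- fitClassifier(data.frame(age = age, aba = aba, group = grp))
    dec <- predictDiagnosis(clf, age, aba)
    maj <- 280 / 400
    expect_lt(abs(mean(dec$label == grp) - maj),
              4 * sqrt(maj * (1 - maj) / n) + 0.01)
})

test_that("a two-point toy boundary separates the points", {
    preds <- data.frame(age = c(70, 70), aba = c(90, 70),
                        group = c("AD", "CN"))
    clf <- suppressWarnings(fitClassifier(preds))
    dec <- predictDiagnosis(clf, preds$age, preds$aba)
    expect_identical(dec$label, c("AD", "CN"))
})

test_that("prediction follows the sign convention with a CN tie-break", {
    clf <- new("ClassifierModel",
               coefficients = c(c0 = 10, c1 = -0.05, c2 = -0.1),
               ridge = FALSE)
    # point exactly on the boundary: 10 - 0.05*100 - 0.1*50 = 0
    dec <- predictDiagnosis(clf, 100, 50)
    expect_identical(dec$label, "CN")
    expect_equal(dec$probability, 0.5)
    # link symmetry
    grid <- expand.grid(age = seq(50, 90, by = 10),
                        aba = seq(40, 110, by = 10))
    d1 <- predictDiagnosis(clf, grid$age, grid$aba)
    score <- 10 - 0.05 * grid$age - 0.1 * grid$aba
    expect_identical(d1$label, ifelse(score < 0, "AD", "CN"))
    expect_equal(d1$probability + plogis(score), rep(1, nrow(grid)),
                 tolerance = 1e-12)
})

refModels <- function() {
    clf <- new("ClassifierModel",
               coefficients = c(c0 = 10, c1 = -0.05, c2 = -0.1),
               ridge = FALSE)
    aba <- new("AbaModel", intercept = 50, coefficients = c(f1 = 3),
               penalty = 0.1, offered = "f1", nTrain = 10L)
    list(clf = clf, aba = aba)
}

subjectTable <- function(f1, age = 70) {
    BrainFeatureSet(matrix(f1, 1, 1, dimnames = list(NULL, "f1")), "s1",
                    "F", age, "CN", "X")
}

test_that("feature scores reproduce the worked decomposition cases", {
    mods <- refModels()
    # D = 10 - 0.05*70 - 0.1*50 = 1.5; f1 = 2: s1 = 0.1*3*2/1.5 = 0.4 (CN)
    rep1 <- featureScores(mods$clf, mods$aba, subjectTable(2))[[1]]
    expect_equal(rep1@denominator, 1.5)
    expect_equal(unname(rep1@scores[["f1"]]), 0.4)
    expect_equal(rep1@sumScores, 0.4)
    expect_equal(rep1@boundary, 0.9)  # 1.5 * (1 - 0.4)
    expect_identical(rep1@decision, "CN")
    expect_identical(scoreDecision(rep1), "CN")

    # f1 = 20: s1 = 4 > 1; boundary 1.5 * (1 - 4) = -4.5 -> AD
    rep2 <- featureScores(mods$clf, mods$aba, subjectTable(20))[[1]]
    expect_equal(unname(rep2@scores[["f1"]]), 4)
    expect_equal(rep2@boundary, -4.5)
    expect_identical(rep2@decision, "AD")
    expect_identical(scoreDecision(rep2), "AD")

    # feature at the training mean contributes nothing
    rep3 <- featureScores(mods$clf, mods$aba, subjectTable(0))[[1]]
    expect_equal(unname(rep3@scores[["f1"]]), 0)
})

test_that("a score sum of exactly 1 lands on the boundary and is CN", {
    # all constants are exact in binary so the boundary is exactly 0:
    # D = 16 - 0.0625*64 - 0.125*48 = 6; f1 = D / (-c2*a1) = 6/0.25 = 24
    clf <- new("ClassifierModel",
               coefficients = c(c0 = 16, c1 = -0.0625, c2 = -0.125),
               ridge = FALSE)
    abaM <- new("AbaModel", intercept = 48, coefficients = c(f1 = 2),
                penalty = 0.1, offered = "f1", nTrain = 10L)
    tab <- BrainFeatureSet(matrix(24, 1, 1, dimnames = list(NULL, "f1")),
                           "s1", "F", 64, "CN", "X")
    rep <- featureScores(clf, abaM, tab)[[1]]
    expect_equal(rep@sumScores, 1)
    expect_equal(rep@boundary, 0)
    expect_identical(rep@decision, "CN")
    expect_identical(scoreDecision(rep), "CN")
})

test_that("degenerate subjects (D = 0) are flagged and refuse a score decision", {
    mods <- refModels()
    # D = 0 at age = (10 - 0.1*50)/0.05 = 100
    expect_warning(rep <- featureScores(mods$clf, mods$aba,
                                        subjectTable(2, age = 100))[[1]],
                   "boundary-degenerate")
    expect_true(rep@degenerate)
    expect_error(scoreDecision(rep), "degenerate")
})

test_that("score decision agrees with the logistic boundary on random models", {
    set.seed(3)
    agree <- replicate(1000, {
        k <- sample(1:6, 1)
        a <- setNames(rnorm(k, 0, 3), paste0("f", seq_len(k)))
        abaM <- new("AbaModel", intercept = runif(1, 40, 90),
                    coefficients = a, penalty = 0.1,
                    offered = names(a), nTrain = 10L)
        co <- c(c0 = rnorm(1, 0, 5), c1 = rnorm(1, 0, 0.3),
                c2 = rnorm(1, 0, 0.3))
        clf <- new("ClassifierModel", coefficients = co, ridge = FALSE)
        age <- runif(1, 50, 95)
        D <- co[["c0"]] + co[["c1"]] * age + co[["c2"]] * abaM@intercept
        if (D == 0) return(TRUE)  # excluded by the precondition
        f <- matrix(rnorm(k, 0, 2), 1, k, dimnames = list(NULL, names(a)))
        tab <- BrainFeatureSet(f, "s1", "F", age, "CN", "X")
        rep <- featureScores(clf, abaM, tab)[[1]]
        # Eq-consistency: boundary from raw features matches (age, aba) form
        aba <- abaM@intercept + sum(a * f)
        bRaw <- co[["c0"]] + co[["c1"]] * age + co[["c2"]] * aba
        abs(bRaw - rep@boundary) < 1e-10 &&
            sum(rep@scores) == rep@sumScores &&
            scoreDecision(rep) == rep@decision
    })
    expect_equal(mean(agree), 1)
})

test_that("quartile context matches an independent quantile recomputation", {
    mods <- refModels()
    set.seed(4)
    n <- 24
    f <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f1"))
    tab <- BrainFeatureSet(f, sprintf("s%02d", 1:n), "F",
                           runif(n, 60, 85), rep_len(c("AD", "CN"), n), "X")
    reps <- featureScores(mods$clf, mods$aba, tab)
    ctx <- quartileContext(reps, groups(tab))
    sAD <- vapply(reps[groups(tab) == "AD"], function(r) r@scores[["f1"]],
                  numeric(1))
    row <- ctx[ctx$group == "AD" & ctx$feature == "f1", ]
    expect_equal(row$q1, interpQuantile(sAD, 0.25), tolerance = 1e-12)
    expect_equal(row$median, interpQuantile(sAD, 0.5), tolerance = 1e-12)
    expect_equal(row$q3, interpQuantile(sAD, 0.75), tolerance = 1e-12)
    expect_equal(row$min, min(sAD))
    expect_equal(row$max, max(sAD))

    expect_error(quartileContext(reps[1:5], groups(tab)[1:5]),
                 "at least 4")

    # degenerate boxes when all training scores are equal
    same <- BrainFeatureSet(matrix(1, 8, 1, dimnames = list(NULL, "f1")),
                            sprintf("d%d", 1:8), "F", rep(70, 8),
                            rep_len(c("AD", "CN"), 8), "X")
    reps2 <- featureScores(mods$clf, mods$aba, same)
    ctx2 <- quartileContext(reps2, groups(same))
    expect_equal(ctx2$min, ctx2$max)

    # long-format table carries one row per subject-feature pair
    tabLong <- featureScoreTable(reps, ctx)
    expect_equal(nrow(tabLong), n)
    expect_true(all(c("score", "q1.AD", "q3.CN") %in% colnames(tabLong)))
})
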