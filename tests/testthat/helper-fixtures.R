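# Fixtures are built in code at test time; nothing is stored on disk.

# a small two-cohort synthetic population for pipeline-level tests
smallConfig <- function(seed = 11, acceleration = 8, nAD = 90, nCN = 210,
                        nInformative = 3, nAgeOnly = 3, nNoise = 10) {
    strata <- data.frame(gender = "F",
                         cohort = rep(c("synthA", "synthB"), each = 2),
                         group = rep(c("AD", "CN"), 2),
                         n = as.integer(rep(c(nAD / 2, nCN / 2), 2)),
                         ageMean = 74, ageSD = 7, ageMin = 55, ageMax = 90,
                         stringsAsFactors = FALSE)
    cohortConfig(strata = strata, nInformative = nInformative,
                 nAgeOnly = nAgeOnly, nNoise = nNoise,
                 acceleration = acceleration, seed = seed)
}

# pipeline config with a lighter forest for unit-test speed; the acceptance
# tests use the full defaults
fastCfg <- function(method = "M6", seed = 1, ...) {
    pipelineConfig(method = method,
                   outlier = list(psi = 64, nTrees = 30),
                   seed = seed, ...)
}

# plain random table with no group signal
makeToyTable <- function(n = 20, p = 3, seed = 99, gender = "M") {
    set.seed(seed)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    BrainFeatureSet(m, subject_id = sprintf("T%03d", seq_len(n)),
                    gender = rep_len(gender, n),
                    age = runif(n, 60, 85),
                    group = rep_len(c("AD", "CN"), n),
                    cohort = "toy")
}

# independent quantile oracle: linear interpolation between order statistics
interpQuantile <- function(x, p) {
    s <- sort(unname(x))
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
    expect_identical(subjectIds(a), subjectIds(b))
    expect_identical(genders(a), genders(b))
    expect_identical(groups(a), groups(b))
    expect_identical(cohorts(a), cohorts(b))
    expect_equal(ages(a), ages(b), tolerance = tol)
    expect_identical(colnames(featureMatrix(a)), colnames(featureMatrix(b)))
    expect_lt(max(abs(featureMatrix(a) - featureMatrix(b))), tol)
}
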