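# Synthetic cohort generator: linear-Gaussian ageing with AD-accelerated
# atrophy planted in a known informative ROI subset, plus ground truth for
# parameter-recovery tests and an exact Bayes reference classifier.

roiVocabulary <- function() {
    c("Whole_hippocampus", "Entorhinal_thickness", "Amygdala", "Subiculum",
      "Middletemporal_thickness", "CA1", "Molecular_layer_HP",
      "Hippocampal_tail", "Presubiculum", "HATA", "GC_ML_DG",
      "Fusiform_thickness", "Bankssts_thickness", "Middletemporal_volume",
      "Inf_Lat_Vent", "Inferiortemporal_thickness", "CA3", "CA4")
}

makeRoiNames <- function(n, kind) {
    if (n == 0) return(character(0))
    hemi <- rep(c("LH_", "RH_"), length.out = n)
    if (kind == "informative") {
        voc <- roiVocabulary()
        stem <- voc[((seq_len(n) - 1) %% length(voc)) + 1]
        if (n > length(voc)) stem <- sprintf("%s_v%d", stem,
                                             (seq_len(n) - 1) %/% length(voc))
        paste0(hemi, stem)
    } else if (kind == "ageing") {
        paste0(hemi, sprintf("AgeingROI%02d", seq_len(n)))
    } else {
        paste0(hemi, sprintf("NoiseROI%02d", seq_len(n)))
    }
}

#' Demographic strata of the three-repository study population
#'
#' Gender-by-cohort-by-group subject counts with per-stratum age mean, SD and
#' range (years) for the ADNI/AIBL/IXI study population this generator
#' emulates (1,901 subjects: 861 male, 1,040 female; IXI contributes
#' cognitively normal subjects only).
#'
#' @return data.frame with columns gender, cohort, group, n, ageMean, ageSD,
#'   ageMin, ageMax.
#' @export
table1Strata <- function() {
    data.frame(
        gender = c("M", "M", "M", "M", "M", "F", "F", "F", "F", "F"),
        cohort = c("ADNI", "ADNI", "AIBL", "AIBL", "IXI",
                   "ADNI", "ADNI", "AIBL", "AIBL", "IXI"),
        group = c("AD", "CN", "AD", "CN", "CN", "AD", "CN", "AD", "CN", "CN"),
        n = c(213L, 317L, 34L, 207L, 90L, 177L, 398L, 45L, 277L, 143L),
        ageMean = c(75.82, 74.2, 74.65, 74.36, 65.5,
                    74.29, 72.1, 75.27, 74.44, 65.1),
        ageSD = c(7.86, 6.36, 9.07, 7.83, 7.27,
                  8.07, 6.24, 7.81, 7.31, 6.31),
        ageMin = c(55.3, 56.2, 58, 54.6, 55.09,
                   55.2, 55.6, 56.3, 55.2, 55.22),
        ageMax = c(90.4, 90.3, 89.4, 89.8, 86.2,
                   91, 89.9, 88.4, 88, 86.32),
        stringsAsFactors = FALSE)
}

fixtureStrata <- function() {
    data.frame(
        gender = c("F", "F", "F", "F"),
        cohort = c("synthA", "synthA", "synthB", "synthB"),
        group = c("AD", "CN", "AD", "CN"),
        n = c(150L, 350L, 150L, 350L),
        ageMean = 74, ageSD = 7, ageMin = 55, ageMax = 90,
        stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' The generative model is linear-Gaussian: an informative feature j of
#' subject s is \code{baseline_j - slope_j * effectiveAge(s) + N(0, sd_j)},
#' where the effective age equals the chronological age plus
#' \code{acceleration} extra years of decline for AD subjects. Ageing-only
#' features decline with chronological age but carry no AD acceleration
#' (age-informative, classification-irrelevant); noise features are
#' independent of both age and group. Ages are drawn from a truncated normal
#' per stratum. Outliers are planted by inflating a random subject's whole
#' feature vector by \code{outlierMagnitude} residual standard deviations
#' (random sign per feature).
#'
#' @param strata data.frame as from [table1Strata()]: gender, cohort, group,
#'   n, ageMean, ageSD, ageMin, ageMax.
#' @param nInformative,nAgeOnly,nNoise number of AD-informative, ageing-only
#'   and pure-noise features.
#' @param infBaseline,infSlope,infNoiseSD informative-feature intercept
#'   (units), ageing slope (units/year) and residual sd.
#' @param acceleration extra effective years of decline for AD subjects.
#' @param ageOnlyBaseline,ageOnlySlope,ageOnlyNoiseSD ageing-only feature law.
#' @param noiseBaseline,noiseSD pure-noise feature law.
#' @param outlierCount,outlierMagnitude planted-outlier count and offset in
#'   residual sd units.
#' @param seed integer; fixes the generated table bit-exactly.
#' @return a \code{CohortConfig} list.
#' @seealso [generateCohort()], [defaultFixtureConfig()]
#' @export
cohortConfig <- function(strata = table1Strata(),
                         nInformative = 5, nAgeOnly = 20, nNoise = 75,
                         infBaseline = 4000, infSlope = 20,
                         infNoiseSD = 135, acceleration = 8,
                         ageOnlyBaseline = 4000, ageOnlySlope = 20,
                         ageOnlyNoiseSD = 135,
                         noiseBaseline = 500, noiseSD = 50,
                         outlierCount = 0, outlierMagnitude = 6,
                         seed = 1) {
    req <- c("gender", "cohort", "group", "n", "ageMean", "ageSD", "ageMin",
             "ageMax")
    if (!all(req %in% colnames(strata)))
        stop("strata must have columns: ", paste(req, collapse = ", "))
    if (any(strata$n < 0)) stop("stratum counts must be >= 0")
    if (any(strata$ageSD <= 0)) stop("age SD must be > 0")
    if (any(strata$ageMin >= strata$ageMax))
        stop("infeasible truncation bounds")
    if (min(infNoiseSD, ageOnlyNoiseSD, noiseSD) <= 0)
        stop("noise sd must be > 0")
    p <- nInformative + nAgeOnly + nNoise
    if (p < 1) stop("at least one feature is required")
    structure(list(
        strata = strata, nInformative = nInformative, nAgeOnly = nAgeOnly,
        nNoise = nNoise, infBaseline = infBaseline, infSlope = infSlope,
        infNoiseSD = infNoiseSD, acceleration = acceleration,
        ageOnlyBaseline = ageOnlyBaseline, ageOnlySlope = ageOnlySlope,
        ageOnlyNoiseSD = ageOnlyNoiseSD, noiseBaseline = noiseBaseline,
        noiseSD = noiseSD, outlierCount = outlierCount,
        outlierMagnitude = outlierMagnitude, seed = as.integer(seed),
        informative = makeRoiNames(nInformative, "informative"),
        ageOnly = makeRoiNames(nAgeOnly, "ageing"),
        noise = makeRoiNames(nNoise, "noise")),
        class = "CohortConfig")
}

#' Default single-gender evaluation fixture
#'
#' A 1,000-subject female cohort (two synthetic sub-cohorts of 150 AD + 350
#' CN each; ages truncated-normal, mean 74, sd 7, range 55-90) with 5
#' AD-informative features (8 planted years of accelerated decline), 20
#' ageing-only features and 75 pure-noise features, and no planted outliers.
#'
#' @param seed integer random seed.
#' @return a \code{CohortConfig}.
#' @export
defaultFixtureConfig <- function(seed = 20210528) {
    cohortConfig(strata = fixtureStrata(), seed = seed)
}

#' Contamination fixture for the outlier stage
#'
#' 800 inlier subjects (CN/AD mix in one stratum pair) plus 20 planted
#' outliers whose feature vectors are inflated by 6 residual sd.
#'
#' @param seed integer random seed.
#' @return a \code{CohortConfig}.
#' @export
contaminationConfig <- function(seed = 20210528) {
    strata <- data.frame(gender = "F", cohort = "synthA",
                         group = c("AD", "CN"), n = c(240L, 580L),
                         ageMean = 74, ageSD = 7, ageMin = 55, ageMax = 90,
                         stringsAsFactors = FALSE)
    cohortConfig(strata = strata, nInformative = 3, nAgeOnly = 3, nNoise = 4,
                 outlierCount = 20, outlierMagnitude = 6, seed = seed)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the cohort described by \code{config} (see [cohortConfig()] for the
#' generative model). Identical seeds give byte-identical output.
#'
#' @param config a \code{CohortConfig}.
#' @return list with elements \code{table} (a [BrainFeatureSet-class]) and
#'   \code{truth}: informative/ageOnly feature names, per-subject effective
#'   brain age (age + planted acceleration for AD), planted-outlier subject
#'   ids, and the per-feature residual sd vector.
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    st <- config$strata
    st <- st[st$n > 0, , drop = FALSE]
    n <- sum(st$n)
    if (n == 0) stop("empty cohort configuration")
    featNames <- c(config$informative, config$ageOnly, config$noise)
    withSeed(config$seed, {
        gender <- rep(st$gender, st$n)
        cohort <- rep(st$cohort, st$n)
        group <- rep(st$group, st$n)
        age <- unlist(lapply(seq_len(nrow(st)), function(i)
            rtruncnorm(st$n[i], st$ageMean[i], st$ageSD[i], st$ageMin[i],
                       st$ageMax[i])))
        effAge <- age + config$acceleration * (group == "AD")
        p <- length(featNames)
        x <- matrix(NA_real_, n, p, dimnames = list(NULL, featNames))
        sdVec <- setNames(c(rep(config$infNoiseSD, config$nInformative),
                            rep(config$ageOnlyNoiseSD, config$nAgeOnly),
                            rep(config$noiseSD, config$nNoise)), featNames)
        for (f in config$informative)
            x[, f] <- config$infBaseline - config$infSlope * effAge +
                rnorm(n, 0, config$infNoiseSD)
        for (f in config$ageOnly)
            x[, f] <- config$ageOnlyBaseline - config$ageOnlySlope * age +
                rnorm(n, 0, config$ageOnlyNoiseSD)
        for (f in config$noise)
            x[, f] <- config$noiseBaseline + rnorm(n, 0, config$noiseSD)
        ids <- sprintf("S%05d", seq_len(n))
        outlierIds <- character(0)
        if (config$outlierCount > 0) {
            pick <- sample(n, config$outlierCount)
            signs <- matrix(sample(c(-1, 1), config$outlierCount * p,
                                   replace = TRUE), config$outlierCount, p)
            x[pick, ] <- x[pick, , drop = FALSE] +
                config$outlierMagnitude * signs *
                matrix(sdVec, config$outlierCount, p, byrow = TRUE)
            outlierIds <- ids[pick]
        }
        table <- BrainFeatureSet(x, subject_id = ids, gender = gender,
                                 age = age, group = group, cohort = cohort)
        list(table = table,
             truth = list(informative = config$informative,
                          ageOnly = config$ageOnly,
                          effectiveAge = setNames(effAge, ids),
                          outliers = outlierIds,
                          residualSD = sdVec))
    })
}

#' Exact Bayes posterior P(AD) under the generative model
#'
#' For a table generated by \code{config}, computes the exact posterior
#' probability of AD per subject by conditioning on age and the subject's
#' gender/cohort stratum. Only the informative features enter the likelihood
#' ratio (ageing-only and noise features have identical class-conditional
#' laws given age and cancel). The implied classifier (posterior > 0.5) is
#' the accuracy upper bound for any pipeline on this data.
#'
#' @param config the \code{CohortConfig} that generated \code{table}.
#' @param table the generated [BrainFeatureSet-class] (outlier-free rows of
#'   planted outliers are scored like any other subject).
#' @return numeric vector of posterior probabilities, one per subject.
#' @export
bayesReference <- function(config, table) {
    stopifnot(inherits(config, "CohortConfig"))
    if (!all(config$informative %in% featureNames(table)))
        stop("table/config mismatch: informative features absent from table")
    st <- config$strata
    key <- paste(st$gender, st$cohort)
    nAD <- tapply(st$n * (st$group == "AD"), key, sum)
    nAll <- tapply(st$n, key, sum)
    prior <- nAD / nAll
    subjKey <- paste(genders(table), cohorts(table))
    if (!all(subjKey %in% names(prior)))
        stop("table/config mismatch: unknown gender/cohort stratum")
    pri <- as.numeric(prior[subjKey])
    age <- ages(table)
    x <- featureMatrix(table)[, config$informative, drop = FALSE]
    llr <- numeric(ncol(table))
    for (f in config$informative) {
        muCN <- config$infBaseline - config$infSlope * age
        muAD <- config$infBaseline - config$infSlope *
            (age + config$acceleration)
        llr <- llr + dnorm(x[, f], muAD, config$infNoiseSD, log = TRUE) -
            dnorm(x[, f], muCN, config$infNoiseSD, log = TRUE)
    }
    post <- ifelse(pri <= 0, 0,
            ifelse(pri >= 1, 1,
                   plogis(log(pri / (1 - pri)) + llr)))
    as.numeric(post)
}
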