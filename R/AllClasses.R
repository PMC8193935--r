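#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats quantile cor sd rnorm runif var coef glm glm.fit
#'   binomial plogis predict qnorm pnorm pt setNames dnorm t.test lm median
#' @importFrom utils read.csv read.delim write.csv head
NULL

#' BrainFeatureSet: per-subject morphometric feature table
#'
#' A \linkS4class{SummarizedExperiment} holding one assay named
#' \code{"morphometry"} with features (FreeSurfer-style ROI volumes and
#' thicknesses) in rows and subjects in columns. The column data carry the
#' subject metadata: \code{subject_id}, \code{gender} (\code{"M"}/\code{"F"}),
#' \code{age} (years), \code{group} (\code{"AD"}/\code{"CN"}) and
#' \code{cohort} (source tag, e.g. ADNI/AIBL/IXI/synthetic).
#'
#' Validity requires unique subject ids, strictly positive finite ages, no
#' missing feature values, and gender/group restricted to the two-level codes
#' above.
#'
#' @seealso [BrainFeatureSet()] for the constructor,
#'   [loadFeatureTable()] to read one from CSV/TSV.
#' @exportClass BrainFeatureSet
setClass("BrainFeatureSet", contains = "SummarizedExperiment")

setValidity("BrainFeatureSet", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    req <- c("subject_id", "gender", "age", "group", "cohort")
    missing_cols <- setdiff(req, colnames(cd))
    if (length(missing_cols) > 0)
        return(paste("missing metadata column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (!"morphometry" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'morphometry' is required")
    if (anyDuplicated(cd$subject_id))
        msg <- c(msg, "duplicate subject_id")
    if (nrow(cd) > 0) {
        if (!all(is.finite(cd$age)) || any(cd$age <= 0))
            msg <- c(msg, "age must be finite and > 0")
        if (!all(cd$gender %in% c("M", "F")))
            msg <- c(msg, "gender must be 'M' or 'F'")
        if (!all(cd$group %in% c("AD", "CN")))
            msg <- c(msg, "group must be 'AD' or 'CN'")
        a <- SummarizedExperiment::assay(object, "morphometry")
        if (!is.numeric(a))
            msg <- c(msg, "feature values must be numeric")
        else if (anyNA(a))
            msg <- c(msg, "missing feature values are not allowed")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "feature names must be present and unique")
    }
    if (length(msg) == 0) TRUE else msg
})

#' StandardizationModel: per-feature z-score model
#'
#' Per-feature mean and standard deviation estimated on a training partition
#' (unbiased n-1 denominator). Age and metadata are never standardized, so
#' downstream age predictions stay in years.
#'
#' @slot mean named numeric, per-feature training mean.
#' @slot sd named numeric, per-feature training sd (all > 0).
#' @exportClass StandardizationModel
setClass("StandardizationModel",
         representation(mean = "numeric", sd = "numeric"))

setValidity("StandardizationModel", function(object) {
    if (length(object@mean) != length(object@sd))
        return("mean and sd must have the same length")
    if (is.null(names(object@mean)) ||
        !identical(names(object@mean), names(object@sd)))
        return("mean and sd must share identical feature names")
    if (any(!is.finite(object@sd)) || any(object@sd <= 0))
        return("sd must be finite and > 0 for every feature")
    TRUE
})

#' IsolationForest: unsupervised anomaly model with Tukey-fence cutoff
#'
#' An ensemble of \code{nTrees} isolation trees, each grown on a uniform
#' random subsample of at most \code{psi} rows, with uniform random split
#' features and split values, truncated at height \code{heightLimit}. Anomaly
#' scores are \code{2^(-E[h(x)]/c(psi))}, in (0, 1]; higher is more anomalous.
#' The \code{cutoff} slot, when fitted, holds the Tukey fence
#' \code{Q3 + 3*IQR} of the training scores.
#'
#' Each tree is stored as a data.frame of nodes with columns \code{feature}
#' (split feature index; \code{NA_integer_} for leaves), \code{value} (split
#' value), \code{left}/\code{right} (child node row indices) and \code{size}
#' (number of training rows reaching the node, used for the average
#' path-length correction at truncated nodes).
#'
#' @exportClass IsolationForest
setClass("IsolationForest",
         representation(trees = "list", psi = "integer",
                        heightLimit = "integer", nTrees = "integer",
                        cn = "numeric", featureNames = "character",
                        cutoff = "numeric"))

#' AbaModel: sparse linear Apparent Brain Age regression
#'
#' LASSO regression of chronological age on standardized morphometric
#' features, fitted on cognitively normal (CN) training subjects only:
#' \code{aba = a0 + sum_i a_i * f_i}. The nonzero-coefficient support is the
#' embedded selection F2, a subset of the features offered by the wrapper
#' (F1).
#'
#' @slot intercept a0, in years.
#' @slot coefficients named numeric over the support F2 (nonzero a_i only).
#' @slot penalty the L1 penalty weight used (glmnet lambda scale).
#' @slot offered the feature set F1 the model was offered.
#' @slot nTrain number of CN training subjects.
#' @exportClass AbaModel
setClass("AbaModel",
         representation(intercept = "numeric", coefficients = "numeric",
                        penalty = "numeric", offered = "character",
                        nTrain = "integer"))

setValidity("AbaModel", function(object) {
    if (length(object@intercept) != 1 || !is.finite(object@intercept))
        return("intercept must be a single finite number")
    k <- length(object@coefficients)
    if (k > 0 && (is.null(names(object@coefficients)) ||
                  anyDuplicated(names(object@coefficients))))
        return("coefficients must be uniquely named")
    if (!all(names(object@coefficients) %in% object@offered))
        return("support F2 must be a subset of the offered set F1")
    if (k > 0 && any(object@coefficients == 0))
        return("stored coefficients must be the nonzero support")
    TRUE
})

#' ClassifierModel: logistic AD/CN boundary on (age, ABA)
#'
#' Stores c0, c1, c2 with the decision convention that a subject is
#' classified AD when \code{c0 + c1*age + c2*aba < 0}; a score of exactly
#' zero is classified CN. The AD probability is \code{plogis(-(c0 + c1*age +
#' c2*aba))}.
#'
#' @slot coefficients numeric of length 3, named c0, c1, c2.
#' @slot ridge logical; TRUE when a small ridge penalty was used as the
#'   fallback for perfect separation.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
         representation(coefficients = "numeric", ridge = "logical"))

setValidity("ClassifierModel", function(object) {
    if (length(object@coefficients) != 3 ||
        !identical(names(object@coefficients), c("c0", "c1", "c2")))
        return("coefficients must be length 3, named c0, c1, c2")
    if (any(!is.finite(object@coefficients)))
        return("coefficients must be finite")
    TRUE
})

#' FeatureScoreReport: per-subject decomposition of a classification
#'
#' For one subject, the per-feature scores \code{s_i = -c2*a_i*f_i / D}
#' with denominator \code{D = c0 + c1*age + c2*a0}, their sum, the boundary
#' value \code{c0 + c1*age + c2*aba}, and the decision label. When D is zero
#' the subject is boundary-degenerate and the scores are undefined.
#'
#' @slot subjectId subject identifier.
#' @slot age chronological age (years).
#' @slot scores named numeric over the support F2.
#' @slot denominator D.
#' @slot sumScores sum of the scores.
#' @slot boundary the linear boundary value of the classification rule.
#' @slot decision "AD" or "CN".
#' @slot degenerate TRUE when D == 0 (scores undefined).
#' @exportClass FeatureScoreReport
setClass("FeatureScoreReport",
         representation(subjectId = "character", age = "numeric",
                        scores = "numeric", denominator = "numeric",
                        sumScores = "numeric", boundary = "numeric",
                        decision = "character", degenerate = "logical"))

#' @describeIn BrainFeatureSet-class compact display
#' @param object a \code{BrainFeatureSet}
#' @export
setMethod("show", "BrainFeatureSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("BrainFeatureSet:", ncol(object), "subjects x", nrow(object),
        "features\n")
    if (ncol(object) > 0) {
        cat("  groups: ", paste(sprintf("%s=%d", names(table(cd$group)),
                                        table(cd$group)), collapse = ", "),
            "\n", sep = "")
        cat("  gender: ", paste(sprintf("%s=%d", names(table(cd$gender)),
                                        table(cd$gender)), collapse = ", "),
            "\n", sep = "")
        cat("  cohorts:", paste(unique(cd$cohort), collapse = ", "), "\n")
        cat(sprintf("  age: %.1f-%.1f (mean %.1f)\n", min(cd$age),
                    max(cd$age), mean(cd$age)))
    }
})

setMethod("show", "StandardizationModel", function(object) {
    cat("StandardizationModel over", length(object@mean), "features\n")
})

setMethod("show", "IsolationForest", function(object) {
    cat(sprintf("IsolationForest: t=%d trees, psi=%d, height limit %d\n",
                object@nTrees, object@psi, object@heightLimit))
    if (length(object@cutoff) == 1)
        cat(sprintf("  Tukey cutoff (Q3 + 3*IQR): %.6f\n", object@cutoff))
})

setMethod("show", "AbaModel", function(object) {
    cat(sprintf("AbaModel: a0 = %.2f years, k = %d support features (F2)\n",
                object@intercept, length(object@coefficients)))
    cat(sprintf("  offered |F1| = %d, penalty = %.5g, trained on %d CN\n",
                length(object@offered), object@penalty, object@nTrain))
})

setMethod("show", "ClassifierModel", function(object) {
    co <- object@coefficients
    cat(sprintf("ClassifierModel: AD iff %.4g %+.4g*age %+.4g*aba < 0%s\n",
                co[1], co[2], co[3],
                if (object@ridge) "  (ridge fallback)" else ""))
})

setMethod("show", "FeatureScoreReport", function(object) {
    cat(sprintf("FeatureScoreReport for %s (age %.1f): %s\n",
                object@subjectId, object@age, object@decision))
    if (object@degenerate) {
        cat("  boundary-degenerate subject (D = 0); scores undefined\n")
    } else {
        cat(sprintf("  D = %.4g, sum(s_i) = %.4g, boundary = %.4g\n",
                    object@denominator, object@sumScores, object@boundary))
    }
})
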