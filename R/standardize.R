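#' Fit a z-score standardization model on a training partition
#'
#' Per-feature mean and standard deviation (unbiased, n-1 denominator) are
#' estimated on the training partition only and later applied unchanged to
#' both training and test partitions. Age and metadata are never
#' standardized. Zero-variance features are rejected with their names, since
#' a z-score is undefined for them.
#'
#' @param train a [BrainFeatureSet-class] with at least 2 subjects.
#' @return a [StandardizationModel-class].
#' @seealso [applyStandardizer()]
#' @export
fitStandardizer <- function(train) {
    m <- featureMatrix(train)
    if (nrow(m) < 2) stop("need at least 2 training subjects")
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    zero <- colnames(m)[!is.finite(s) | s <= 0]
    if (length(zero) > 0)
        stop("zero-variance feature(s): ", paste(zero, collapse = ", "))
    methods::new("StandardizationModel", mean = mu, sd = s)
}

#' Apply a fitted standardization model
#'
#' Transforms every feature to \code{z = (x - mean) / sd} using the training
#' moments stored in \code{model}; metadata are untouched. Feature names must
#' match the model's exactly.
#'
#' @param model a [StandardizationModel-class].
#' @param x a [BrainFeatureSet-class] with the same feature names.
#' @return a standardized [BrainFeatureSet-class].
#' @export
applyStandardizer <- function(model, x) {
    m <- featureMatrix(x)
    if (!identical(colnames(m), names(model@mean)))
        stop("feature-name mismatch between table and standardization model")
    z <- sweep(sweep(m, 2, model@mean, "-"), 2, model@sd, "/")
    BrainFeatureSet(z, subject_id = subjectIds(x), gender = genders(x),
                    age = ages(x), group = groups(x), cohort = cohorts(x))
}
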