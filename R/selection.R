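# Point-biserial ranking and the classification-biased forward feature
# selection wrapper (inner cross-validation over the outer-fold training
# partition only).

#' SelectionTrace: wrapper feature-selection result
#'
#' @slot selected the accepted feature subset F1, in acceptance order.
#' @slot trace data.frame with one row per evaluated candidate: feature,
#'   rank, r, accuracyWith, accuracyWithout, accepted.
#' @exportClass SelectionTrace
setClass("SelectionTrace",
         representation(selected = "character", trace = "data.frame"))

setMethod("show", "SelectionTrace", function(object) {
    cat("SelectionTrace: |F1| =", length(object@selected), "of",
        nrow(object@trace), "candidates\n")
    cat("  F1:", paste(object@selected, collapse = ", "), "\n")
})

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous variable and a binary variable
#' coded 0/1. Zero-variance values give r = 0 by convention.
#'
#' @param values numeric vector.
#' @param labels binary vector (logical, 0/1 numeric, or two-level
#'   character).
#' @return the correlation coefficient r.
#' @export
pointBiserial <- function(values, labels) {
    if (is.character(labels) || is.factor(labels)) {
        lv <- sort(unique(as.character(labels)))
        if (length(lv) != 2) stop("labels must have exactly two classes")
        labels <- as.numeric(as.character(labels) == lv[2])
    }
    labels <- as.numeric(labels)
    if (length(unique(labels)) != 2) stop("one class absent")
    if (var(values) == 0) return(0)
    cor(values, labels)
}

#' Rank features by absolute point-biserial correlation with the AD label
#'
#' Features are ordered by decreasing |r| of the point-biserial correlation
#' with the binary AD/CN label (AD coded 1); ties are broken
#' lexicographically by feature name. The ranking is invariant under
#' per-feature affine rescaling, so it is identical on raw and standardized
#' features.
#'
#' @param train a [BrainFeatureSet-class] containing both classes.
#' @return data.frame with columns feature, r, absR, in rank order.
#' @export
rankFeatures <- function(train) {
    g <- groups(train)
    if (length(unique(g)) != 2) stop("training table must contain both classes")
    y <- as.numeric(g == "AD")
    x <- featureMatrix(train)
    r <- suppressWarnings(as.numeric(cor(x, y)))
    r[!is.finite(r)] <- 0  # zero-variance features
    ord <- order(-abs(r), colnames(x), method = "radix")
    data.frame(feature = colnames(x)[ord], r = r[ord], absR = abs(r)[ord],
               stringsAsFactors = FALSE)
}

# mean inner-CV classification accuracy of a candidate feature subset:
# per inner fold, fit the CN-only LASSO age model and the (age, ABA)
# logistic classifier on the inner-training split, evaluate on the
# inner-validation split
innerCvAccuracy <- function(x, age, isAD, fold, subset, penalty) {
    acc <- vapply(sort(unique(fold)), function(f) {
        tr <- fold != f
        cn <- tr & !isAD
        fit <- lassoFit(x[cn, subset, drop = FALSE], age[cn], penalty)
        abaTr <- fit$intercept +
            as.numeric(x[tr, subset, drop = FALSE] %*% fit$beta)
        clf <- suppressWarnings(
            glm.fit(cbind(1, age[tr], abaTr), as.numeric(isAD[tr]),
                    family = binomial()))
        co <- clf$coefficients
        co[!is.finite(co)] <- 0
        abaVal <- fit$intercept +
            as.numeric(x[!tr, subset, drop = FALSE] %*% fit$beta)
        eta <- co[1] + co[2] * age[!tr] + co[3] * abaVal
        mean((eta > 0) == isAD[!tr])
    }, numeric(1))
    mean(acc)
}

#' Classification-biased forward feature selection (FFS)
#'
#' Iterates over the point-biserial-ranked features. For each candidate, the
#' current subset plus the candidate is evaluated by inner stratified
#' cross-validation on the outer-fold training partition only: a LASSO age
#' regression is fitted on the inner-training CN subjects, a logistic
#' classifier is fitted on (age, ABA) of all inner-training subjects, and
#' classification accuracy is measured on the inner-validation split. The
#' candidate is kept iff the mean inner accuracy strictly improves by more
#' than \code{epsilon}. The default \code{epsilon = NULL} requires the
#' improvement to exceed one validation subject (1/n): a gain of exactly one
#' re-classified subject is the resolution of the inner-CV accuracy estimate
#' and indistinguishable from noise, so it does not count as a strict
#' improvement. The top-ranked feature is always retained so the age model
#' is never featureless. One pass, no backtracking.
#'
#' @param train the outer-fold training partition (standardized,
#'   outlier-filtered), a [BrainFeatureSet-class] with both classes.
#' @param ranking a ranking data.frame from [rankFeatures()].
#' @param innerFolds number of stratified inner CV folds.
#' @param epsilon minimum accuracy improvement to accept a candidate;
#'   NULL (default) uses 1/n, i.e. one validation subject.
#' @param topK evaluate only the top K ranked candidates (Inf = all).
#' @param penalty fixed LASSO penalty used inside the wrapper (glmnet lambda
#'   scale).
#' @param seed integer seed for the inner fold assignment.
#' @return a [SelectionTrace-class]; \code{selected(trace)} is F1.
#' @export
forwardSelect <- function(train, ranking, innerFolds = 5, epsilon = NULL,
                          topK = Inf, penalty = 0.1, seed = 1) {
    g <- groups(train)
    if (length(unique(g)) != 2) stop("training table must contain both classes")
    if (is.null(epsilon)) epsilon <- 1 / length(g)
    x <- featureMatrix(train)
    age <- ages(train)
    isAD <- g == "AD"
    fold <- stratifiedFolds(g, innerFolds, seed)
    cand <- ranking$feature
    if (is.finite(topK)) cand <- head(cand, topK)
    selected <- character(0)
    bestAcc <- -Inf
    rows <- vector("list", length(cand))
    for (i in seq_along(cand)) {
        f <- cand[i]
        acc <- innerCvAccuracy(x, age, isAD, fold, c(selected, f), penalty)
        accBefore <- if (i == 1) NA_real_ else bestAcc
        accept <- i == 1 || acc > bestAcc + epsilon
        if (accept) {
            selected <- c(selected, f)
            bestAcc <- if (i == 1) acc else max(acc, bestAcc)
        }
        rows[[i]] <- data.frame(feature = f, rank = i, r = ranking$r[i],
                                accuracyWith = acc,
                                accuracyWithout = accBefore,
                                accepted = accept,
                                stringsAsFactors = FALSE)
    }
    methods::new("SelectionTrace", selected = selected,
                 trace = do.call(rbind, rows))
}

#' @rdname forwardSelect
#' @param trace a [SelectionTrace-class]
#' @export
selected <- function(trace) trace@selected
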