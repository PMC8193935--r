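# Isolation forest with Tukey-fence cutoff. Unsupervised: labels are never
# used. Scores follow s(x) = 2^(-E[h(x)]/c(psi)), where h includes the
# standard average-path-length correction c(size) at truncated nodes.

# average unsuccessful-search path length in a BST of n nodes
cFactor <- function(n) {
    if (n > 2) 2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
    else if (n == 2) 1
    else 0
}

# grow one isolation tree on x[idx, ]; returns a node table (data.frame)
growITree <- function(x, idx, heightLimit) {
    maxNodes <- min(2L * length(idx), 2L^(heightLimit + 1L)) - 1L
    maxNodes <- max(maxNodes, 1L)
    feature <- rep(NA_integer_, maxNodes)
    value <- rep(NA_real_, maxNodes)
    left <- rep(NA_integer_, maxNodes)
    right <- rep(NA_integer_, maxNodes)
    size <- rep(NA_integer_, maxNodes)
    count <- 0L
    grow <- function(rows, depth) {
        count <<- count + 1L
        id <- count
        n <- length(rows)
        size[id] <<- n
        if (depth >= heightLimit || n <= 1) return(id)
        sub <- x[rows, , drop = FALSE]
        lo <- apply(sub, 2, min)
        hi <- apply(sub, 2, max)
        splittable <- which(hi > lo)
        if (length(splittable) == 0) return(id)
        f <- if (length(splittable) == 1) splittable
             else splittable[sample.int(length(splittable), 1)]
        v <- runif(1, lo[f], hi[f])
        goLeft <- sub[, f] < v
        if (!any(goLeft) || all(goLeft)) return(id)  # degenerate draw
        feature[id] <<- f
        value[id] <<- v
        left[id] <<- grow(rows[goLeft], depth + 1L)
        right[id] <<- grow(rows[!goLeft], depth + 1L)
        id
    }
    grow(idx, 0L)
    data.frame(feature = feature[seq_len(count)], value = value[seq_len(count)],
               left = left[seq_len(count)], right = right[seq_len(count)],
               size = size[seq_len(count)])
}

treePathLengths <- function(tree, x) {
    h <- numeric(nrow(x))
    rec <- function(node, rows, depth) {
        f <- tree$feature[node]
        if (is.na(f)) {
            h[rows] <<- depth + cFactor(tree$size[node])
            return(invisible(NULL))
        }
        goLeft <- x[rows, f] < tree$value[node]
        if (any(goLeft)) rec(tree$left[node], rows[goLeft], depth + 1)
        if (any(!goLeft)) rec(tree$right[node], rows[!goLeft], depth + 1)
    }
    if (nrow(x) > 0) rec(1L, seq_len(nrow(x)), 0)
    h
}

#' Fit an isolation forest on a training partition
#'
#' Grows \code{nTrees} isolation trees, each on a uniform random subsample of
#' \code{min(psi, n)} training rows, choosing a uniform random split feature
#' (among non-constant ones) and a uniform random split value within the
#' node's range, stopping at height \code{heightLimit} or singleton nodes.
#' Class labels are never used. Defaults follow the standard
#' recommendation: psi = 256, height limit 8, 100 trees.
#'
#' @param train a [BrainFeatureSet-class] (typically standardized).
#' @param psi sub-sampling size (>= 2).
#' @param heightLimit tree height limit l.
#' @param nTrees number of trees t.
#' @param seed integer; identical seeds give identical forests.
#' @return an [IsolationForest-class] (cutoff not yet fitted; see
#'   [calibrateCutoff()]).
#' @export
fitIsolationForest <- function(train, psi = 256, heightLimit = 8,
                               nTrees = 100, seed = 1) {
    if (ncol(train) == 0) stop("empty table")
    if (psi < 2) stop("psi must be >= 2")
    x <- featureMatrix(train)
    n <- nrow(x)
    sampleSize <- min(as.integer(psi), n)
    trees <- withSeed(seed, lapply(seq_len(nTrees), function(i) {
        idx <- if (sampleSize < n) sample.int(n, sampleSize)
               else seq_len(n)
        growITree(x, idx, as.integer(heightLimit))
    }))
    methods::new("IsolationForest", trees = trees, psi = as.integer(psi),
                 heightLimit = as.integer(heightLimit),
                 nTrees = as.integer(nTrees), cn = cFactor(sampleSize),
                 featureNames = colnames(x), cutoff = numeric(0))
}

#' Anomaly scores from a fitted isolation forest
#'
#' \code{score(x) = 2^(-E[h(x)] / c(psi))} with the expectation over trees;
#' path lengths at truncated or multi-point leaves are extended by the
#' average-path correction \code{c(size)}. Scores lie in (0, 1]; larger
#' means more anomalous.
#'
#' @param model an [IsolationForest-class].
#' @param table a [BrainFeatureSet-class] whose feature names match training.
#' @return named numeric vector of scores (names = subject ids).
#' @export
scoreOutliers <- function(model, table) {
    x <- featureMatrix(table)
    if (!identical(colnames(x), model@featureNames))
        stop("feature-name mismatch between table and isolation forest")
    h <- rowMeans(vapply(model@trees, treePathLengths, numeric(nrow(x)),
                         x = x))
    setNames(2^(-h / model@cn), subjectIds(table))
}

#' Tukey-fence outlier cutoff
#'
#' \code{cutoff = Q3 + 3 * IQR} of the training anomaly scores, with
#' quartiles computed by linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param scores numeric vector of at least 4 training scores.
#' @return the cutoff threshold.
#' @export
tukeyCutoff <- function(scores) {
    if (length(scores) < 4) stop("need at least 4 scores")
    q <- quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] + 3 * (q[2] - q[1])
}

#' Score training data and store the Tukey cutoff in the model
#'
#' @param model an [IsolationForest-class].
#' @param train the training [BrainFeatureSet-class] the forest was fitted
#'   on.
#' @return the model with its \code{cutoff} slot fitted.
#' @export
calibrateCutoff <- function(model, train) {
    model@cutoff <- as.numeric(tukeyCutoff(scoreOutliers(model, train)))
    model
}

#' Partition a table into kept and removed rows by anomaly score
#'
#' A record is removed iff its score is strictly greater than the threshold
#' (a score exactly equal to the cutoff is kept). kept and removed partition
#' the input.
#'
#' @param table a [BrainFeatureSet-class].
#' @param scores anomaly scores aligned with the table rows.
#' @param threshold the fitted cutoff.
#' @return list with elements \code{kept} and \code{removed}.
#' @export
filterOutliers <- function(table, scores, threshold) {
    if (length(scores) != ncol(table))
        stop("scores length does not match table rows")
    out <- scores > threshold
    list(kept = subsetSubjects(table, !out),
         removed = subsetSubjects(table, out))
}
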