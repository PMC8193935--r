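# Logistic AD/CN classification on (age, ABA) and the per-feature score
# decomposition that explains each prediction.

# ridge-penalized logistic regression by IRLS (penalty on non-intercept
# terms); finite coefficients even under perfect separation or single-
# observation classes
ridgeLogistic <- function(X, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
    P <- diag(c(0, rep(1, ncol(X) - 1)))
    beta <- numeric(ncol(X))
    for (i in seq_len(maxit)) {
        eta <- as.numeric(X %*% beta)
        p <- plogis(eta)
        w <- pmax(p * (1 - p), 1e-10)
        grad <- crossprod(X, y - p) - lambda * P %*% beta
        H <- crossprod(X * w, X) + lambda * P
        delta <- solve(H, grad)
        beta <- beta + as.numeric(delta)
        if (max(abs(delta)) < tol) break
    }
    beta
}

#' Fit the logistic AD/CN classifier on (age, ABA)
#'
#' Maximum-likelihood logistic regression of the AD label on chronological
#' age and Apparent Brain Age, both in years, over the outer-training
#' subjects. Coefficients are stored as (c0, c1, c2) with the convention
#' that a subject is classified AD when \code{c0 + c1*age + c2*aba < 0}
#' (the negated GLM coefficients). Under perfect separation the fit falls
#' back to a small ridge penalty with a warning.
#'
#' @param preds training data.frame with columns age, aba, group (from
#'   [predictAba()]).
#' @return a [ClassifierModel-class].
#' @export
fitClassifier <- function(preds) {
    if (length(unique(preds$group)) != 2)
        stop("both classes must be present")
    y <- as.numeric(preds$group == "AD")
    separated <- FALSE
    fit <- withCallingHandlers(
        glm(y ~ age + aba, data = preds, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)) ||
                grepl("did not converge", conditionMessage(w)))
                separated <<- TRUE
            invokeRestart("muffleWarning")
        })
    b <- coef(fit)
    if (separated || any(!is.finite(b)) || max(abs(b)) > 1e3) {
        warning("perfect separation detected; refitting with a small ridge ",
                "penalty")
        b <- ridgeLogistic(cbind(1, preds$age, preds$aba), y)
        ridge <- TRUE
    } else {
        ridge <- FALSE
    }
    methods::new("ClassifierModel",
                 coefficients = setNames(-as.numeric(b),
                                         c("c0", "c1", "c2")),
                 ridge = ridge)
}

#' Predict the diagnosis label and AD probability
#'
#' The label comes from the sign of the linear score
#' \code{c0 + c1*age + c2*aba}: AD when strictly negative, CN otherwise
#' (a subject exactly on the boundary is classified CN). The AD probability
#' is the logistic link applied to the negated score.
#'
#' @param model a [ClassifierModel-class].
#' @param age,aba numeric vectors (years).
#' @return data.frame with columns label, probability (of AD), score.
#' @export
predictDiagnosis <- function(model, age, aba) {
    co <- model@coefficients
    score <- co["c0"] + co["c1"] * age + co["c2"] * aba
    data.frame(label = ifelse(score < 0, "AD", "CN"),
               probability = plogis(-score),
               score = as.numeric(score),
               stringsAsFactors = FALSE)
}

#' Per-feature score decomposition of a classification
#'
#' For each subject, the contribution of support feature i to the
#' classification rule is \code{s_i = -c2 * a_i * f_i / D} with
#' \code{D = c0 + c1*age + c2*a0}. The linear boundary value satisfies
#' \code{boundary = D * (1 - sum(s_i))}, so the score sum reproduces the
#' classification decision exactly whenever D != 0 (see [scoreDecision()]).
#' A high positive score flags a feature contributing toward the AD side;
#' negative or low scores indicate the absence of abnormal atrophy in that
#' region. Subjects with D == 0 are flagged boundary-degenerate and their
#' scores are undefined.
#'
#' @param clf a [ClassifierModel-class].
#' @param abaModel the [AbaModel-class] that produced ABA.
#' @param table a standardized [BrainFeatureSet-class].
#' @return a list of [FeatureScoreReport-class], one per subject.
#' @export
featureScores <- function(clf, abaModel, table) {
    co <- clf@coefficients
    a <- abaModel@coefficients
    preds <- predictAba(abaModel, table)
    dec <- predictDiagnosis(clf, preds$age, preds$aba)
    x <- if (length(a) > 0)
        featureMatrix(table)[, names(a), drop = FALSE]
    else matrix(0, ncol(table), 0)
    lapply(seq_len(ncol(table)), function(i) {
        D <- as.numeric(co["c0"] + co["c1"] * preds$age[i] +
                        co["c2"] * abaModel@intercept)
        degenerate <- D == 0
        s <- if (degenerate || length(a) == 0) setNames(numeric(0), NULL)
             else setNames(-co[["c2"]] * a * x[i, ] / D, names(a))
        if (degenerate)
            warning("boundary-degenerate subject (D = 0): ",
                    preds$subject_id[i])
        methods::new("FeatureScoreReport",
                     subjectId = preds$subject_id[i], age = preds$age[i],
                     scores = s, denominator = D,
                     sumScores = if (degenerate) NA_real_ else sum(s),
                     boundary = dec$score[i], decision = dec$label[i],
                     degenerate = degenerate)
    })
}

#' Classification decision from the feature-score sum
#'
#' Algebraically identical to the logistic boundary rule: since
#' \code{boundary = D * (1 - sum(s_i))}, the decision is AD iff
#' \code{sum(s_i) > 1} when D > 0 and iff \code{sum(s_i) < 1} when D < 0.
#' A score sum of exactly 1 lies on the boundary and is classified CN.
#'
#' @param report a [FeatureScoreReport-class] with D != 0.
#' @return "AD" or "CN".
#' @export
scoreDecision <- function(report) {
    D <- report@denominator
    if (report@degenerate || D == 0)
        stop("boundary-degenerate subject: scores undefined (D = 0)")
    s <- report@sumScores
    if ((D > 0 && s > 1) || (D < 0 && s < 1)) "AD" else "CN"
}

#' Quartile context of training feature scores per group
#'
#' Five-number summaries (min, Q1, median, Q3, max; type-7 quantiles) of the
#' per-feature scores of the AD and CN training subjects. Used as the
#' reference boxes against which a test subject's scores are read.
#'
#' @param reports list of [FeatureScoreReport-class] for training subjects
#'   (all from the same model pair).
#' @param labels "AD"/"CN" group per report.
#' @return data.frame with columns feature, group, min, q1, median, q3, max.
#' @export
quartileContext <- function(reports, labels) {
    stopifnot(length(reports) == length(labels))
    keep <- !vapply(reports, function(r) r@degenerate, logical(1))
    reports <- reports[keep]
    labels <- labels[keep]
    feats <- names(reports[[1]]@scores)
    out <- list()
    for (grp in c("AD", "CN")) {
        idx <- which(labels == grp)
        if (length(idx) < 4)
            stop("need at least 4 training subjects in group ", grp)
        m <- do.call(rbind, lapply(reports[idx], function(r)
            r@scores[feats]))
        q <- apply(m, 2, quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                   type = 7, names = FALSE)
        out[[grp]] <- data.frame(feature = feats, group = grp,
                                 min = q[1, ], q1 = q[2, ], median = q[3, ],
                                 q3 = q[4, ], max = q[5, ],
                                 row.names = NULL, stringsAsFactors = FALSE)
    }
    rbind(out$AD, out$CN)
}

#' Long-format feature-score table
#'
#' One row per subject-feature pair, suitable for CSV emission and box-plot
#' rendering; optionally joined with the training quartile context.
#'
#' @param reports list of [FeatureScoreReport-class].
#' @param context optional quartile table from [quartileContext()].
#' @return data.frame with columns subject_id, decision, feature, score and,
#'   when context is given, the per-group quartile columns.
#' @export
featureScoreTable <- function(reports, context = NULL) {
    rows <- lapply(reports, function(r) {
        if (r@degenerate || length(r@scores) == 0) return(NULL)
        data.frame(subject_id = r@subjectId, decision = r@decision,
                   feature = names(r@scores), score = as.numeric(r@scores),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(context) && !is.null(tab)) {
        wide <- stats::reshape(
            context, direction = "wide", idvar = "feature",
            timevar = "group", v.names = c("min", "q1", "median", "q3",
                                           "max"))
        tab <- merge(tab, wide, by = "feature", sort = FALSE)
    }
    tab
}
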