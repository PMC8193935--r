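# Apparent Brain Age: LASSO regression of chronological age on standardized
# morphometric features, trained on cognitively normal subjects only.

# single-lambda LASSO via glmnet; intercept unpenalized, no internal
# re-standardization (features are already z-scored upstream). glmnet needs
# >= 2 columns, so a single offered feature is padded with an all-zero dummy.
lassoFit <- function(x, y, lambda) {
    x <- as.matrix(x)
    nm <- colnames(x)
    padded <- ncol(x) == 1
    if (padded) x <- cbind(x, `..pad` = 0)
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-12, maxit = 1e6)
    co <- as.numeric(coef(fit))
    beta <- co[-1]
    if (padded) beta <- beta[1]
    list(intercept = co[1], beta = setNames(beta, nm))
}

#' Fit the Apparent Brain Age LASSO model on CN training subjects
#'
#' Minimizes the squared error of age predictions plus an L1 penalty on the
#' feature coefficients (intercept unpenalized), on cognitively normal
#' training subjects only. \code{penalty = "auto"} selects the penalty by
#' k-fold cross-validated mean absolute error on the CN training set over
#' glmnet's logarithmic lambda grid. The nonzero support defines the
#' embedded selection F2 (a subset of the offered set F1).
#'
#' @param train_cn a standardized [BrainFeatureSet-class] containing only CN
#'   rows.
#' @param offered character vector F1 of features to offer (>= 1).
#' @param penalty "auto" or a fixed non-negative penalty (glmnet lambda
#'   scale, i.e. the objective is RSS/(2n) + lambda * sum(|a_i|)).
#' @param cvFolds folds for the "auto" penalty search.
#' @param seed integer seed for the penalty-search fold assignment.
#' @return an [AbaModel-class].
#' @export
fitAba <- function(train_cn, offered, penalty = "auto", cvFolds = 5,
                   seed = 1) {
    g <- groups(train_cn)
    if (length(g) == 0) stop("empty CN training set")
    if (any(g != "CN")) stop("train_cn must contain only CN rows")
    offered <- as.character(offered)
    if (length(offered) < 1) stop("at least one offered feature is required")
    x <- featureMatrix(train_cn)
    bad <- setdiff(offered, colnames(x))
    if (length(bad) > 0)
        stop("offered feature(s) absent from table: ",
             paste(bad, collapse = ", "))
    x <- x[, offered, drop = FALSE]
    y <- ages(train_cn)
    if (identical(penalty, "auto")) {
        xcv <- if (ncol(x) == 1) cbind(x, `..pad` = 0) else x
        foldid <- withSeed(seed, sample(rep_len(seq_len(cvFolds), nrow(x))))
        cvfit <- glmnet::cv.glmnet(xcv, y, alpha = 1, type.measure = "mae",
                                   foldid = foldid, standardize = FALSE,
                                   intercept = TRUE)
        lambda <- cvfit$lambda.min
    } else {
        lambda <- as.numeric(penalty)
        if (!is.finite(lambda) || lambda < 0)
            stop("penalty must be 'auto' or a non-negative number")
    }
    fit <- lassoFit(x, y, lambda)
    beta <- fit$beta[fit$beta != 0]
    if (length(beta) == 0)
        message("fitAba: all coefficients shrunk to zero; ",
                "intercept-only model (a0 = ", signif(fit$intercept, 5), ")")
    methods::new("AbaModel", intercept = fit$intercept, coefficients = beta,
                 penalty = lambda, offered = offered,
                 nTrain = nrow(x))
}

#' Predict Apparent Brain Age and the Age Deviation Score
#'
#' \code{aba = a0 + sum_i a_i * f_i} over the model support, and
#' \code{ads = aba - age}. The table must be standardized with the same
#' training-partition standardization model as the ABA training data.
#'
#' @param model an [AbaModel-class].
#' @param table a standardized [BrainFeatureSet-class] containing all support
#'   features.
#' @return data.frame with columns subject_id, group, age, aba, ads.
#' @export
predictAba <- function(model, table) {
    supp <- names(model@coefficients)
    bad <- setdiff(supp, featureNames(table))
    if (length(bad) > 0)
        stop("support feature(s) missing from table: ",
             paste(bad, collapse = ", "))
    aba <- rep(model@intercept, ncol(table))
    if (length(supp) > 0) {
        x <- featureMatrix(table)[, supp, drop = FALSE]
        aba <- aba + as.numeric(x %*% model@coefficients)
    }
    data.frame(subject_id = subjectIds(table), group = groups(table),
               age = ages(table), aba = aba, ads = aba - ages(table),
               stringsAsFactors = FALSE)
}

#' Age-regression quality within a diagnostic group
#'
#' Mean absolute error (years) and Pearson correlation between predicted
#' ABA and chronological age, within one group.
#'
#' @param preds prediction data.frame from [predictAba()].
#' @param group "AD" or "CN".
#' @return list with elements \code{mae} and \code{r}; r is NaN (with a
#'   warning) when either variable has zero variance.
#' @export
regressionMetrics <- function(preds, group) {
    p <- preds[preds$group == group, , drop = FALSE]
    if (nrow(p) < 2) stop("need at least 2 subjects in group ", group)
    mae <- mean(abs(p$aba - p$age))
    if (var(p$aba) == 0 || var(p$age) == 0) {
        warning("zero variance in aba or age; r undefined")
        r <- NaN
    } else {
        r <- cor(p$aba, p$age)
    }
    list(mae = mae, r = r)
}
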