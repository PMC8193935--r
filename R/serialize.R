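# JSON serialization of fitted models. Numbers are written at full IEEE
# precision (digits = NA) so a round trip reproduces predictions bit-exactly.

modelToList <- function(object) {
    if (methods::is(object, "StandardizationModel")) {
        list(class = "StandardizationModel",
             features = lapply(setNames(seq_along(object@mean),
                                        names(object@mean)),
                               function(i) list(mean = object@mean[[i]],
                                                sd = object@sd[[i]])))
    } else if (methods::is(object, "AbaModel")) {
        list(class = "AbaModel", a0 = object@intercept,
             coefficients = as.list(object@coefficients),
             penalty = object@penalty, offered = as.list(object@offered),
             nTrain = object@nTrain)
    } else if (methods::is(object, "ClassifierModel")) {
        list(class = "ClassifierModel",
             c0 = object@coefficients[["c0"]],
             c1 = object@coefficients[["c1"]],
             c2 = object@coefficients[["c2"]],
             ridge = object@ridge)
    } else if (methods::is(object, "IsolationForest")) {
        list(class = "IsolationForest", psi = object@psi,
             heightLimit = object@heightLimit, nTrees = object@nTrees,
             cn = object@cn, featureNames = as.list(object@featureNames),
             cutoff = if (length(object@cutoff)) object@cutoff else NULL,
             trees = lapply(object@trees, function(tr)
                 list(feature = tr$feature, value = tr$value,
                      left = tr$left, right = tr$right, size = tr$size)))
    } else if (methods::is(object, "SelectionTrace")) {
        list(class = "SelectionTrace",
             selected = as.list(object@selected),
             trace = as.list(object@trace))
    } else if (inherits(object, "AbaPipeline")) {
        list(class = "AbaPipeline", method = object$method,
             standardizer = modelToList(object$standardizer),
             forest = if (is.null(object$forest)) NULL
                      else modelToList(object$forest),
             ranking = as.list(object$ranking),
             selection = if (is.null(object$selection)) NULL
                         else modelToList(object$selection),
             aba = modelToList(object$aba),
             classifier = modelToList(object$classifier))
    } else stop("unsupported model class: ", paste(class(object),
                                                   collapse = "/"))
}

listToModel <- function(x) {
    asNum <- function(v) if (is.null(v)) numeric(0) else
        vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
               numeric(1))
    asInt <- function(v) if (is.null(v)) integer(0) else
        vapply(v, function(e) if (is.null(e)) NA_integer_ else as.integer(e),
               integer(1))
    asChr <- function(v) if (is.null(v)) character(0) else
        vapply(v, as.character, character(1))
    switch(x$class,
        StandardizationModel = {
            mu <- vapply(x$features, function(f) f$mean, numeric(1))
            s <- vapply(x$features, function(f) f$sd, numeric(1))
            methods::new("StandardizationModel", mean = mu, sd = s)
        },
        AbaModel = {
            co <- asNum(x$coefficients)
            names(co) <- names(x$coefficients)
            methods::new("AbaModel", intercept = as.numeric(x$a0),
                         coefficients = co, penalty = as.numeric(x$penalty),
                         offered = asChr(x$offered),
                         nTrain = as.integer(x$nTrain))
        },
        ClassifierModel = methods::new(
            "ClassifierModel",
            coefficients = c(c0 = as.numeric(x$c0), c1 = as.numeric(x$c1),
                             c2 = as.numeric(x$c2)),
            ridge = isTRUE(x$ridge)),
        IsolationForest = methods::new(
            "IsolationForest",
            trees = lapply(x$trees, function(tr)
                data.frame(feature = asInt(tr$feature),
                           value = asNum(tr$value), left = asInt(tr$left),
                           right = asInt(tr$right), size = asInt(tr$size))),
            psi = as.integer(x$psi),
            heightLimit = as.integer(x$heightLimit),
            nTrees = as.integer(x$nTrees), cn = as.numeric(x$cn),
            featureNames = asChr(x$featureNames),
            cutoff = if (is.null(x$cutoff)) numeric(0)
                     else as.numeric(x$cutoff)),
        SelectionTrace = methods::new(
            "SelectionTrace", selected = asChr(x$selected),
            trace = data.frame(
                feature = asChr(x$trace$feature),
                rank = asInt(x$trace$rank), r = asNum(x$trace$r),
                accuracyWith = asNum(x$trace$accuracyWith),
                accuracyWithout = asNum(x$trace$accuracyWithout),
                accepted = vapply(x$trace$accepted, isTRUE, logical(1)),
                stringsAsFactors = FALSE)),
        AbaPipeline = structure(list(
            standardizer = listToModel(x$standardizer),
            forest = if (is.null(x$forest)) NULL else listToModel(x$forest),
            ranking = data.frame(feature = asChr(x$ranking$feature),
                                 r = asNum(x$ranking$r),
                                 absR = asNum(x$ranking$absR),
                                 stringsAsFactors = FALSE),
            selection = if (is.null(x$selection)) NULL
                        else listToModel(x$selection),
            aba = listToModel(x$aba),
            classifier = listToModel(x$classifier),
            method = x$method), class = "AbaPipeline"),
        stop("unknown model class in JSON: ", x$class))
}

#' Serialize a fitted model to JSON
#'
#' Supports [StandardizationModel-class] (feature name -> mean/sd),
#' [IsolationForest-class], [AbaModel-class] (a0, feature -> a_i, penalty),
#' [ClassifierModel-class], [SelectionTrace-class] and the \code{AbaPipeline}
#' bundle from [fitFinalModel()]. Full numeric precision is kept so
#' [readModelJSON()] reproduces predictions bit-exactly.
#'
#' @param object a supported model object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(object, path) {
    # digits = I(17): significant (not decimal) digits, enough to make the
    # decimal representation of any double round-trip exactly
    jsonlite::write_json(modelToList(object), path, auto_unbox = TRUE,
                         digits = I(17), null = "null", na = "null")
    invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
    listToModel(jsonlite::read_json(path, simplifyVector = FALSE))
}
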