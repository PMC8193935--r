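#' Construct a BrainFeatureSet from a subjects-by-features matrix
#'
#' @param features numeric matrix, subjects in rows, features in columns;
#'   column names are the feature names.
#' @param subject_id character vector of unique subject identifiers.
#' @param gender "M"/"F" per subject.
#' @param age chronological age in years (> 0).
#' @param group diagnosis label, "AD" or "CN".
#' @param cohort source-cohort tag (e.g. "ADNI", "AIBL", "IXI", "synthetic").
#' @return a validated [BrainFeatureSet-class].
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
#' bfs <- BrainFeatureSet(m, subject_id = c("s1", "s2", "s3"),
#'                        gender = c("M", "F", "M"), age = c(70, 75, 80),
#'                        group = c("AD", "CN", "CN"), cohort = "toy")
#' @export
BrainFeatureSet <- function(features, subject_id, gender, age, group,
                            cohort) {
    features <- as.matrix(features)
    if (nrow(features) != length(subject_id))
        stop("features must have one row per subject")
    n <- length(subject_id)
    cohort <- rep_len(as.character(cohort), n)
    gender <- rep_len(as.character(gender), n)
    cd <- S4Vectors::DataFrame(subject_id = as.character(subject_id),
                               gender = gender,
                               age = as.numeric(age),
                               group = as.character(group),
                               cohort = cohort,
                               row.names = as.character(subject_id))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(morphometry = t(features)), colData = cd)
    methods::new("BrainFeatureSet", se)
}

#' Accessors for BrainFeatureSet metadata and features
#'
#' \code{featureMatrix} returns the subjects-by-features numeric matrix;
#' \code{subjectIds}, \code{ages}, \code{genders}, \code{groups} and
#' \code{cohorts} return the per-subject metadata vectors;
#' \code{featureNames} returns the feature-name vector.
#'
#' @param x a [BrainFeatureSet-class]
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "morphometry"))

#' @rdname accessors
#' @export
subjectIds <- function(x) SummarizedExperiment::colData(x)$subject_id

#' @rdname accessors
#' @export
ages <- function(x) SummarizedExperiment::colData(x)$age

#' @rdname accessors
#' @export
genders <- function(x) SummarizedExperiment::colData(x)$gender

#' @rdname accessors
#' @export
groups <- function(x) SummarizedExperiment::colData(x)$group

#' @rdname accessors
#' @export
cohorts <- function(x) SummarizedExperiment::colData(x)$cohort

#' @rdname accessors
#' @export
featureNames <- function(x) rownames(x)

# subset by subject (column) index/logical/id, keeping all features
subsetSubjects <- function(x, idx) {
    methods::new("BrainFeatureSet", x[, idx])
}

#' Default metadata-column schema for feature-table files
#'
#' Maps the five required metadata fields to file column names. All other
#' columns in the file are treated as numeric features.
#'
#' @return named character vector with entries subject_id, gender, age,
#'   group, cohort.
#' @export
defaultSchema <- function() {
    c(subject_id = "subject_id", gender = "gender", age = "age",
      group = "group", cohort = "cohort")
}

#' Read a subject feature table from CSV/TSV
#'
#' The file must have a header. Columns named in \code{schema} become the
#' subject metadata; every other column is a numeric morphometric feature.
#' Validation errors (duplicate subject ids, non-numeric feature cells,
#' missing values, missing metadata columns, empty table) abort with a
#' message.
#'
#' @param path file path; ".tsv"/".txt" are read tab-separated, anything
#'   else comma-separated.
#' @param schema named character vector mapping the required fields to file
#'   column names, as from [defaultSchema()]. A YAML file with a
#'   \code{schema:} mapping is also accepted (path given as a string).
#' @return a [BrainFeatureSet-class].
#' @seealso [writeFeatureTable()]
#' @export
loadFeatureTable <- function(path, schema = defaultSchema()) {
    if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
        y <- yaml::read_yaml(schema)
        schema <- unlist(if (!is.null(y$schema)) y$schema else y)
    }
    schema <- schema[c("subject_id", "gender", "age", "group", "cohort")]
    if (anyNA(schema))
        stop("schema must name all of subject_id, gender, age, group, cohort")
    sep_tab <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)
    # metadata columns must never be type-guessed ("F" would parse as FALSE)
    cc <- setNames(rep("character", 4),
                   unname(schema[c("subject_id", "gender", "group",
                                   "cohort")]))
    df <- withCallingHandlers(
        if (sep_tab) read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE, colClasses = cc)
        else read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = cc),
        warning = function(w) {
            # a metadata column may be absent; that is reported as an error
            # with the column's name below, not as a colClasses warning
            if (grepl("colClasses", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    if (nrow(df) == 0) stop("empty table: ", path)
    missing_cols <- setdiff(unname(schema), colnames(df))
    if (length(missing_cols) > 0)
        stop("missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    ids <- as.character(df[[schema["subject_id"]]])
    if (anyDuplicated(ids))
        stop("duplicate subject_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    feat_cols <- setdiff(colnames(df), unname(schema))
    if (length(feat_cols) == 0) stop("no feature columns found")
    bad <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
    if (length(bad) > 0)
        stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
    m <- as.matrix(df[feat_cols])
    rownames(m) <- NULL
    BrainFeatureSet(m, subject_id = ids,
                    gender = df[[schema["gender"]]],
                    age = df[[schema["age"]]],
                    group = df[[schema["group"]]],
                    cohort = df[[schema["cohort"]]])
}

#' Write a BrainFeatureSet to CSV/TSV
#'
#' Writes metadata columns followed by all feature columns. Doubles are
#' written with 17 significant digits so that [loadFeatureTable()]
#' round-trips every value exactly. Paths ending in ".tsv"/".txt" are
#' written tab-separated, matching the loader.
#'
#' @param x a [BrainFeatureSet-class]
#' @param path output path.
#' @param schema column-name map as in [loadFeatureTable()].
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path, schema = defaultSchema()) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
           else ","
    metaNames <- unname(schema[c("subject_id", "gender", "age", "group",
                                 "cohort")])
    fm <- featureMatrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c(metaNames, colnames(fm)), collapse = sep), con)
    meta <- paste(subjectIds(x), genders(x), sprintf("%.17g", ages(x)),
                  groups(x), cohorts(x), sep = sep)
    nums <- apply(fm, 1, function(r)
        paste(sprintf("%.17g", r), collapse = sep))
    writeLines(paste(meta, nums, sep = sep), con)
    invisible(path)
}

#' Split a feature table by gender
#'
#' The analysis pipeline runs on each gender group separately; this returns
#' the male and female partitions. Their union is the input table.
#'
#' @param x a [BrainFeatureSet-class]
#' @return named list with elements \code{M} and \code{F}.
#' @export
splitByGender <- function(x) {
    g <- genders(x)
    bad <- setdiff(unique(g), c("M", "F"))
    if (length(bad) > 0)
        stop("unknown gender code: ", paste(bad, collapse = ", "))
    list(M = subsetSubjects(x, g == "M"),
         F = subsetSubjects(x, g == "F"))
}
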