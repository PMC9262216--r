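#' Construct a FeatureTable from a subjects-by-features matrix
#'
#' @param values numeric matrix, one row per subject, one column per
#'   feature.  Column names are the feature names; row names (or
#'   \code{subjectIds}) identify subjects.
#' @param outcome per-subject class labels (character or factor) with
#'   exactly two distinct levels.
#' @param targetClass the outcome level treated as the positive /
#'   target class (e.g. \code{"ASD"}).
#' @param subjectIds optional subject identifiers overriding
#'   \code{rownames(values)}; defaults to \code{S1..SN} when absent.
#' @param featureInfo optional data.frame with columns \code{kind}
#'   (behavioral/neuroanatomical/other), \code{measure} (volume, area,
#'   thickness, meancurv, score, other) and \code{units}, one row per
#'   feature.  Defaults to \code{kind = "other"}.
#'
#' @return a validated [FeatureTable-class].
#' @examples
#' vals <- matrix(rnorm(12), 4, 3,
#'                dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
#' ft <- featureTable(vals, outcome = c("A", "A", "B", "B"),
#'                    targetClass = "A")
#' nSubjects(ft)
#' @export
featureTable <- function(values, outcome, targetClass, subjectIds = NULL,
                         featureInfo = NULL) {
    stopIf(!is.matrix(values) || !is.numeric(values),
           "'values' must be a numeric matrix (subjects x features)")
    n <- nrow(values); p <- ncol(values)
    if (is.null(subjectIds))
        subjectIds <- rownames(values)
    if (is.null(subjectIds))
        subjectIds <- paste0("S", seq_len(n))
    stopIf(length(subjectIds) != n, "need one subject id per row")
    stopIf(is.null(colnames(values)), "'values' must have feature names")
    stopIf(length(outcome) != n, "need one outcome label per subject")
    outcome <- factor(as.character(outcome))
    if (is.null(featureInfo))
        featureInfo <- data.frame(kind = rep("other", p),
                                  measure = rep("other", p),
                                  units = rep("", p))
    for (col in c("kind", "measure", "units"))
        if (!col %in% colnames(featureInfo))
            featureInfo[[col]] <- if (col == "units") "" else "other"
    rd <- S4Vectors::DataFrame(featureInfo[, c("kind", "measure", "units")])
    rownames(rd) <- colnames(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = t(values)),
        rowData = rd,
        colData = S4Vectors::DataFrame(outcome = outcome,
                                       row.names = subjectIds))
    S4Vectors::metadata(se)$targetClass <- targetClass
    methods::new("FeatureTable", se)
}

#' Accessors for FeatureTable objects
#'
#' \code{featureValues} returns the subjects-by-features numeric matrix
#' (the transpose of the stored assay); \code{outcome} the per-subject
#' factor; \code{targetClass}/\code{otherClass} the positive and
#' negative outcome levels; \code{subjectIds} and \code{featureNames}
#' the identifiers; \code{classCounts} a named count of subjects per
#' outcome level, target class first.
#'
#' @param x a [FeatureTable-class].
#' @param ... ignored.
#' @name FeatureTable-accessors
#' @aliases featureValues outcome targetClass otherClass subjectIds
#'   nSubjects nFeatures classCounts
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x, ...)
    t(SummarizedExperiment::assay(x, "values")))

#' @rdname FeatureTable-accessors
#' @export
setMethod("outcome", "FeatureTable", function(x, ...)
    SummarizedExperiment::colData(x)$outcome)

#' @rdname FeatureTable-accessors
#' @export
setMethod("targetClass", "FeatureTable", function(x, ...)
    S4Vectors::metadata(x)$targetClass)

#' @rdname FeatureTable-accessors
#' @export
setMethod("otherClass", "FeatureTable", function(x, ...)
    setdiff(levels(outcome(x)), targetClass(x)))

#' @rdname FeatureTable-accessors
#' @export
setMethod("subjectIds", "FeatureTable", function(x, ...) colnames(x))

#' @rdname FeatureTable-accessors
#' @export
setMethod("nSubjects", "FeatureTable", function(x) ncol(x))

#' @rdname FeatureTable-accessors
#' @export
setMethod("nFeatures", "FeatureTable", function(x) nrow(x))

#' @rdname FeatureTable-accessors
#' @export
setMethod("classCounts", "FeatureTable", function(x) {
    tab <- table(outcome(x))
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts[c(targetClass(x), otherClass(x))]
})

#' @export
#' @describeIn FeatureTable-accessors compact display.
setMethod("show", "FeatureTable", function(object) {
    cc <- classCounts(object)
    cat(sprintf(
        "FeatureTable: %d subjects x %d features\n", nSubjects(object),
        nFeatures(object)))
    cat(sprintf("  outcome: %s (target) n=%d | %s n=%d\n",
                names(cc)[1], cc[1], names(cc)[2], cc[2]))
    kinds <- table(SummarizedExperiment::rowData(object)$kind)
    cat("  feature kinds:",
        paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
})

#' Read a subjects-by-features CSV into a FeatureTable
#'
#' Expects an RFC-4180-style comma-separated file with a header row, dot
#' decimal separators and UTF-8 encoding — the shape produced by
#' FreeSurfer's \code{aparcstats2table} exports once an id and an
#' outcome column are added.  Column order is preserved and defines the
#' feature index order used in all downstream reports.
#'
#' @param file path (or connection) to the CSV.
#' @param subjectCol,outcomeCol header names of the subject-id and
#'   outcome columns.
#' @param targetClass the outcome level to treat as the target class.
#' @param featureInfo optional per-feature metadata data.frame (see
#'   [featureTable()]); may also be the path of a JSON file mapping
#'   feature names to \code{kind}/\code{measure}/\code{units}.
#' @return a validated [FeatureTable-class].
#' @details Missing or non-numeric cells in feature columns are an
#'   error (naming the offending row and column): with cohorts of a few
#'   dozen subjects, silent imputation would corrupt clause intervals.
#' @export
readFeatureTable <- function(file, subjectCol = "subject_id",
                             outcomeCol = "outcome", targetClass,
                             featureInfo = NULL) {
    raw <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
    hdr <- colnames(raw)
    stopIf(anyDuplicated(hdr) > 0L, "duplicate column names in header: %s",
           paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    for (col in c(subjectCol, outcomeCol))
        stopIf(!col %in% hdr, "required column '%s' missing from header", col)
    featCols <- setdiff(hdr, c(subjectCol, outcomeCol))
    stopIf(length(featCols) == 0L, "no feature columns found")
    ids <- raw[[subjectCol]]
    stopIf(anyDuplicated(ids) > 0L, "duplicate subject ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- matrix(NA_real_, nrow(raw), length(featCols),
                   dimnames = list(ids, featCols))
    for (j in seq_along(featCols)) {
        cell <- raw[[featCols[j]]]
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(num) | !nzchar(trimws(cell)))
        stopIf(length(bad) > 0L,
               "non-numeric or empty value in column '%s', row %d ('%s')",
               featCols[j], bad[1], cell[bad[1]])
        vals[, j] <- num
    }
    oc <- raw[[outcomeCol]]
    stopIf(length(unique(oc)) != 2L,
           "outcome column '%s' must have exactly 2 levels, found %d",
           outcomeCol, length(unique(oc)))
    if (is.character(featureInfo) && length(featureInfo) == 1L) {
        meta <- jsonlite::read_json(featureInfo, simplifyVector = TRUE)
        featureInfo <- data.frame(
            kind = vapply(featCols, function(f)
                meta[[f]]$kind %||% "other", character(1)),
            measure = vapply(featCols, function(f)
                meta[[f]]$measure %||% "other", character(1)),
            units = vapply(featCols, function(f)
                meta[[f]]$units %||% "", character(1)))
    }
    featureTable(vals, outcome = oc, targetClass = targetClass,
                 subjectIds = ids, featureInfo = featureInfo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a FeatureTable to CSV
#'
#' Inverse of [readFeatureTable()]: values are written with 10
#' significant digits, which round-trips every table this package
#' produces.
#'
#' @param x a [FeatureTable-class].
#' @param file output path.
#' @inheritParams readFeatureTable
#' @export
writeFeatureTable <- function(x, file, subjectCol = "subject_id",
                              outcomeCol = "outcome") {
    vals <- featureValues(x)
    df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                     setNames(list(subjectIds(x)), subjectCol))
    for (f in rownames(x))
        df[[f]] <- format(vals[, f], digits = 10, trim = TRUE,
                          scientific = FALSE)
    df[[outcomeCol]] <- as.character(outcome(x))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Subset a FeatureTable to named features
#'
#' @param x a [FeatureTable-class].
#' @param features character vector of feature names to keep (order
#'   taken from the request).
#' @return a [FeatureTable-class] with only the named features; subjects
#'   and outcome unchanged.
#' @export
subsetFeatures <- function(x, features) {
    stopIf(length(features) == 0L, "an empty feature set is invalid")
    missing <- setdiff(features, rownames(x))
    stopIf(length(missing) > 0L, "unknown feature(s): %s",
           paste(missing, collapse = ", "))
    x[features, ]
}

#' Split a FeatureTable into a named cohort and its complement
#'
#' Used to carve a discovery cohort for clause search, or a balanced
#' training set for classification, out of the full table.
#'
#' @param x a [FeatureTable-class].
#' @param ids subject identifiers for the first table; must be a proper
#'   non-empty subset of \code{subjectIds(x)}.
#' @return a list with elements \code{selected} (exactly \code{ids}, in
#'   table order) and \code{remainder} (the complement).
#' @export
splitSubjects <- function(x, ids) {
    missing <- setdiff(ids, subjectIds(x))
    stopIf(length(missing) > 0L, "unknown subject id(s): %s",
           paste(missing, collapse = ", "))
    stopIf(length(ids) == 0L, "empty subject selection")
    keep <- subjectIds(x) %in% ids
    stopIf(all(keep), "selection covers all subjects; complement is empty")
    list(selected = x[, keep], remainder = x[, !keep])
}
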