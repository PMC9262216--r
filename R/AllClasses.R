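#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' FeatureTable: subjects-by-features data with a binary outcome
#'
#' A \code{FeatureTable} holds one numeric matrix of measurements for a
#' cohort of subjects together with a two-level nominal outcome (for
#' example ASD vs NT) and per-feature metadata.  It extends
#' \linkS4class{SummarizedExperiment}: features are rows, subjects are
#' columns, the single assay is named \code{"values"}, the outcome lives
#' in \code{colData(x)$outcome} and the designated target class in
#' \code{metadata(x)$targetClass}.  Per-feature metadata (\code{kind},
#' \code{measure}, \code{units}) lives in \code{rowData}.
#'
#' Validity requires: all assay values finite; unique non-empty feature
#' and subject names; an outcome factor with exactly two levels, each
#' with at least one subject; a target class that is one of the levels;
#' \code{kind} within \{behavioral, neuroanatomical, other\} and
#' \code{measure} within \{volume, area, thickness, meancurv, score,
#' other\}.
#'
#' @seealso [featureTable()], [readFeatureTable()], [subsetFeatures()],
#'   [splitSubjects()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

.FEATURE_KINDS <- c("behavioral", "neuroanatomical", "other")
.FEATURE_MEASURES <- c("volume", "area", "thickness", "meancurv", "score",
                       "other")

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "values"))
        msg <- c(msg, "assay must be a single matrix named 'values'")
    v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "all feature values must be finite numbers")
    fn <- rownames(object)
    if (is.null(fn) || anyDuplicated(fn) || any(!nzchar(fn)))
        msg <- c(msg, "feature names must be unique and non-empty")
    sn <- colnames(object)
    if (is.null(sn) || anyDuplicated(sn) || any(!nzchar(sn)))
        msg <- c(msg, "subject identifiers must be unique and non-empty")
    oc <- SummarizedExperiment::colData(object)$outcome
    if (is.null(oc) || !is.factor(oc) || nlevels(oc) != 2L) {
        msg <- c(msg, "colData must contain a two-level factor 'outcome'")
    } else {
        if (any(table(oc) < 1L))
            msg <- c(msg, "each outcome class needs at least one subject")
        tc <- S4Vectors::metadata(object)$targetClass
        if (is.null(tc) || length(tc) != 1L || !tc %in% levels(oc))
            msg <- c(msg, "metadata targetClass must be one outcome level")
    }
    rd <- SummarizedExperiment::rowData(object)
    for (col in c("kind", "measure")) {
        allowed <- if (col == "kind") .FEATURE_KINDS else .FEATURE_MEASURES
        if (!col %in% colnames(rd) || !all(rd[[col]] %in% allowed))
            msg <- c(msg, sprintf("rowData '%s' must be one of: %s",
                                  col, paste(allowed, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' ConjunctiveClause: a logical AND of feature-interval conditions
#'
#' A conjunctive clause is a set of conjuncts, each pairing a feature
#' with a closed numeric interval.  A subject matches the clause when
#' every conjunct holds, i.e. each named feature value lies within its
#' interval (boundaries included).  The number of conjuncts is the
#' clause \emph{order}; lower order means a more parsimonious model.
#' Conjuncts are stored sorted by feature name, which defines the
#' canonical form used for equality and de-duplication.
#'
#' @slot features character vector of distinct feature names.
#' @slot lower,upper numeric interval bounds, \code{lower <= upper}.
#' @seealso [conjunctiveClause()], [clauseMatches()], [evaluateClause()]
#' @export
setClass("ConjunctiveClause",
         representation(features = "character",
                        lower = "numeric",
                        upper = "numeric"))

setValidity("ConjunctiveClause", function(object) {
    msg <- character()
    p <- length(object@features)
    if (p < 1L)
        msg <- c(msg, "a clause needs at least one conjunct")
    if (length(object@lower) != p || length(object@upper) != p)
        msg <- c(msg, "features, lower and upper must have equal length")
    if (anyDuplicated(object@features))
        msg <- c(msg, "feature names within a clause must be distinct")
    if (any(!nzchar(object@features)))
        msg <- c(msg, "feature names must be non-empty")
    if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
        msg <- c(msg, "interval bounds must be finite")
    else if (any(object@lower > object@upper))
        msg <- c(msg, "each interval needs lower <= upper")
    if (is.unsorted(object@features, strictly = TRUE) && p > 1L)
        msg <- c(msg, "conjuncts must be sorted by feature name")
    if (length(msg)) msg else TRUE
})

#' PlantedRule: a ground-truth conjunctive rule for synthetic cohorts
#'
#' Couples a [ConjunctiveClause-class] with the class label whose
#' subjects are guaranteed (up to the generator's leakage) to satisfy
#' it.  Returned by the synthetic-cohort generators alongside the table
#' so downstream recovery can be checked against ground truth.
#'
#' @slot clause the planted [ConjunctiveClause-class] (order 1 to 5).
#' @slot targetClass the class whose members satisfy the rule.
#' @seealso [plantedRule()], [generateCohort()]
#' @export
setClass("PlantedRule",
         representation(clause = "ConjunctiveClause",
                        targetClass = "character"))

setValidity("PlantedRule", function(object) {
    msg <- character()
    if (length(object@targetClass) != 1L || !nzchar(object@targetClass))
        msg <- c(msg, "targetClass must be a single non-empty label")
    if (length(object@clause@features) > 5L)
        msg <- c(msg, "planted rules are restricted to order 1..5")
    if (length(msg)) msg else TRUE
})

#' ClauseMetrics: evaluation of a clause against a cohort
#'
#' Match counts and derived scores for one clause on one
#' [FeatureTable-class]: out of \code{nTotal} subjects of which
#' \code{nClass} belong to the target class, the clause matches
#' \code{nMatch} subjects, \code{kMatch} of them in the target class.
#' \code{pmf} is the hypergeometric probability of that configuration,
#' \code{fitness = -log10(pmf)}, \code{ppv = kMatch/nMatch} (NA when the
#' clause matches nobody), and \code{classCoverage = kMatch/nClass}.
#' \code{sensitivity} holds per-feature fitness contributions once
#' [featureSensitivity()] has been run (empty before that).
#'
#' @seealso [evaluateClause()], [hypergeomPmf()], [featureSensitivity()]
#' @export
setClass("ClauseMetrics",
         representation(nTotal = "integer", nClass = "integer",
                        nMatch = "integer", kMatch = "integer",
                        pmf = "numeric", fitness = "numeric",
                        ppv = "numeric", classCoverage = "numeric",
                        sensitivity = "numeric"))

setValidity("ClauseMetrics", function(object) {
    msg <- character()
    n <- object@nMatch; k <- object@kMatch
    if (k < 0L || k > min(n, object@nClass) || n > object@nTotal)
        msg <- c(msg, "need 0 <= kMatch <= min(nMatch, nClass), nMatch <= nTotal")
    if (object@pmf <= 0 || object@pmf > 1)
        msg <- c(msg, "pmf must lie in (0, 1]")
    if (object@fitness < 0)
        msg <- c(msg, "fitness must be >= 0")
    if (n == 0L) {
        if (!is.na(object@ppv))
            msg <- c(msg, "ppv must be NA (undefined) when nMatch is 0")
    } else if (is.na(object@ppv) || abs(object@ppv - k / n) > 1e-12) {
        msg <- c(msg, "ppv must equal kMatch/nMatch")
    }
    if (abs(object@classCoverage - k / object@nClass) > 1e-12)
        msg <- c(msg, "classCoverage must equal kMatch/nClass")
    if (length(msg)) msg else TRUE
})

#' ClauseArchive: best unique clauses retained per order
#'
#' The elitist archive kept by [runCCEA()]: for every clause order up to
#' \code{maxOrder}, the highest-fitness unique clauses that pass the
#' per-feature sensitivity criterion, together with their metrics and
#' provenance (run index and generation of first discovery).  Entries
#' are sorted by descending fitness with ties broken by lower order,
#' then lexicographic canonical form.
#'
#' @seealso [runCCEA()], [archiveTable()], [selectParsimonious()],
#'   [bestClause()]
#' @export
setClass("ClauseArchive",
         representation(entries = "list", maxOrder = "integer",
                        archiveSize = "integer",
                        sensitivityThreshold = "numeric"))

setValidity("ClauseArchive", function(object) {
    keys <- vapply(object@entries, function(e) e$key, character(1))
    if (anyDuplicated(keys))
        return("archive entries must be unique canonical clauses")
    TRUE
})

#' ConfusionMatrix: 2x2 counts from binary classification
#'
#' Counts of true/false positives and negatives with the target class as
#' positive.  Derived scores (accuracy, positive predictive value,
#' recall) come from [matrixMetrics()].
#'
#' @slot tp,fn,fp,tn non-negative integer counts.
#' @slot targetClass,otherClass the positive and negative labels.
#' @seealso [confusionMatrix()], [matrixMetrics()], [loocv()],
#'   [trainTestClassify()]
#' @export
setClass("ConfusionMatrix",
         representation(tp = "integer", fn = "integer",
                        fp = "integer", tn = "integer",
                        targetClass = "character",
                        otherClass = "character"))

setValidity("ConfusionMatrix", function(object) {
    counts <- c(object@tp, object@fn, object@fp, object@tn)
    if (any(counts < 0L))
        return("confusion-matrix counts must be non-negative")
    if (sum(counts) < 1L)
        return("confusion matrix must count at least one prediction")
    TRUE
})
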