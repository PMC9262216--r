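#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("outcome", function(x, ...) standardGeneric("outcome"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("targetClass", function(x, ...) standardGeneric("targetClass"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("otherClass", function(x, ...) standardGeneric("otherClass"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname ConjunctiveClause-accessors
#' @export
setGeneric("clauseFeatures", function(x) standardGeneric("clauseFeatures"))

#' @rdname ConjunctiveClause-accessors
#' @export
setGeneric("clauseIntervals", function(x) standardGeneric("clauseIntervals"))

#' @rdname ConjunctiveClause-accessors
#' @export
setGeneric("clauseOrder", function(x) standardGeneric("clauseOrder"))

#' @rdname ConjunctiveClause-accessors
#' @export
setGeneric("canonicalKey", function(x) standardGeneric("canonicalKey"))

#' @rdname ClauseMetrics-accessors
#' @export
setGeneric("fitness", function(x) standardGeneric("fitness"))

#' @rdname ClauseMetrics-accessors
#' @export
setGeneric("ppv", function(x) standardGeneric("ppv"))

#' @rdname ClauseMetrics-accessors
#' @export
setGeneric("classCoverage", function(x) standardGeneric("classCoverage"))

#' @rdname ClauseArchive
#' @export
setGeneric("archiveTable", function(x, ...) standardGeneric("archiveTable"))

#' @rdname bestClause
#' @export
setGeneric("bestClause", function(x, ...) standardGeneric("bestClause"))
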