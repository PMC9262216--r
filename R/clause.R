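#' Construct a conjunctive clause
#'
#' @param features character vector of distinct feature names.
#' @param lower,upper numeric bounds of the closed interval attached to
#'   each feature (recycled scalar allowed); \code{lower <= upper}.
#' @return a [ConjunctiveClause-class] in canonical form (conjuncts
#'   sorted by feature name).
#' @examples
#' cc <- conjunctiveClause(
#'     c("lh_posteriorcingulate_volume", "lh_rostralmiddlefrontal_volume"),
#'     lower = c(3500, 20000), upper = c(4600, 25000))
#' clauseOrder(cc)
#' @export
conjunctiveClause <- function(features, lower, upper) {
    p <- length(features)
    lower <- rep_len(as.numeric(lower), p)
    upper <- rep_len(as.numeric(upper), p)
    ord <- order(features)
    methods::new("ConjunctiveClause", features = as.character(features)[ord],
                 lower = lower[ord], upper = upper[ord])
}

#' Accessors for ConjunctiveClause objects
#'
#' \code{clauseFeatures} returns the conjunct feature names,
#' \code{clauseIntervals} a two-column matrix of bounds,
#' \code{clauseOrder} the number of conjuncts and \code{canonicalKey} a
#' string identifying the clause up to conjunct order (used for
#' de-duplication and archive membership).
#'
#' @param x a [ConjunctiveClause-class].
#' @name ConjunctiveClause-accessors
NULL

#' @rdname ConjunctiveClause-accessors
#' @export
setMethod("clauseFeatures", "ConjunctiveClause", function(x) x@features)

#' @rdname ConjunctiveClause-accessors
#' @export
setMethod("clauseIntervals", "ConjunctiveClause", function(x) {
    m <- cbind(lower = x@lower, upper = x@upper)
    rownames(m) <- x@features
    m
})

#' @rdname ConjunctiveClause-accessors
#' @export
setMethod("clauseOrder", "ConjunctiveClause", function(x)
    length(x@features))

#' @rdname ConjunctiveClause-accessors
#' @export
setMethod("canonicalKey", "ConjunctiveClause", function(x)
    paste(sprintf("%s:[%.15g,%.15g]", x@features, x@lower, x@upper),
          collapse = " & "))

#' @export
#' @describeIn ConjunctiveClause-accessors display as a conjunction.
setMethod("show", "ConjunctiveClause", function(object) {
    cat(paste(sprintf("%s in [%g, %g]", object@features, object@lower,
                      object@upper),
              collapse = " AND "), "\n")
})

#' Which subjects satisfy a conjunctive clause?
#'
#' A subject matches when every conjunct's closed interval contains the
#' subject's value for that feature (boundaries count as inside).
#'
#' @param clause a [ConjunctiveClause-class].
#' @param table a [FeatureTable-class] containing every clause feature.
#' @return named logical vector, one element per subject.
#' @export
clauseMatches <- function(clause, table) {
    missing <- setdiff(clause@features, rownames(table))
    stopIf(length(missing) > 0L, "clause feature(s) absent from table: %s",
           paste(missing, collapse = ", "))
    vals <- featureValues(table)
    m <- rep(TRUE, nSubjects(table))
    for (i in seq_along(clause@features)) {
        v <- vals[, clause@features[i]]
        m <- m & v >= clause@lower[i] & v <= clause@upper[i]
    }
    names(m) <- subjectIds(table)
    m
}

#' Construct a planted ground-truth rule
#'
#' @inheritParams conjunctiveClause
#' @param targetClass label of the class whose subjects satisfy the rule.
#' @return a [PlantedRule-class].
#' @export
plantedRule <- function(features, lower, upper, targetClass) {
    methods::new("PlantedRule",
                 clause = conjunctiveClause(features, lower, upper),
                 targetClass = targetClass)
}

#' @export
#' @describeIn plantedRule display.
setMethod("show", "PlantedRule", function(object) {
    cat(sprintf("PlantedRule (target class '%s'):\n", object@targetClass))
    show(object@clause)
})

#' Serialize clauses and metrics to JSON
#'
#' Writes feature names, numeric bounds at full precision and all
#' metrics, so archives can be re-loaded and every reported number
#' recomputed.
#'
#' @param models list of \code{list(clause=, metrics=)} pairs, as
#'   returned by [selectParsimonious()].
#' @param file output path.
#' @export
writeClauseJSON <- function(models, file) {
    out <- lapply(models, function(m) {
        list(features = clauseFeatures(m$clause),
             lower = m$clause@lower, upper = m$clause@upper,
             fitness = fitness(m$metrics), pmf = m$metrics@pmf,
             nMatch = m$metrics@nMatch, kMatch = m$metrics@kMatch,
             ppv = ppv(m$metrics), classCoverage = classCoverage(m$metrics),
             sensitivity = as.list(m$metrics@sensitivity))
    })
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' Format clauses as a human-readable report table
#'
#' One row per model, mirroring a "CC #, feature, [lower, upper]"
#' presentation with fitness, PPV and class coverage appended.
#'
#' @inheritParams writeClauseJSON
#' @return a data.frame.
#' @export
clauseReportTable <- function(models) {
    rows <- lapply(seq_along(models), function(i) {
        m <- models[[i]]
        data.frame(
            model = i,
            order = clauseOrder(m$clause),
            clause = paste(sprintf("%s [%g,%g]", clauseFeatures(m$clause),
                                   m$clause@lower, m$clause@upper),
                           collapse = " AND "),
            fitness = fitness(m$metrics),
            ppv = ppv(m$metrics),
            classCoverage = classCoverage(m$metrics))
    })
    do.call(rbind, rows)
}
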