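#' Hypergeometric probability mass function
#'
#' Probability of drawing exactly \code{k} target-class members when a
#' clause matches \code{n} of \code{N} subjects of whom \code{K} belong
#' to the target class:
#' \deqn{P(k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.}
#' Computed in log space (via \code{lchoose}) so that large cohorts do
#' not overflow.  Note this probability is not a p-value; the clause
#' fitness used throughout the package is \code{-log10} of it, so that
#' less-probable-by-chance configurations score higher.
#'
#' @param k matches inside the target class.
#' @param N total number of subjects.
#' @param K number of target-class subjects.
#' @param n total matches.
#' @param log.p return the natural-log PMF instead.
#' @return the probability (vectorized over \code{k}, \code{n}).
#' @examples
#' hypergeomPmf(7, N = 21, K = 7, n = 7)   # 1/choose(21, 7)
#' @export
hypergeomPmf <- function(k, N, K, n, log.p = FALSE) {
    len <- max(length(k), length(n))
    k <- rep_len(as.numeric(k), len)
    n <- rep_len(as.numeric(n), len)
    stopIf(length(N) != 1L || length(K) != 1L, "N and K must be scalars")
    stopIf(K < 0 || K > N || any(n < 0) || any(n > N),
           "need 0 <= K <= N and 0 <= n <= N")
    stopIf(any(k < pmax(0, n - (N - K))) || any(k > pmin(n, K)),
           "k outside the hypergeometric support for (N, K, n)")
    lp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
    if (log.p) lp else exp(lp)
}

# Fitness lookup for one cohort: F[n+1, k+1] = -log10 pmf(k; N, K, n),
# precomputed over the full support so clause evaluation is O(row scan).
# With directed = TRUE, configurations not positively associated with
# the target class (k/n <= K/N, i.e. PPV at or below the class prior)
# score 0: the search models the target class, and the hypergeometric
# improbability is otherwise two-sided (a clause matching exactly the
# controls would score as high as one matching exactly the cases).
fitnessLookup <- function(N, K, directed = FALSE) {
    F <- matrix(NA_real_, N + 1L, N + 1L)
    for (n in 0:N) {
        ks <- max(0L, n - (N - K)):min(n, K)
        val <- -hypergeomPmf(ks, N, K, n, log.p = TRUE) / log(10)
        if (directed)
            val[n == 0L | ks * N <= n * K] <- 0
        F[n + 1L, ks + 1L] <- val
    }
    F
}

#' Evaluate a conjunctive clause against a cohort
#'
#' Counts the subjects matching the clause by exact row scan, scores the
#' configuration with the hypergeometric PMF and derives
#' \code{fitness = -log10(pmf)}, positive predictive value
#' (\code{kMatch/nMatch}) and class coverage (\code{kMatch/nClass}).
#' A clause matching no subjects carries no information: its pmf is 1,
#' its fitness 0 and its PPV undefined (NA).
#'
#' @param clause a [ConjunctiveClause-class].
#' @param table a [FeatureTable-class].
#' @param target the positive class label; defaults to
#'   \code{targetClass(table)}.
#' @return a [ClauseMetrics-class] (sensitivity left unpopulated; see
#'   [featureSensitivity()]).
#' @export
evaluateClause <- function(clause, table, target = targetClass(table)) {
    stopIf(!target %in% levels(outcome(table)),
           "'%s' is not an outcome level of the table", target)
    m <- clauseMatches(clause, table)
    inClass <- outcome(table) == target
    counts <- c(N = nSubjects(table), K = sum(inClass),
                n = sum(m), k = sum(m & inClass))
    metricsFromCounts(counts["k"], counts["N"], counts["K"], counts["n"])
}

# Build ClauseMetrics from raw counts (shared by evaluateClause and the
# search loops, which count matches without constructing clause objects).
metricsFromCounts <- function(k, N, K, n, sensitivity = numeric()) {
    k <- unname(k); N <- unname(N); K <- unname(K); n <- unname(n)
    lp <- hypergeomPmf(k, N, K, n, log.p = TRUE)
    methods::new("ClauseMetrics",
                 nTotal = as.integer(N), nClass = as.integer(K),
                 nMatch = as.integer(n), kMatch = as.integer(k),
                 pmf = exp(lp), fitness = max(0, -lp / log(10)),
                 ppv = if (n == 0) NA_real_ else k / n,
                 classCoverage = k / K,
                 sensitivity = sensitivity)
}

#' Accessors for ClauseMetrics
#'
#' @param x a [ClauseMetrics-class].
#' @name ClauseMetrics-accessors
NULL

#' @rdname ClauseMetrics-accessors
#' @export
setMethod("fitness", "ClauseMetrics", function(x) x@fitness)

#' @rdname ClauseMetrics-accessors
#' @export
setMethod("ppv", "ClauseMetrics", function(x) x@ppv)

#' @rdname ClauseMetrics-accessors
#' @export
setMethod("classCoverage", "ClauseMetrics", function(x) x@classCoverage)

#' @export
#' @describeIn ClauseMetrics-accessors display.
setMethod("show", "ClauseMetrics", function(object) {
    cat(sprintf(
        "ClauseMetrics: n=%d matched (k=%d in class of %d; N=%d)\n",
        object@nMatch, object@kMatch, object@nClass, object@nTotal))
    cat(sprintf("  fitness=%.4f (pmf=%.4g)  PPV=%s  coverage=%.3f\n",
                object@fitness, object@pmf,
                ifelse(is.na(object@ppv), "undefined",
                       sprintf("%.3f", object@ppv)),
                object@classCoverage))
    if (length(object@sensitivity))
        cat("  sensitivity:",
            paste(sprintf("%s=%.3f", names(object@sensitivity),
                          object@sensitivity), collapse = ", "), "\n")
})

#' Per-feature sensitivity of a clause
#'
#' The sensitivity of a feature is the clause fitness minus the fitness
#' of the clause with that feature's conjunct removed — the amount of
#' fitness the feature contributes.  For an order-1 clause the reduced
#' clause matches everybody (fitness 0), so sensitivity equals the
#' clause's own fitness.  A conjunct whose interval spans the feature's
#' full observed range leaves the match set unchanged when dropped and
#' therefore has sensitivity 0.
#'
#' @inheritParams evaluateClause
#' @return named numeric vector, one sensitivity per clause feature.
#' @export
featureSensitivity <- function(clause, table, target = targetClass(table)) {
    full <- evaluateClause(clause, table, target)
    feats <- clauseFeatures(clause)
    sens <- vapply(seq_along(feats), function(i) {
        if (length(feats) == 1L)
            return(full@fitness)
        reduced <- methods::new("ConjunctiveClause",
                                features = clause@features[-i],
                                lower = clause@lower[-i],
                                upper = clause@upper[-i])
        full@fitness - evaluateClause(reduced, table, target)@fitness
    }, numeric(1))
    names(sens) <- feats
    sens
}

#' Does every feature of a clause contribute fitness?
#'
#' The overfitting guard applied before a clause may enter the archive:
#' every feature's sensitivity must exceed the threshold (strictly).
#'
#' @param sensitivity named numeric vector from [featureSensitivity()],
#'   or a [ClauseMetrics-class] with populated sensitivity.
#' @param threshold minimum contribution; default 0 (any non-positive
#'   contribution disqualifies).
#' @return logical scalar.
#' @export
passesSensitivity <- function(sensitivity, threshold = 0) {
    if (methods::is(sensitivity, "ClauseMetrics"))
        sensitivity <- sensitivity@sensitivity
    stopIf(length(sensitivity) == 0L, "sensitivity has not been computed")
    all(sensitivity > threshold)
}
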