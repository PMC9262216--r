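# Independent brute-force oracles and tiny fixture builders.  These
# deliberately avoid the package's vectorized code paths: clause counts
# come from explicit per-subject loops and KNN predictions from a naive
# all-pairs distance sort.

# tiny deterministic table: values given subject-by-subject
makeTable <- function(values, outcome, targetClass = "case",
                      features = NULL) {
    if (!is.matrix(values)) values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- if (!is.null(features)) features
            else paste0("f", seq_len(ncol(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
    featureTable(values, outcome = outcome, targetClass = targetClass)
}

# clause match counts by explicit per-subject, per-conjunct loop
oracleCounts <- function(clause, table, target = targetClass(table)) {
    vals <- featureValues(table)
    iv <- clauseIntervals(clause)
    oc <- as.character(outcome(table))
    n <- 0L; k <- 0L
    for (s in seq_len(nrow(vals))) {
        ok <- TRUE
        for (f in rownames(iv)) {
            x <- vals[s, f]
            if (x < iv[f, "lower"] || x > iv[f, "upper"]) { ok <- FALSE; break }
        }
        if (ok) {
            n <- n + 1L
            if (oc[s] == target) k <- k + 1L
        }
    }
    c(n = n, k = k)
}

# naive KNN prediction with the package's documented tie rules but an
# independent implementation (explicit loops, no shared code)
oracleKnn <- function(trainVals, trainLabels, testRow, k,
                      scale = TRUE, distance = "euclidean") {
    if (scale) {
        ctr <- colMeans(trainVals)
        sdv <- apply(trainVals, 2, stats::sd)
        sdv[sdv == 0 | is.na(sdv)] <- 1
        trainVals <- t((t(trainVals) - ctr) / sdv)
        testRow <- (testRow - ctr) / sdv
    }
    d <- numeric(nrow(trainVals))
    for (i in seq_len(nrow(trainVals))) {
        diff <- trainVals[i, ] - testRow
        d[i] <- if (distance == "euclidean") sqrt(sum(diff^2))
            else sum(abs(diff))
    }
    ord <- base::order(d)
    nbr <- ord[seq_len(k)]
    votes <- table(trainLabels[nbr])
    tied <- names(votes)[votes == max(votes)]
    if (length(tied) == 1L) return(tied)
    trainLabels[nbr[trainLabels[nbr] %in% tied][1L]]
}

oracleLoocv <- function(table, k, scale = TRUE) {
    vals <- featureValues(table)
    labels <- as.character(outcome(table))
    preds <- character(nrow(vals))
    for (i in seq_len(nrow(vals)))
        preds[i] <- oracleKnn(vals[-i, , drop = FALSE], labels[-i],
                              vals[i, ], k, scale = scale)
    preds
}

# standard planted two-feature rule used by several tests
defaultPlantedRule <- function()
    plantedRule(c("pf_a", "pf_b"), lower = c(4000, 1480),
                upper = c(4600, 1700), targetClass = "ASD")
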