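#' Configuration for KNN classification
#'
#' @param k neighbor count (>= 1; at most the training-set size).
#' @param distance \code{"euclidean"} (default) or \code{"manhattan"}.
#' @param scaling \code{"zscore"} (default; per-feature
#'   standardization fit on the training rows only) or \code{"none"}.
#'   Standardization is the defensible default here because cohorts mix
#'   features spanning five orders of magnitude (regional volumes
#'   ~10^4 mm^3 against curvatures ~10^-1): unscaled Euclidean
#'   distances would be dominated by volume.
#' @return validated list of class \code{knnConfig}.
#' @details Deterministic tie rules: a plurality vote among the k
#'   nearest neighbors decides the label; a tied vote (possible for
#'   even k) is resolved by the class of the single nearest neighbor
#'   among the tied classes; exact distance ties are resolved by
#'   training-row order (the earlier row wins a neighbor slot).
#' @export
knnConfig <- function(k = 3, distance = c("euclidean", "manhattan"),
                      scaling = c("zscore", "none")) {
    distance <- match.arg(distance)
    scaling <- match.arg(scaling)
    stopIf(k < 1, "k must be at least 1")
    structure(list(k = as.integer(k), distance = distance,
                   scaling = scaling), class = "knnConfig")
}

#' Fit per-feature scaling statistics on a training table
#'
#' Location is the per-feature mean and scale the standard deviation of
#' the training rows only (never the test rows).  Constant features get
#' scale 1, with a warning, so they drop out of the distance without
#' dividing by zero.
#'
#' @param train a [FeatureTable-class].
#' @return list with named numeric vectors \code{center} and
#'   \code{scale}.
#' @export
fitScaling <- function(train) {
    stopIf(nSubjects(train) < 1L, "empty training table")
    vals <- featureValues(train)
    center <- colMeans(vals)
    scale <- apply(vals, 2, stats::sd)
    scale[is.na(scale)] <- 0     # single training row
    if (any(scale == 0)) {
        warning(sprintf("constant feature(s) scaled by 1: %s",
                        paste(colnames(vals)[scale == 0], collapse = ", ")))
        scale[scale == 0] <- 1
    }
    list(center = center, scale = scale)
}

applyScaling <- function(vals, scaling) {
    if (is.null(scaling)) return(vals)
    sweep(sweep(vals, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

#' Predict class labels with k-nearest neighbors
#'
#' @param train a [FeatureTable-class] of labelled subjects.
#' @param test a [FeatureTable-class], numeric matrix or single numeric
#'   vector with the same features as \code{train}.
#' @param config a [knnConfig()].
#' @param scaling optional scaling statistics from [fitScaling()];
#'   defaults to fitting on \code{train} when the config requests
#'   z-score scaling.
#' @return character vector of predicted labels, one per test row.
#' @export
knnPredict <- function(train, test, config = knnConfig(), scaling = NULL) {
    trainVals <- featureValues(train)
    testVals <- if (methods::is(test, "FeatureTable")) featureValues(test)
        else if (is.matrix(test)) test
        else matrix(test, nrow = 1, dimnames = list(NULL, names(test)))
    stopIf(ncol(testVals) != ncol(trainVals) ||
           (!is.null(colnames(testVals)) &&
            !identical(colnames(testVals), colnames(trainVals))),
           "train and test must share the same feature columns")
    stopIf(config$k > nSubjects(train),
           "k = %d exceeds the training set size %d", config$k,
           nSubjects(train))
    if (is.null(scaling) && config$scaling == "zscore")
        scaling <- fitScaling(train)
    tr <- applyScaling(trainVals, scaling)
    te <- applyScaling(testVals, scaling)
    labels <- as.character(outcome(train))
    vapply(seq_len(nrow(te)), function(i) {
        d <- if (config$distance == "euclidean")
            sqrt(rowSums(sweep(tr, 2, te[i, ], "-")^2))
        else
            rowSums(abs(sweep(tr, 2, te[i, ], "-")))
        ord <- base::order(d)                # stable: earlier row wins ties
        nbr <- ord[seq_len(config$k)]
        votes <- table(labels[nbr])
        tied <- names(votes)[votes == max(votes)]
        if (length(tied) == 1L) return(tied)
        # tied vote: class of the nearest neighbor among the tied classes
        labels[nbr[labels[nbr] %in% tied][1L]]
    }, character(1))
}

#' Construct a confusion matrix
#'
#' Either from truth/prediction label vectors or from the four counts
#' directly.
#'
#' @param truth,predicted character/factor label vectors (with
#'   \code{targetClass} as the positive class), or NULL when counts are
#'   given.
#' @param targetClass,otherClass positive and negative class labels.
#' @param tp,fn,fp,tn direct counts (used when \code{truth} is NULL).
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(truth = NULL, predicted = NULL, targetClass,
                            otherClass, tp = 0, fn = 0, fp = 0, tn = 0) {
    if (!is.null(truth)) {
        truth <- as.character(truth); predicted <- as.character(predicted)
        stopIf(length(truth) != length(predicted),
               "truth and predicted lengths differ")
        tp <- sum(truth == targetClass & predicted == targetClass)
        fn <- sum(truth == targetClass & predicted != targetClass)
        fp <- sum(truth != targetClass & predicted == targetClass)
        tn <- sum(truth != targetClass & predicted != targetClass)
    }
    methods::new("ConfusionMatrix", tp = as.integer(tp),
                 fn = as.integer(fn), fp = as.integer(fp),
                 tn = as.integer(tn), targetClass = targetClass,
                 otherClass = otherClass)
}

#' Accuracy, PPV and recall of a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with \code{accuracy} = (tp+tn)/total, \code{ppv} =
#'   tp/(tp+fp) (NA when no positive prediction was made) and
#'   \code{recall} (class coverage) = tp/(tp+fn).
#' @export
matrixMetrics <- function(cm) {
    stopIf(!methods::is(cm, "ConfusionMatrix"),
           "'cm' must be a ConfusionMatrix")
    total <- cm@tp + cm@fn + cm@fp + cm@tn
    list(accuracy = (cm@tp + cm@tn) / total,
         ppv = if (cm@tp + cm@fp == 0) NA_real_ else
             cm@tp / (cm@tp + cm@fp),
         recall = if (cm@tp + cm@fn == 0) NA_real_ else
             cm@tp / (cm@tp + cm@fn))
}

#' @export
#' @describeIn matrixMetrics display.
setMethod("show", "ConfusionMatrix", function(object) {
    m <- matrixMetrics(object)
    cat(sprintf("ConfusionMatrix (positive = %s): ACC %.2f%%\n",
                object@targetClass, 100 * m$accuracy))
    tab <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2,
                  dimnames = list(
                      paste("True", c(object@targetClass,
                                      object@otherClass)),
                      paste("Predicted", c(object@targetClass,
                                           object@otherClass))))
    print(tab)
})

#' Leave-one-out cross-validation of a KNN classifier
#'
#' One fold per subject: scaling statistics are re-fit on the remaining
#' N-1 rows, the held-out subject is predicted, and the 2x2 confusion
#' matrix is accumulated with the table's target class as positive.
#' Fully deterministic.
#'
#' @param table a [FeatureTable-class].
#' @param config a [knnConfig()]; requires \code{k < N - 1}.
#' @return list with \code{cm} (a [ConfusionMatrix-class]),
#'   \code{predictions} (named character vector) and \code{metrics}
#'   (from [matrixMetrics()]).
#' @export
loocv <- function(table, config = knnConfig()) {
    n <- nSubjects(table)
    stopIf(config$k > n - 1L,
           "k = %d too large for leave-one-out on %d subjects", config$k, n)
    preds <- vapply(seq_len(n), function(i) {
        knnPredict(table[, -i], table[, i], config)
    }, character(1))
    names(preds) <- subjectIds(table)
    cm <- confusionMatrix(as.character(outcome(table)), preds,
                          targetClass = targetClass(table),
                          otherClass = otherClass(table))
    list(cm = cm, predictions = preds, metrics = matrixMetrics(cm))
}

#' Train/test KNN classification
#'
#' Scaling is fit on the training table only; every test subject is
#' predicted independently and the confusion matrix is computed over
#' the test rows.
#'
#' @param train,test disjoint [FeatureTable-class] objects sharing the
#'   same features.
#' @param config a [knnConfig()].
#' @return list with \code{cm}, \code{predictions} and \code{metrics}.
#' @export
trainTestClassify <- function(train, test, config = knnConfig()) {
    overlap <- intersect(subjectIds(train), subjectIds(test))
    stopIf(length(overlap) > 0L, "train and test subjects overlap: %s",
           paste(overlap, collapse = ", "))
    stopIf(!identical(rownames(train), rownames(test)),
           "train and test must share the same features")
    preds <- knnPredict(train, test, config)
    names(preds) <- subjectIds(test)
    cm <- confusionMatrix(as.character(outcome(test)), preds,
                          targetClass = targetClass(train),
                          otherClass = otherClass(train))
    list(cm = cm, predictions = preds, metrics = matrixMetrics(cm))
}
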