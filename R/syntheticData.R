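# Synthetic-cohort generation: small unbalanced classes, continuous
# features on heterogeneous scales, and planted conjunctive rules with a
# controlled amount of leakage into the non-target class.

# Per-measure location/scale used when a schema row does not provide
# them.  Locations mimic FreeSurfer regional summaries (volumes in the
# thousands of mm^3, thickness ~2.5 mm, mean curvature ~0.16 1/mm) and
# 0-20 behavioral score scales.
.MEASURE_PARAMS <- list(
    volume    = list(locRange = c(4000, 23000), relScale = 0.12,
                     units = "mm3",  kind = "neuroanatomical"),
    area      = list(locRange = c(1500, 9000),  relScale = 0.12,
                     units = "mm2",  kind = "neuroanatomical"),
    thickness = list(locRange = c(2.3, 2.8),    absScale = 0.15,
                     units = "mm",   kind = "neuroanatomical"),
    meancurv  = list(locRange = c(0.12, 0.2),   absScale = 0.02,
                     units = "1/mm", kind = "neuroanatomical"),
    score     = list(locRange = c(10, 16),      absScale = 3,
                     units = "score-points", kind = "behavioral"),
    other     = list(locRange = c(0, 0),        absScale = 1,
                     units = "", kind = "other"))

#' Build a feature schema for synthetic cohorts
#'
#' A schema is a data.frame with one row per feature: \code{name},
#' \code{kind}, \code{measure}, \code{units}, and the Gaussian
#' \code{location}/\code{scale} the generator draws from.  Locations are
#' spread deterministically across each measure's typical range so that
#' volumes land in the thousands of mm^3, thicknesses near 2.5 mm, mean
#' curvatures near 0.16 and behavioral scores on a 0-20 scale.
#'
#' @param measures character vector (one entry per feature) drawn from
#'   volume, area, thickness, meancurv, score, other.
#' @param names optional feature names; defaults to
#'   \code{<measure>_<i>}.
#' @return schema data.frame.
#' @export
featureSchema <- function(measures, names = NULL) {
    stopIf(!all(measures %in% names(.MEASURE_PARAMS)),
           "unknown measure(s): %s",
           paste(setdiff(measures, names(.MEASURE_PARAMS)), collapse = ", "))
    if (is.null(names)) {
        idx <- stats::ave(seq_along(measures), measures, FUN = seq_along)
        names <- sprintf("%s_%03d", measures, idx)
    }
    stopIf(anyDuplicated(names) > 0L, "schema feature names must be unique")
    rows <- lapply(seq_along(measures), function(i) {
        p <- .MEASURE_PARAMS[[measures[i]]]
        nOfMeasure <- sum(measures == measures[i])
        j <- sum(measures[seq_len(i)] == measures[i])
        loc <- if (nOfMeasure == 1L) mean(p$locRange) else
            p$locRange[1] + (j - 1) / (nOfMeasure - 1) * diff(p$locRange)
        sc <- if (!is.null(p$absScale)) p$absScale else abs(loc) * p$relScale
        data.frame(name = names[i], kind = p$kind, measure = measures[i],
                   units = p$units, location = loc, scale = max(sc, 1e-8))
    })
    do.call(rbind, rows)
}

#' ASD-study-like feature schema
#'
#' 276 neuroanatomical features (69 regions x volume, area, thickness,
#' mean curvature) plus 13 behavioral score features, mirroring the
#' shape of a cohort that combines FreeSurfer parcellation exports with
#' theory-of-mind, language and nonverbal-IQ assessments.
#'
#' @param nRegions number of brain regions (default 69, giving 276
#'   anatomical features).
#' @param nBehavioral number of behavioral score features (default 13).
#' @return schema data.frame.
#' @export
asdFeatureSchema <- function(nRegions = 69, nBehavioral = 13) {
    measures <- c(rep(c("volume", "area", "thickness", "meancurv"),
                      each = nRegions),
                  rep("score", nBehavioral))
    featureSchema(measures)
}

schemaSupport <- function(schemaRow)
    schemaRow$location + c(-6, 6) * schemaRow$scale

# Draw one value strictly outside [lo, hi] but inside the feature's
# support; used to guarantee a non-target subject violates a conjunct.
drawOutside <- function(lo, hi, support) {
    wl <- max(0, lo - support[1]); wr <- max(0, support[2] - hi)
    stopIf(wl + wr <= 0,
           "planted interval [%g, %g] covers the schema support; %s",
           lo, hi, "non-target subjects cannot violate it")
    repeat {
        v <- if (stats::runif(1) < wl / (wl + wr))
            stats::runif(1, support[1], lo)
        else
            stats::runif(1, hi, support[2])
        if (v < lo || v > hi) return(v)
    }
}

checkRules <- function(rules, schema, targetLabel) {
    allFeats <- character()
    for (r in rules) {
        stopIf(!methods::is(r, "PlantedRule"),
               "'rules' must be a list of PlantedRule objects")
        stopIf(r@targetClass != targetLabel,
               "planted rule targets class '%s', cohort target is '%s'",
               r@targetClass, targetLabel)
        feats <- clauseFeatures(r@clause)
        stopIf(any(feats %in% allFeats),
               "planted rules must use disjoint feature sets")
        allFeats <- c(allFeats, feats)
        for (i in seq_along(feats)) {
            row <- schema[schema$name == feats[i], ]
            stopIf(nrow(row) == 0L,
                   "planted feature '%s' is not in the schema", feats[i])
            sup <- schemaSupport(row)
            stopIf(r@clause@lower[i] < sup[1] || r@clause@upper[i] > sup[2],
                   "interval for '%s' lies outside the schema support [%g, %g]",
                   feats[i], sup[1], sup[2])
        }
    }
    allFeats
}

#' Generate a synthetic cohort with planted conjunctive rules
#'
#' Emulates the statistical structure the clause search assumes: two
#' classes with small unbalanced counts, continuous features on
#' heterogeneous scales, and one or more planted feature-interval
#' conjunctions that separate the target class.  Every target-class
#' subject satisfies every planted rule; at most
#' \code{floor(leakage * nOther)} non-target subjects satisfy any given
#' rule (each remaining non-target subject is forced to violate at
#' least one conjunct); noise features are drawn identically for both
#' classes.  The same seed always reproduces the identical table.
#'
#' @param nTarget,nOther subject counts for the target and non-target
#'   class (defaults 7 and 14, a small unbalanced discovery cohort).
#' @param rules list of [PlantedRule-class] objects (disjoint feature
#'   sets).  Rule features absent from \code{schema} get a schema entry
#'   inferred from their interval (location = midpoint, scale =
#'   half-width).
#' @param nNoiseFeatures number of uninformative features appended
#'   (cycled across volume/area/thickness/meancurv/score measures).
#' @param schema optional [featureSchema()] data.frame.
#' @param leakage fraction in [0, 1] of non-target subjects allowed to
#'   satisfy each planted rule.
#' @param classLabels length-2 character: target label then other
#'   label.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with \code{table} (a [FeatureTable-class]) and
#'   \code{rules} (the ground truth, never embedded in the table).
#' @examples
#' rule <- plantedRule(c("volume_001", "volume_002"),
#'                     lower = c(3500, 20000), upper = c(4600, 25000),
#'                     targetClass = "ASD")
#' syn <- generateCohort(rules = list(rule), nNoiseFeatures = 10, seed = 1)
#' table(clauseMatches(rule@clause, syn$table), outcome(syn$table))
#' @export
generateCohort <- function(nTarget = 7, nOther = 14, rules = list(),
                           nNoiseFeatures = 50, schema = NULL, leakage = 0,
                           classLabels = c("ASD", "NT"), seed = 1) {
    stopIf(nTarget < 1 || nOther < 1, "class counts must be positive")
    stopIf(leakage < 0 || leakage > 1, "leakage must lie in [0, 1]")
    targetLabel <- classLabels[1]; otherLabel <- classLabels[2]

    ruleFeats <- unique(unlist(lapply(rules, function(r)
        clauseFeatures(r@clause))))
    if (is.null(schema)) {
        noiseMeasures <- rep_len(c("volume", "area", "thickness", "meancurv",
                                   "score"), max(nNoiseFeatures, 0L))
        schema <- if (nNoiseFeatures > 0)
            featureSchema(noiseMeasures,
                          names = sprintf("noise_%03d",
                                          seq_len(nNoiseFeatures)))
        else featureSchema(character())
    }
    # give planted features a schema entry when the caller did not
    for (r in rules) {
        feats <- clauseFeatures(r@clause)
        for (i in seq_along(feats)) {
            if (feats[i] %in% schema$name) next
            mid <- (r@clause@lower[i] + r@clause@upper[i]) / 2
            halfw <- max((r@clause@upper[i] - r@clause@lower[i]) / 2,
                         1e-6 * max(1, abs(mid)))
            schema <- rbind(
                data.frame(name = feats[i], kind = "neuroanatomical",
                           measure = "other", units = "",
                           location = mid, scale = halfw),
                schema)
        }
    }
    checkRules(rules, schema, targetLabel)

    n <- nTarget + nOther
    isTarget <- c(rep(TRUE, nTarget), rep(FALSE, nOther))
    ids <- c(sprintf("%s_%02d", targetLabel, seq_len(nTarget)),
             sprintf("%s_%02d", otherLabel, seq_len(nOther)))

    withSeed(seed, {
        vals <- vapply(seq_len(nrow(schema)), function(j)
            stats::rnorm(n, schema$location[j], schema$scale[j]),
            numeric(n))
        dimnames(vals) <- list(ids, schema$name)
        for (r in rules) {
            feats <- clauseFeatures(r@clause)
            nLeak <- floor(leakage * nOther)
            leakers <- nTarget + sample.int(nOther, nLeak)
            satisfy <- c(which(isTarget), leakers)
            for (i in seq_along(feats)) {
                vals[satisfy, feats[i]] <- stats::runif(
                    length(satisfy), r@clause@lower[i], r@clause@upper[i])
            }
            violators <- setdiff(which(!isTarget), leakers)
            vioConj <- sample.int(length(feats), length(violators),
                                  replace = TRUE)
            for (v in seq_along(violators)) {
                i <- vioConj[v]
                row <- schema[schema$name == feats[i], ]
                vals[violators[v], feats[i]] <- drawOutside(
                    r@clause@lower[i], r@clause@upper[i],
                    schemaSupport(row))
            }
        }
        tab <- featureTable(
            vals,
            outcome = ifelse(isTarget, targetLabel, otherLabel),
            targetClass = targetLabel, subjectIds = ids,
            featureInfo = schema[, c("kind", "measure", "units")])
        list(table = tab, rules = rules)
    })
}

#' Generate a null cohort (no class signal)
#'
#' All features are drawn i.i.d. standard normal for every subject and
#' the class labels are assigned independently of the features.  Used to
#' study the selection effect: even under the null, the best of many
#' scanned clauses beats the class prior, which is why sensitivity
#' pruning and parsimony matter.
#'
#' @inheritParams generateCohort
#' @param nFeatures number of i.i.d. features (must be positive).
#' @return a [FeatureTable-class].
#' @export
generateNullCohort <- function(nTarget = 7, nOther = 14, nFeatures = 50,
                               classLabels = c("ASD", "NT"), seed = 1) {
    stopIf(nTarget < 1 || nOther < 1, "class counts must be positive")
    stopIf(nFeatures < 1, "nFeatures must be positive")
    n <- nTarget + nOther
    ids <- c(sprintf("%s_%02d", classLabels[1], seq_len(nTarget)),
             sprintf("%s_%02d", classLabels[2], seq_len(nOther)))
    withSeed(seed, {
        vals <- matrix(stats::rnorm(n * nFeatures), n, nFeatures,
                       dimnames = list(ids, sprintf("null_%03d",
                                                    seq_len(nFeatures))))
        featureTable(vals,
                     outcome = rep(classLabels, c(nTarget, nOther)),
                     targetClass = classLabels[1], subjectIds = ids)
    })
}

#' Plant a two-feature interaction with no marginal effect
#'
#' Builds a cohort in which a two-feature conjunctive rule separates the
#' target class perfectly although neither feature shows a location
#' difference between classes.  The target class sits in a central
#' rectangle of the two-feature plane; the non-target class is a
#' balanced mixture of two opposite off-axis clusters, one overlapping
#' the rule's interval on each feature.  The in-band non-target cluster
#' of each feature is shifted so the non-target class mean equals the
#' target class mean exactly (to numerical precision), not merely in
#' expectation.  Consequently each single-feature projection of the
#' returned rule still covers the whole target class but captures about
#' half the non-target class, while the full conjunction captures none.
#'
#' @inheritParams generateCohort
#' @param features length-2 character, names of the interacting pair.
#' @param nNoiseFeatures number of i.i.d. standard-normal noise
#'   features appended.
#' @param halfWidth half-width of the target rectangle on each axis.
#' @param offset distance of the non-target clusters from the centre
#'   (must exceed \code{2 * halfWidth} for a leak-free rule).
#' @return list with \code{table} and \code{rule} (the ground-truth
#'   [PlantedRule-class] whose intervals span target plus in-band
#'   non-target values on each axis).
#' @export
plantInteractionNoMainEffect <- function(nTarget = 7, nOther = 14,
                                         features = c("interact_a",
                                                      "interact_b"),
                                         nNoiseFeatures = 20,
                                         halfWidth = 1, offset = 6,
                                         classLabels = c("ASD", "NT"),
                                         seed = 1) {
    stopIf(length(features) != 2L || features[1] == features[2],
           "'features' must name two distinct features")
    stopIf(nTarget < 4 || nOther < 4,
           "need at least 4 subjects per class to balance the mixture")
    stopIf(offset <= 2 * halfWidth,
           "offset must exceed twice the half-width")
    n <- nTarget + nOther
    ids <- c(sprintf("%s_%02d", classLabels[1], seq_len(nTarget)),
             sprintf("%s_%02d", classLabels[2], seq_len(nOther)))
    nA <- floor(nOther / 2); nB <- nOther - nA

    withSeed(seed, {
        # exactly zero-mean target values: paired +/- deltas (plus 0)
        symmetric <- function(count) {
            half <- floor(count / 2)
            d <- stats::runif(half, 0.1 * halfWidth, halfWidth)
            out <- c(d, -d, if (count %% 2) 0)
            sample(out)
        }
        tA <- symmetric(nTarget); tB <- symmetric(nTarget)
        # cluster B sits high on feature 1; cluster A is shifted so the
        # non-target mean on feature 1 is exactly the target mean (0)
        b1 <- offset + stats::runif(nB, -halfWidth, halfWidth)
        rawA1 <- stats::runif(nA, -halfWidth, halfWidth)
        a1 <- rawA1 - mean(rawA1) - nB * mean(b1) / nA
        # mirrored construction on feature 2
        a2 <- offset + stats::runif(nA, -halfWidth, halfWidth)
        rawB2 <- stats::runif(nB, -halfWidth, halfWidth)
        b2 <- rawB2 - mean(rawB2) - nA * mean(a2) / nB

        f1 <- c(tA, a1, b1)
        f2 <- c(tB, a2, b2)
        pad <- 1e-3 * halfWidth
        rule <- plantedRule(
            features,
            lower = c(min(c(tA, a1)) - pad, min(c(tB, b2)) - pad),
            upper = c(max(c(tA, a1)) + pad, max(c(tB, b2)) + pad),
            targetClass = classLabels[1])

        noise <- matrix(stats::rnorm(n * nNoiseFeatures), n, nNoiseFeatures,
                        dimnames = list(NULL, sprintf("noise_%03d",
                                                      seq_len(max(nNoiseFeatures, 0L)))))
        vals <- cbind(matrix(c(f1, f2), n, 2,
                             dimnames = list(NULL, features)),
                      noise)
        rownames(vals) <- ids
        tab <- featureTable(
            vals,
            outcome = rep(classLabels, c(nTarget, nOther)),
            targetClass = classLabels[1], subjectIds = ids)
        list(table = tab, rule = rule)
    })
}

#' Archive a synthetic cohort with its ground truth
#'
#' Writes the table as CSV (via [writeFeatureTable()]) and the planted
#' rules, seed and generator call as JSON next to it.
#'
#' @param cohort list returned by [generateCohort()].
#' @param csvFile,jsonFile output paths.
#' @param seed the seed used, recorded for provenance.
#' @export
writeCohortFixture <- function(cohort, csvFile, jsonFile, seed = NA) {
    writeFeatureTable(cohort$table, csvFile)
    rules <- cohort$rules %||% list(cohort$rule)
    gt <- lapply(rules, function(r)
        list(targetClass = r@targetClass,
             features = clauseFeatures(r@clause),
             lower = r@clause@lower, upper = r@clause@upper))
    jsonlite::write_json(list(seed = seed, rules = gt), jsonFile,
                         auto_unbox = TRUE, digits = NA)
    invisible(c(csvFile, jsonFile))
}
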