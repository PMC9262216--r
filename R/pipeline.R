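# End-to-end orchestration: clause discovery on a fixed discovery
# cohort, parsimonious model selection, feature-union construction, and
# KNN validation / prediction, all driven by one config object with a
# single root seed.

#' Unique feature union across selected models
#'
#' Deduplicated union of all conjunct features across the given models,
#' in first-appearance order, followed by any extra features not
#' already present — e.g. the "8 unique features of the selected
#' two-feature models", optionally extended with behavioral scores.
#'
#' @param models list of \code{list(clause=, ...)} entries (from
#'   [selectParsimonious()]); may be empty when \code{extra} is not.
#' @param extra character vector of feature names appended after the
#'   model features.
#' @return ordered character vector of unique feature names.
#' @export
uniqueFeatureUnion <- function(models, extra = character()) {
    stopIf(length(models) == 0L && length(extra) == 0L,
           "need at least one model or extra feature")
    feats <- unlist(lapply(models, function(m) clauseFeatures(m$clause)))
    unique(c(feats, extra))
}

#' Assemble a pipeline configuration
#'
#' @param input path to a subjects-by-features CSV (see
#'   [readFeatureTable()]), or NULL when \code{synthetic} is given.
#' @param synthetic list of arguments for [generateCohort()] (its
#'   \code{seed} is derived from \code{seed} below).
#' @param targetClass positive class label.
#' @param subjectCol,outcomeCol CSV column roles for \code{input}.
#' @param discoveryIds subject ids forming the clause-discovery cohort
#'   (an explicit historical list, not a random split); NULL uses all
#'   subjects.
#' @param ccea a [cceaConfig()]; its seed is derived from \code{seed}.
#' @param selection named list \code{order -> topM}, e.g.
#'   \code{list(`2` = 8, `3` = 6)}.
#' @param experiments list of KNN experiments, each a list with
#'   \code{name}, \code{featureSource} (one of \code{"order2_union"},
#'   \code{"order3_union"}, \code{"combined_union"},
#'   \code{"explicit"}), optional \code{features} (for explicit),
#'   optional \code{extraFeatures} (appended to the union), \code{k},
#'   and optional \code{scaling}/\code{distance}.
#' @param trainIds optional subject ids for a balanced training split;
#'   the remaining subjects form the test set.
#' @param outputDir optional directory for report files.
#' @param seed root seed for all stages.
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(input = NULL, synthetic = NULL, targetClass,
                           subjectCol = "subject_id",
                           outcomeCol = "outcome", discoveryIds = NULL,
                           ccea = cceaConfig(),
                           selection = list(`2` = 8),
                           experiments = list(), trainIds = NULL,
                           outputDir = NULL, seed = 1,
                           logLevel = c("info", "quiet", "debug")) {
    stopIf(is.null(input) && is.null(synthetic),
           "either 'input' or 'synthetic' must be provided")
    sources <- c("order2_union", "order3_union", "combined_union",
                 "explicit")
    for (e in experiments) {
        stopIf(is.null(e$name) || is.null(e$featureSource) || is.null(e$k),
               "each experiment needs name, featureSource and k")
        stopIf(!e$featureSource %in% sources,
               "unknown featureSource '%s'", e$featureSource)
        stopIf(e$featureSource == "explicit" && length(e$features) == 0L,
               "explicit experiments need a 'features' list")
    }
    cfg <- list(input = input, synthetic = synthetic,
                targetClass = targetClass, subjectCol = subjectCol,
                outcomeCol = outcomeCol, discoveryIds = discoveryIds,
                ccea = ccea, selection = selection,
                experiments = experiments, trainIds = trainIds,
                outputDir = outputDir, seed = as.integer(seed),
                logLevel = match.arg(logLevel))
    class(cfg) <- "pipelineConfig"
    cfg
}

pipeLog <- function(cfg, level, fmt, ...) {
    ranks <- c(quiet = 0, info = 1, debug = 2)
    if (ranks[[cfg$logLevel]] >= ranks[[level]])
        message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

stageError <- function(stage, fmt, ...) {
    stop(sprintf("[stage:%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

#' Run the full discovery-validation pipeline
#'
#' Stages, in order: (1) load or synthesize the cohort and split off
#' the discovery subjects; (2) evolutionary clause search on the
#' discovery cohort; (3) parsimonious model selection per configured
#' order; (4) feature-union construction; (5) KNN leave-one-out
#' cross-validation of every experiment on all subjects (discovery and
#' holdout combined — faithful to the study design it mirrors, and
#' knowingly optimistic since the selected features have seen the
#' discovery subjects); (6) train/test classification when
#' \code{trainIds} is configured.  All randomness derives from the
#' config's root seed, so identical configs give identical reports
#' (timestamps aside).
#'
#' @param config a [pipelineConfig()].
#' @return a \code{RunReport}: list with \code{clauses} (per-order
#'   model tables), \code{unions}, \code{experiments} (confusion
#'   matrices, metrics and predictions per experiment), and
#'   \code{provenance} (config hash, seed, timestamp).
#' @export
runPipeline <- function(config) {
    stopIf(!inherits(config, "pipelineConfig"),
           "'config' must come from pipelineConfig()")

    # stage 1: input
    table <- if (!is.null(config$input)) {
        pipeLog(config, "info", "reading table from %s", config$input)
        readFeatureTable(config$input, subjectCol = config$subjectCol,
                         outcomeCol = config$outcomeCol,
                         targetClass = config$targetClass)
    } else {
        args <- config$synthetic
        args$seed <- deriveSeed(config$seed, "synth")
        pipeLog(config, "info", "generating synthetic cohort (seed %d)",
                args$seed)
        do.call(generateCohort, args)$table
    }
    discovery <- if (is.null(config$discoveryIds)) table else {
        if (length(config$discoveryIds) == 0L)
            stageError("discovery", "empty discovery cohort")
        ok <- config$discoveryIds %in% subjectIds(table)
        if (!all(ok))
            stageError("discovery", "unknown discovery id(s): %s",
                       paste(config$discoveryIds[!ok], collapse = ", "))
        if (length(config$discoveryIds) == nSubjects(table)) table
        else splitSubjects(table, config$discoveryIds)$selected
    }
    cc <- classCounts(discovery)
    pipeLog(config, "info", "discovery cohort: %d %s / %d %s",
            cc[1], names(cc)[1], cc[2], names(cc)[2])

    # stage 2: clause search
    ccfg <- config$ccea
    ccfg$seed <- deriveSeed(config$seed, "ccea")
    archive <- runCCEA(discovery, config$targetClass, ccfg)
    pipeLog(config, "info", "archived %d clauses", length(archive@entries))

    # stage 3: parsimonious selection
    models <- list()
    for (ord in names(config$selection)) {
        sel <- selectParsimonious(archive, as.integer(ord),
                                  config$selection[[ord]])
        models[[ord]] <- sel
        pipeLog(config, "info", "order %s: selected %d models", ord,
                length(sel))
    }

    # stage 4: feature unions
    unions <- list()
    if (!is.null(models[["2"]]) && length(models[["2"]]))
        unions$order2_union <- uniqueFeatureUnion(models[["2"]])
    if (!is.null(models[["3"]]) && length(models[["3"]]))
        unions$order3_union <- uniqueFeatureUnion(models[["3"]])

    # stages 5-6: KNN experiments
    split <- NULL
    if (!is.null(config$trainIds))
        split <- splitSubjects(table, config$trainIds)
    experiments <- list()
    for (e in config$experiments) {
        feats <- switch(
            e$featureSource,
            explicit = e$features,
            order2_union = unions$order2_union,
            order3_union = unions$order3_union,
            combined_union = uniqueFeatureUnion(
                models[["2"]] %||% list(), e$extraFeatures %||% character()))
        if (e$featureSource %in% c("order2_union", "order3_union") &&
            length(e$extraFeatures))
            feats <- unique(c(feats, e$extraFeatures))
        if (is.null(feats) || length(feats) == 0L)
            stageError("knn", "experiment '%s': empty feature set", e$name)
        kcfg <- knnConfig(k = e$k,
                          distance = e$distance %||% "euclidean",
                          scaling = e$scaling %||% "zscore")
        sub <- subsetFeatures(table, feats)
        res <- list(name = e$name, features = feats, k = kcfg$k,
                    loocv = loocv(sub, kcfg))
        pipeLog(config, "info", "experiment '%s': LOOCV accuracy %.2f%%",
                e$name, 100 * res$loocv$metrics$accuracy)
        if (!is.null(split)) {
            res$trainTest <- trainTestClassify(
                subsetFeatures(split$selected, feats),
                subsetFeatures(split$remainder, feats), kcfg)
            pipeLog(config, "info",
                    "experiment '%s': train/test accuracy %.2f%%",
                    e$name, 100 * res$trainTest$metrics$accuracy)
        }
        experiments[[e$name]] <- res
    }

    report <- list(
        clauses = lapply(models, clauseReportTable),
        unions = unions,
        experiments = experiments,
        provenance = list(
            configHash = rlang::hash(unclass(config)),
            seed = config$seed,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
    class(report) <- "RunReport"

    if (!is.null(config$outputDir))
        writeRunReport(report, models, config$outputDir)
    report
}

#' Write pipeline outputs to a directory
#'
#' Produces \code{clauses.json} (full-precision clause archive),
#' \code{clauses_table.txt} (human-readable model table),
#' \code{knn_results.csv} (per-experiment confusion counts and
#' accuracies) and \code{report.json}.
#'
#' @param report a \code{RunReport} from [runPipeline()].
#' @param models the per-order model lists (clause + metrics).
#' @param dir output directory (created if needed).
#' @export
writeRunReport <- function(report, models, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    allModels <- do.call(c, unname(models))
    if (length(allModels)) {
        writeClauseJSON(allModels, file.path(dir, "clauses.json"))
        tab <- clauseReportTable(allModels)
        utils::write.table(tab, file.path(dir, "clauses_table.txt"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (length(report$experiments)) {
        rows <- lapply(report$experiments, function(e) {
            row <- data.frame(experiment = e$name, k = e$k,
                              nFeatures = length(e$features),
                              loocvAccuracy = e$loocv$metrics$accuracy,
                              tp = e$loocv$cm@tp, fn = e$loocv$cm@fn,
                              fp = e$loocv$cm@fp, tn = e$loocv$cm@tn)
            if (!is.null(e$trainTest))
                row$testAccuracy <- e$trainTest$metrics$accuracy
            row
        })
        utils::write.csv(do.call(rbind, rows),
                         file.path(dir, "knn_results.csv"),
                         row.names = FALSE)
    }
    json <- list(
        unions = report$unions,
        experiments = lapply(report$experiments, function(e) {
            out <- list(features = e$features, k = e$k,
                        loocv = c(e$loocv$metrics,
                                  list(tp = e$loocv$cm@tp,
                                       fn = e$loocv$cm@fn,
                                       fp = e$loocv$cm@fp,
                                       tn = e$loocv$cm@tn)))
            if (!is.null(e$trainTest))
                out$trainTest <- c(e$trainTest$metrics,
                                   list(tp = e$trainTest$cm@tp,
                                        fn = e$trainTest$cm@fn,
                                        fp = e$trainTest$cm@fp,
                                        tn = e$trainTest$cm@tn))
            out
        }),
        provenance = report$provenance)
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Feature sets printed by the original study
#'
#' The unique feature names of the selected two-feature models (8
#' neuroanatomical features), the selected three-feature models (9
#' features, mixing behavioral and neuroanatomical), and their
#' combination with the three behavioral scores (11 features).  Names
#' use underscores in \code{hemisphere_region_measure} form.
#'
#' @return list with \code{secondOrder}, \code{thirdOrder} and
#'   \code{combined} character vectors.
#' @export
studyFeatureSets <- function() {
    secondOrder <- c(
        "lh_posteriorcingulate_volume", "lh_rostralmiddlefrontal_volume",
        "rh_rostralmiddlefrontal_volume", "lh_medialorbitofrontal_thickness",
        "rh_rostralmiddlefrontal_area", "rh_isthmuscingulate_volume",
        "rh_posteriorcingulate_volume", "rh_posteriorcingulate_area")
    thirdOrder <- c(
        "ToMTB_total", "ToMI2_early_subscale_mean",
        "lh_parsorbitalis_meancurv", "rh_superiorparietal_thickness",
        "rh_parsorbitalis_meancurv", "rh_inferiortemporal_meancurv",
        "ToMI2_total_composite_mean", "lh_postcentral_thickness")
    behavioral <- c("ToMTB_total", "ToMI2_total_composite_mean",
                    "ToMI2_early_subscale_mean")
    list(secondOrder = secondOrder,
         thirdOrder = unique(c(thirdOrder,
                               "lh_medialorbitofrontal_thickness")),
         combined = unique(c(secondOrder, behavioral)))
}

#' Re-run the published validation experiments on deposited data
#'
#' If a subject-level CSV with the study's 28 subjects and the printed
#' feature sets is available, runs the three leave-one-out
#' cross-validation experiments (8 features with k = 3, 9 features with
#' k = 7, 11 features with k = 2) and reports their accuracies.  When
#' the file is absent, or lacks the required feature columns, the
#' result records status \code{"not-evaluable"} instead of failing:
#' the deposited supplementary files are not guaranteed to contain the
#' subject-level feature matrix.
#'
#' @param dataPath path to the deposited CSV (subjects x features with
#'   an outcome column).
#' @param targetClass positive class label in that file.
#' @param subjectCol,outcomeCol its column roles.
#' @param featureMap optional named character vector translating this
#'   package's feature names (see [studyFeatureSets()]) to the file's
#'   column names.
#' @param scaling passed to [knnConfig()] — the original analysis does
#'   not state whether features were standardized, so both settings are
#'   worth trying.
#' @return list with \code{status} ("evaluated" or "not-evaluable"),
#'   \code{reason}, and per-experiment accuracies when evaluated.
#' @export
reproduceStudyValidation <- function(dataPath, targetClass = "ASD",
                                     subjectCol = "subject_id",
                                     outcomeCol = "outcome",
                                     featureMap = NULL,
                                     scaling = "zscore") {
    if (!file.exists(dataPath))
        return(list(status = "not-evaluable",
                    reason = sprintf("no file at '%s'", dataPath)))
    table <- tryCatch(
        readFeatureTable(dataPath, subjectCol = subjectCol,
                         outcomeCol = outcomeCol,
                         targetClass = targetClass),
        error = function(e) e)
    if (inherits(table, "error"))
        return(list(status = "not-evaluable",
                    reason = conditionMessage(table)))
    sets <- studyFeatureSets()
    if (!is.null(featureMap))
        sets <- lapply(sets, function(s)
            ifelse(s %in% names(featureMap), featureMap[s], s))
    experiments <- list(
        list(name = "secondOrder", features = sets$secondOrder, k = 3),
        list(name = "thirdOrder", features = sets$thirdOrder, k = 7),
        list(name = "combined", features = sets$combined, k = 2))
    missing <- setdiff(unique(unlist(lapply(experiments, `[[`,
                                            "features"))),
                       rownames(table))
    if (length(missing))
        return(list(status = "not-evaluable",
                    reason = sprintf("feature column(s) absent: %s",
                                     paste(missing, collapse = ", "))))
    results <- lapply(experiments, function(e) {
        res <- loocv(subsetFeatures(table, e$features),
                     knnConfig(k = e$k, scaling = scaling))
        list(name = e$name, k = e$k, accuracy = res$metrics$accuracy,
             cm = res$cm)
    })
    names(results) <- vapply(results, `[[`, character(1), "name")
    list(status = "evaluated", results = results)
}
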