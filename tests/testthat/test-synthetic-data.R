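test_that("planted rules are satisfied exactly as guaranteed", {
    rule <- defaultPlantedRule()
    syn <- generateCohort(nTarget = 7, nOther = 14, rules = list(rule),
                          nNoiseFeatures = 10, leakage = 0, seed = 3)
    m <- evaluateClause(rule@clause, syn$table)
    expect_equal(ppv(m), 1.0)
    expect_equal(classCoverage(m), 1.0)
    # re-scan rows against ground truth across several seeds
    for (s in c(11, 12, 13, 14)) {
        syn <- generateCohort(rules = list(rule), nNoiseFeatures = 5,
                              leakage = 0, seed = s)
        hits <- clauseMatches(rule@clause, syn$table)
        expect_true(all(hits[outcome(syn$table) == "ASD"]))
        expect_false(any(hits[outcome(syn$table) == "NT"]))
    }
})

test_that("identical seeds reproduce bit-identical cohorts", {
    rule <- defaultPlantedRule()
    a <- generateCohort(rules = list(rule), nNoiseFeatures = 8, seed = 77)
    b <- generateCohort(rules = list(rule), nNoiseFeatures = 8, seed = 77)
    expect_identical(featureValues(a$table), featureValues(b$table))
    c <- generateCohort(rules = list(rule), nNoiseFeatures = 8, seed = 78)
    expect_false(identical(featureValues(a$table), featureValues(c$table)))
})

test_that("leakage bounds the non-target subjects matching a rule", {
    rule <- defaultPlantedRule()
    for (s in 1:5) {
        syn <- generateCohort(nTarget = 7, nOther = 14,
                              rules = list(rule), nNoiseFeatures = 4,
                              leakage = 0.5, seed = 20 + s)
        cnt <- oracleCounts(rule@clause, syn$table)
        expect_lte(cnt["n"] - cnt["k"], ceiling(0.5 * 14))
        expect_equal(unname(cnt["k"]), 7L)  # target class always matches
    }
})

test_that("generator output is schema-complete and ground truth stays out",
{
    schema <- featureSchema(c("volume", "thickness", "score", "meancurv"))
    syn <- generateCohort(nTarget = 4, nOther = 6, rules = list(),
                          nNoiseFeatures = 0, schema = schema, seed = 1)
    expect_equal(rownames(syn$table), schema$name)
    expect_equal(syn$rules, list())
    info <- SummarizedExperiment::rowData(syn$table)
    expect_equal(as.character(info$measure), schema$measure)
})

test_that("planted intervals outside the schema support are refused", {
    schema <- featureSchema("thickness")        # N(2.55, 0.15)
    bad <- plantedRule(schema$name[1], lower = 50, upper = 60,
                       targetClass = "ASD")
    expect_error(generateCohort(rules = list(bad), nNoiseFeatures = 2,
                                schema = schema, seed = 1),
                 "support")
})

test_that("null cohorts show the selection effect the pruning addresses", {
    tab <- generateNullCohort(nTarget = 7, nOther = 14, nFeatures = 8,
                              seed = 6)
    ex <- exhaustiveSearch(tab, maxOrder = 1)
    best <- ex[["1"]]$clauses[[1]]
    m <- evaluateClause(best, tab)
    # the best of many scanned first-order clauses beats the prior even
    # though no feature carries signal
    expect_gt(ppv(m), 7 / 21)
    expect_error(generateNullCohort(nFeatures = 0), "positive")
    expect_identical(
        featureValues(generateNullCohort(seed = 4)),
        featureValues(generateNullCohort(seed = 4)))
})

test_that("no-main-effect interaction: equal class means, joint signal", {
    for (s in c(1, 2, 3, 10, 25)) {
        pim <- plantInteractionNoMainEffect(nTarget = 7, nOther = 14,
                                            nNoiseFeatures = 5, seed = s)
        v <- featureValues(pim$table)
        oc <- outcome(pim$table)
        feats <- clauseFeatures(pim$rule@clause)
        for (f in feats)
            expect_equal(mean(v[oc == "ASD", f]), mean(v[oc == "NT", f]),
                         tolerance = 1e-9)
        # the full conjunction is perfect
        joint <- evaluateClause(pim$rule@clause, pim$table)
        expect_equal(ppv(joint), 1.0)
        expect_equal(classCoverage(joint), 1.0)
        # each single-feature projection keeps full coverage but only
        # about prior-level precision (half the non-target class leaks in)
        iv <- clauseIntervals(pim$rule@clause)
        for (f in feats) {
            proj <- conjunctiveClause(f, iv[f, "lower"], iv[f, "upper"])
            pm <- evaluateClause(proj, pim$table)
            expect_equal(classCoverage(pm), 1.0)
            expect_lte(ppv(pm), 0.55)
        }
    }
})

test_that("interaction planting rejects cohorts too small to balance", {
    expect_error(plantInteractionNoMainEffect(nTarget = 3, nOther = 14),
                 "at least 4")
})

test_that("cohort fixtures archive the table with its ground truth", {
    rule <- defaultPlantedRule()
    syn <- generateCohort(rules = list(rule), nNoiseFeatures = 3, seed = 8)
    csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
    writeCohortFixture(syn, csv, js, seed = 8)
    gt <- jsonlite::read_json(js, simplifyVector = TRUE)
    expect_equal(gt$seed, 8)
    expect_equal(gt$rules$features[[1]], c("pf_a", "pf_b"))
    expect_true(file.exists(csv))
})
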