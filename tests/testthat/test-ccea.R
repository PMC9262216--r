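# The evolutionary search is validated against exhaustive enumeration
# (the oracle) on tables small enough to enumerate; its archive
# invariants are checked structurally.  Test configurations are scaled
# down from the defaults — correctness is anchored to the oracle, not
# to any particular budget.

smallConfig <- function(seed = 1, ...)
    cceaConfig(populationSize = 100, generations = 100, runs = 2,
               maxOrder = 3, archiveSize = 20, seed = seed, ...)

test_that("config validation rejects degenerate settings", {
    expect_error(cceaConfig(populationSize = 1), "at least 2")
    expect_error(cceaConfig(mutAdd = 0.5), "sum to 1")
    expect_error(cceaConfig(crossoverRate = 1.5), "\\[0, 1\\]")
})

test_that("search recovers a planted rule at oracle-optimal fitness", {
    rule <- defaultPlantedRule()
    syn <- generateCohort(rules = list(rule), nNoiseFeatures = 6,
                          seed = 31)
    arch <- runCCEA(syn$table, config = smallConfig(seed = 2))
    top <- bestClause(arch, order = 2)
    expect_equal(fitness(top$metrics), log10(choose(21, 7)),
                 tolerance = 1e-9)
    expect_equal(ppv(top$metrics), 1.0)
    expect_equal(classCoverage(top$metrics), 1.0)
    ex <- exhaustiveSearch(syn$table, maxOrder = 2)
    expect_equal(fitness(top$metrics), ex[["2"]]$fitness,
                 tolerance = 1e-9)
    # the planted pair attains the optimum (possibly among ties)
    tab <- archiveTable(arch)
    best2 <- tab[tab$order == 2 &
                 tab$fitness >= ex[["2"]]$fitness - 1e-9, ]
    expect_true(any(grepl("pf_a", best2$clause) &
                    grepl("pf_b", best2$clause)))
})

test_that("search equals the exhaustive optimum on random tables", {
    for (s in 1:6) {
        tab <- generateNullCohort(nTarget = 6, nOther = 10,
                                  nFeatures = 6, seed = 200 + s)
        ex <- exhaustiveSearch(tab)
        best <- max(ex[["1"]]$fitness, ex[["2"]]$fitness)
        arch <- runCCEA(tab, config = cceaConfig(
            populationSize = 100, generations = 100, runs = 3,
            maxOrder = 2, seed = s))
        at <- archiveTable(arch)
        expect_equal(max(at$fitness[at$order <= 2]), best,
                     tolerance = 1e-9)
    }
})

test_that("identical table and config give identical archives", {
    syn <- generateCohort(rules = list(defaultPlantedRule()),
                          nNoiseFeatures = 5, seed = 13)
    a <- archiveTable(runCCEA(syn$table, config = smallConfig(seed = 5)))
    b <- archiveTable(runCCEA(syn$table, config = smallConfig(seed = 5)))
    expect_identical(a, b)
    c <- archiveTable(runCCEA(syn$table, config = smallConfig(seed = 6)))
    expect_false(identical(a, c))
})

test_that("archive entries are unique, sensitivity-pruned and sorted", {
    syn <- generateCohort(rules = list(defaultPlantedRule()),
                          nNoiseFeatures = 8, seed = 17)
    arch <- runCCEA(syn$table, config = smallConfig(seed = 3))
    tab <- archiveTable(arch)
    expect_gt(nrow(tab), 0)
    expect_false(any(duplicated(tab$clause)))
    expect_true(all(table(tab$order) <= arch@archiveSize))
    expect_true(all(tab$fitness > 0))
    # sorted by fitness desc, ties by lower order
    expect_true(all(diff(tab$fitness) <= 1e-12))
    for (e in arch@entries) {
        expect_true(passesSensitivity(e$metrics@sensitivity,
                                      arch@sensitivityThreshold))
        # metrics are faithful: re-evaluating the clause reproduces them
        m <- evaluateClause(e$clause, syn$table)
        expect_equal(fitness(m), e$fitness, tolerance = 1e-12)
        expect_equal(m@nMatch, e$metrics@nMatch)
    }
})

test_that("exhaustive search guards and forced optima behave", {
    tab <- generateNullCohort(nTarget = 4, nOther = 6, nFeatures = 14,
                              seed = 1)
    expect_error(exhaustiveSearch(tab), "refus")
    expect_error(exhaustiveSearch(tab, maxOrder = 3, maxFeatures = 20),
                 "order")

    # one feature perfectly separating the classes forces the optimum
    vals <- cbind(sep = c(1:4, 11:16), junk = rep(c(2, 3), 5))
    sepTab <- makeTable(vals, outcome = rep(c("case", "ctrl"), c(4, 6)))
    ex <- exhaustiveSearch(sepTab, maxOrder = 1)
    best <- ex[["1"]]$clauses[[1]]
    expect_equal(clauseFeatures(best), "sep")
    iv <- clauseIntervals(best)
    expect_equal(unname(iv["sep", ]), c(1, 4))
    expect_equal(ex[["1"]]$fitness, -log10(1 / choose(10, 4)),
                 tolerance = 1e-9)

    # constant features carry no information at all
    constTab <- makeTable(matrix(5, 8, 2),
                          outcome = rep(c("case", "ctrl"), 4))
    exC <- exhaustiveSearch(constTab)
    expect_equal(exC[["1"]]$fitness, 0)
    expect_equal(exC[["2"]]$fitness, 0)
})

test_that("selectParsimonious returns top models of exactly one order", {
    syn <- generateCohort(rules = list(defaultPlantedRule()),
                          nNoiseFeatures = 6, seed = 19)
    arch <- runCCEA(syn$table, config = smallConfig(seed = 7))
    sel <- selectParsimonious(arch, order = 2, topM = 5)
    expect_lte(length(sel), 5)
    expect_true(all(vapply(sel, function(m) clauseOrder(m$clause),
                           integer(1)) == 2L))
    fits <- vapply(sel, function(m) fitness(m$metrics), numeric(1))
    expect_true(all(diff(fits) <= 1e-12))
    # asking beyond the archive returns everything available
    all2 <- selectParsimonious(arch, order = 2, topM = 10000)
    tab <- archiveTable(arch)
    expect_equal(length(all2), sum(tab$order == 2))
    expect_warning(selectParsimonious(arch, order = 5, topM = 3),
                   "no clauses")
})
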