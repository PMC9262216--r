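test_that("clause matching uses closed intervals over all conjuncts", {
    cc <- conjunctiveClause(c("pcc_volume", "rmf_volume"),
                            lower = c(3500, 20000),
                            upper = c(4600, 25000))
    tab <- makeTable(rbind(c(4000, 22000),
                           c(3500, 25000),     # on both boundaries
                           c(4000, 26000)),    # second conjunct violated
                     outcome = c("case", "case", "ctrl"),
                     features = c("pcc_volume", "rmf_volume"))
    expect_equal(unname(clauseMatches(cc, tab)), c(TRUE, TRUE, FALSE))
    expect_error(clauseMatches(conjunctiveClause("ghost", 0, 1), tab),
                 "ghost")
})

test_that("clause construction enforces canonical form and invariants", {
    cc <- conjunctiveClause(c("b_feat", "a_feat"), lower = c(1, 2),
                            upper = c(3, 4))
    expect_equal(clauseFeatures(cc), c("a_feat", "b_feat"))
    expect_equal(clauseOrder(cc), 2L)
    expect_identical(canonicalKey(cc),
                     canonicalKey(conjunctiveClause(
                         c("a_feat", "b_feat"), c(2, 1), c(4, 3))))
    expect_error(conjunctiveClause(character(), numeric(), numeric()))
    expect_error(conjunctiveClause("x", 2, 1))
    expect_error(conjunctiveClause(c("x", "x"), c(0, 0), c(1, 1)))
})

test_that("hypergeometric pmf matches closed forms and dhyper", {
    expect_equal(hypergeomPmf(7, N = 21, K = 7, n = 7), 1 / 116280,
                 tolerance = 1e-12)
    expect_equal(hypergeomPmf(1, N = 4, K = 2, n = 2), 2 / 3,
                 tolerance = 1e-12)
    expect_equal(hypergeomPmf(5, N = 10, K = 5, n = 10), 1.0)
    # exact integer-arithmetic closed form (choose() is exact here)
    for (N in c(10, 21, 35)) for (K in c(3, floor(N / 3))) {
        for (n in c(1, floor(N / 2), N)) {
            ks <- max(0, n - (N - K)):min(n, K)
            exact <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
            expect_equal(hypergeomPmf(ks, N, K, n), exact,
                         tolerance = 1e-12)
        }
    }
    # stats::dhyper as an independent implementation, full support N<=100
    for (N in c(50, 100)) {
        K <- 37 %% N; n <- floor(N / 3)
        ks <- max(0, n - (N - K)):min(n, K)
        expect_equal(hypergeomPmf(ks, N, K, n),
                     stats::dhyper(ks, K, N - K, n), tolerance = 1e-12)
        expect_equal(sum(hypergeomPmf(ks, N, K, n)), 1, tolerance = 1e-12)
    }
    expect_error(hypergeomPmf(3, N = 4, K = 2, n = 2), "support")
    expect_error(hypergeomPmf(0, N = 4, K = 5, n = 2), "K")
})

test_that("a clause matching exactly the target class is maximally fit", {
    # enumerate all admissible (n, k) for the 21-subject configuration
    N <- 21; K <- 7
    pmfs <- unlist(lapply(0:N, function(n) {
        ks <- max(0, n - (N - K)):min(n, K)
        hypergeomPmf(ks, N, K, n)
    }))
    expect_equal(min(pmfs), 1 / choose(21, 7), tolerance = 1e-12)
    expect_equal(hypergeomPmf(7, N, K, 7), min(pmfs), tolerance = 1e-15)
})

test_that("evaluateClause derives fitness, PPV and coverage from counts", {
    rule <- defaultPlantedRule()
    syn <- generateCohort(rules = list(rule), nNoiseFeatures = 6, seed = 4)
    m <- evaluateClause(rule@clause, syn$table)
    expect_equal(fitness(m), log10(116280), tolerance = 1e-9)
    expect_equal(ppv(m), 1.0)
    expect_equal(classCoverage(m), 1.0)
    cnt <- oracleCounts(rule@clause, syn$table)
    expect_equal(m@nMatch, unname(cnt["n"]))
    expect_equal(m@kMatch, unname(cnt["k"]))

    vals <- featureValues(syn$table)
    wide <- conjunctiveClause("noise_001", min(vals[, "noise_001"]),
                              max(vals[, "noise_001"]))
    mWide <- evaluateClause(wide, syn$table)
    expect_equal(mWide@nMatch, 21L)
    expect_equal(fitness(mWide), 0)

    nobody <- conjunctiveClause("noise_001", -2, -1)
    m0 <- evaluateClause(nobody, syn$table)
    expect_true(is.na(ppv(m0)))
    expect_equal(fitness(m0), 0)
    expect_equal(m0@pmf, 1)
})

test_that("dropping a conjunct never shrinks the match set", {
    syn <- generateCohort(rules = list(defaultPlantedRule()),
                          nNoiseFeatures = 8, seed = 15)
    vals <- featureValues(syn$table)
    set.seed(99)
    for (rep in 1:20) {
        feats <- sample(rownames(syn$table), sample(2:4, 1))
        lo <- vapply(feats, function(f) sample(vals[, f], 1), numeric(1))
        hi <- lo + vapply(feats, function(f)
            stats::runif(1, 0, diff(range(vals[, f]))), numeric(1))
        cc <- conjunctiveClause(feats, lo, hi)
        full <- clauseMatches(cc, syn$table)
        for (i in seq_along(feats)) {
            keep <- setdiff(seq_along(feats), i)
            red <- conjunctiveClause(clauseFeatures(cc)[keep],
                                     cc@lower[keep], cc@upper[keep])
            expect_true(all(clauseMatches(red, syn$table) >= full))
        }
    }
})

test_that("feature sensitivity measures each conjunct's contribution", {
    rule <- defaultPlantedRule()
    syn <- generateCohort(rules = list(rule), nNoiseFeatures = 6, seed = 5)
    vals <- featureValues(syn$table)

    # redundant full-range conjunct contributes nothing
    padded <- conjunctiveClause(
        c(clauseFeatures(rule@clause), "noise_003"),
        lower = c(rule@clause@lower, min(vals[, "noise_003"])),
        upper = c(rule@clause@upper, max(vals[, "noise_003"])))
    s <- featureSensitivity(padded, syn$table)
    expect_equal(unname(s["noise_003"]), 0)
    expect_false(passesSensitivity(s))
    expect_true(all(s[clauseFeatures(rule@clause)] > 0))

    # order-1 sensitivity equals the clause's own fitness
    one <- conjunctiveClause("pf_a", 4000, 4600)
    m1 <- evaluateClause(one, syn$table)
    expect_equal(unname(featureSensitivity(one, syn$table)), fitness(m1))

    # no-main-effect interaction: both features contribute
    pim <- plantInteractionNoMainEffect(seed = 6, nNoiseFeatures = 4)
    sInt <- featureSensitivity(pim$rule@clause, pim$table)
    expect_true(all(sInt > 0))
    expect_true(passesSensitivity(sInt))
})

test_that("passesSensitivity applies a strict threshold", {
    expect_false(passesSensitivity(c(f1 = 2.1, f2 = 0.0)))
    expect_true(passesSensitivity(c(f1 = 2.1, f2 = 1.3)))
    expect_false(passesSensitivity(c(f1 = 2.1, f2 = 1.3), threshold = 1.5))
    expect_error(passesSensitivity(numeric()), "not been computed")
})
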