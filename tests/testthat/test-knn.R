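test_that("scaling statistics come from the training rows only", {
    tab <- makeTable(cbind(a = c(1, 1, 1, 1), b = c(0, 2, 4, 6)),
                     outcome = c("case", "case", "ctrl", "ctrl"))
    expect_warning(sc <- fitScaling(tab), "constant")
    expect_equal(unname(sc$scale["a"]), 1)
    expect_equal(unname(sc$scale["b"]), stats::sd(c(0, 2, 4, 6)))
    # single training row: all scales fall back to 1
    expect_warning(sc1 <- fitScaling(tab[, 1]), "constant")
    expect_true(all(sc1$scale == 1))
    # standardized columns have mean 0, sd 1
    syn <- generateCohort(nTarget = 4, nOther = 6, nNoiseFeatures = 5,
                          seed = 44)
    vals <- featureValues(syn$table)
    sc2 <- fitScaling(syn$table)
    z <- sweep(sweep(vals, 2, sc2$center), 2, sc2$scale, "/")
    expect_true(all(abs(colMeans(z)) < 1e-12))
    expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
})

test_that("knnPredict follows plurality and documented tie rules", {
    train <- makeTable(rbind(A = c(0, 0), B = c(0.1, 0),
                             C = c(5, 5), D = c(5.1, 5)),
                       outcome = c("pos", "pos", "neg", "neg"),
                       targetClass = "pos")
    cfgNoScale <- knnConfig(k = 3, scaling = "none")
    expect_equal(knnPredict(train, c(f1 = 0.05, f2 = 0),
                            cfgNoScale), "pos")
    # k=1 on an exact training row returns that row's label
    expect_equal(knnPredict(train, c(f1 = 5, f2 = 5),
                            knnConfig(k = 1, scaling = "none")), "neg")
    # k=2 vote ties resolved by the class of the single nearest neighbor
    # (at (2.51, 2.51) the two nearest are B then C; at (2.53, 2.53)
    # they are C then B — brute-force distance sort confirms)
    expect_equal(knnPredict(train, c(f1 = 2.51, f2 = 2.51),
                            knnConfig(k = 2, scaling = "none")), "pos")
    expect_equal(knnPredict(train, c(f1 = 2.53, f2 = 2.53),
                            knnConfig(k = 2, scaling = "none")), "neg")
    expect_error(knnPredict(train, c(x = 1), cfgNoScale), "feature")
    expect_error(knnPredict(train, c(f1 = 0, f2 = 0),
                            knnConfig(k = 5)), "exceeds")
})

test_that("loocv matches a naive brute-force oracle", {
    for (s in 1:4) {
        n <- c(12, 20, 31, 40)[s]
        syn <- generateCohort(nTarget = floor(n / 3),
                              nOther = n - floor(n / 3),
                              nNoiseFeatures = 5, seed = 500 + s)
        for (k in c(1, 2, 3, 7)) {
            res <- loocv(syn$table, knnConfig(k = k))
            expect_equal(unname(res$predictions),
                         oracleLoocv(syn$table, k))
            # marginals equal the class counts
            cc <- classCounts(syn$table)
            expect_equal(res$cm@tp + res$cm@fn, unname(cc[1]))
            expect_equal(res$cm@fp + res$cm@tn, unname(cc[2]))
        }
    }
})

test_that("loocv handles forced outcomes and degenerate k", {
    # two tight, well-separated clusters: k=1 LOOCV is perfect
    set.seed(1)
    vals <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                  matrix(rnorm(12, 8, 0.1), 6, 2))
    tab <- makeTable(vals, outcome = rep(c("case", "ctrl"), c(5, 6)))
    expect_equal(loocv(tab, knnConfig(k = 1))$metrics$accuracy, 1.0)
    # 2+2 points, k=3: every fold sees 1 friend vs 2 foes, accuracy 0
    quad <- makeTable(rbind(c(0, 0), c(0.2, 0), c(5, 5), c(5.2, 5)),
                      outcome = c("case", "case", "ctrl", "ctrl"))
    expect_equal(loocv(quad, knnConfig(k = 3,
                                       scaling = "none"))$metrics$accuracy,
                 0.0)
    expect_error(loocv(quad, knnConfig(k = 3 + 1)), "too large")
})

test_that("z-scored predictions are invariant to per-feature rescaling", {
    syn <- generateCohort(nTarget = 5, nOther = 9, nNoiseFeatures = 4,
                          seed = 66)
    base <- loocv(syn$table, knnConfig(k = 3))$predictions
    vals <- featureValues(syn$table)
    vals[, 2] <- vals[, 2] * 1000
    vals[, 4] <- vals[, 4] * 0.004
    rescaled <- featureTable(vals, outcome = as.character(outcome(syn$table)),
                             targetClass = "ASD",
                             subjectIds = subjectIds(syn$table))
    expect_equal(loocv(rescaled, knnConfig(k = 3))$predictions, base)
})

test_that("label-permuted separated data scores near the majority rate", {
    set.seed(7)
    vals <- rbind(matrix(rnorm(14, 0, 0.2), 7, 2),
                  matrix(rnorm(28, 6, 0.2), 14, 2))
    accs <- vapply(1:20, function(i) {
        perm <- sample(rep(c("case", "ctrl"), c(7, 14)))
        tab <- makeTable(vals, outcome = perm)
        loocv(tab, knnConfig(k = 3))$metrics$accuracy
    }, numeric(1))
    # chance level for a 7/14 split; binomial error bands around 2/3
    expect_gt(mean(accs), 0.45)
    expect_lt(mean(accs), 0.8)
})

test_that("train/test classification fits scaling on train only", {
    syn <- generateCohort(nTarget = 6, nOther = 12, nNoiseFeatures = 4,
                          seed = 91)
    ids <- subjectIds(syn$table)
    sp <- splitSubjects(syn$table, ids[c(1:4, 7:14)])
    res <- trainTestClassify(sp$selected, sp$remainder, knnConfig(k = 3))
    expect_length(res$predictions, nSubjects(sp$remainder))
    expect_equal(res$cm@tp + res$cm@fn + res$cm@fp + res$cm@tn,
                 nSubjects(sp$remainder))
    expect_error(trainTestClassify(sp$selected, sp$selected,
                                   knnConfig(k = 1)), "overlap")
    # well-separated clusters classify perfectly at k=1
    set.seed(2)
    tr <- makeTable(rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
                          matrix(rnorm(8, 9, 0.1), 4, 2)),
                    outcome = rep(c("case", "ctrl"), c(4, 4)))
    te <- featureTable(matrix(c(0.05, -0.02, 9.1, 8.9), 2, 2,
                              byrow = TRUE,
                              dimnames = list(c("t1", "t2"),
                                              c("f1", "f2"))),
                       outcome = c("case", "ctrl"), targetClass = "case")
    resSep <- trainTestClassify(tr, te, knnConfig(k = 1))
    expect_equal(unname(resSep$predictions), c("case", "ctrl"))
    expect_equal(resSep$metrics$accuracy, 1.0)
})

test_that("matrix metrics reproduce the published arithmetic", {
    cm <- confusionMatrix(tp = 8, fn = 1, fp = 2, tn = 17,
                          targetClass = "ASD", otherClass = "NT")
    m <- matrixMetrics(cm)
    expect_equal(round(100 * m$accuracy, 2), 89.29)
    expect_equal(m$ppv, 0.8)
    expect_equal(m$recall, 8 / 9)
    perfect <- confusionMatrix(tp = 3, fn = 0, fp = 0, tn = 13,
                               targetClass = "ASD", otherClass = "NT")
    expect_equal(matrixMetrics(perfect)$accuracy, 1.0)
    none <- confusionMatrix(tp = 0, fn = 2, fp = 0, tn = 5,
                            targetClass = "ASD", otherClass = "NT")
    expect_true(is.na(matrixMetrics(none)$ppv))
})
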