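#' Configuration for the conjunctive clause evolutionary algorithm
#'
#' Hyperparameters of the generational evolutionary search.  The
#' defaults are standard Michigan-style rule-evolution settings;
#' correctness of the search is anchored to [exhaustiveSearch()] rather
#' than to any particular choice here.  Candidate interval bounds
#' always snap to values observed in the training table, which keeps
#' the search space finite and the reported clauses reproducible.
#'
#' @param populationSize individuals per generation (>= 2).
#' @param generations generations per run.
#' @param runs independent repetitions whose archives are merged
#'   (default 5, to search the fitness landscape more thoroughly).
#' @param maxOrder largest clause order explored (default 5).
#' @param archiveSize best unique clauses retained per order.
#' @param mutAdd,mutDrop,mutMove,mutReplace probabilities of the four
#'   mutation operators (add a conjunct, drop one, move one interval
#'   bound to the adjacent observed value, replace a feature); must sum
#'   to 1 — every offspring undergoes exactly one.
#' @param crossoverRate probability a selected pair exchanges conjuncts
#'   (uniform per-feature exchange).
#' @param tournamentSize selection tournament size.
#' @param sensitivityThreshold minimum per-feature fitness contribution
#'   a clause must show to enter the archive (strictly greater than;
#'   default 0).
#' @param seed root seed; run r uses \code{seed + r}.
#' @return validated list of class \code{cceaConfig}.
#' @export
cceaConfig <- function(populationSize = 200, generations = 500, runs = 5,
                       maxOrder = 5, archiveSize = 50,
                       mutAdd = 0.2, mutDrop = 0.2, mutMove = 0.4,
                       mutReplace = 0.2, crossoverRate = 0.5,
                       tournamentSize = 3, sensitivityThreshold = 0,
                       seed = 1) {
    cfg <- list(populationSize = as.integer(populationSize),
                generations = as.integer(generations),
                runs = as.integer(runs), maxOrder = as.integer(maxOrder),
                archiveSize = as.integer(archiveSize),
                mutAdd = mutAdd, mutDrop = mutDrop, mutMove = mutMove,
                mutReplace = mutReplace, crossoverRate = crossoverRate,
                tournamentSize = as.integer(tournamentSize),
                sensitivityThreshold = sensitivityThreshold,
                seed = as.integer(seed))
    stopIf(cfg$populationSize < 2L, "population must hold at least 2")
    stopIf(cfg$generations < 1L || cfg$runs < 1L || cfg$archiveSize < 1L,
           "generations, runs and archiveSize must be positive")
    stopIf(cfg$maxOrder < 1L, "maxOrder must be at least 1")
    probs <- c(cfg$mutAdd, cfg$mutDrop, cfg$mutMove, cfg$mutReplace,
               cfg$crossoverRate)
    stopIf(any(probs < 0) || any(probs > 1),
           "operator probabilities must lie in [0, 1]")
    stopIf(abs(cfg$mutAdd + cfg$mutDrop + cfg$mutMove + cfg$mutReplace - 1)
           > 1e-9, "the four mutation probabilities must sum to 1")
    class(cfg) <- "cceaConfig"
    cfg
}

# --- internal search context -------------------------------------------

# Precomputes everything clause evaluation needs: the value matrix, the
# class indicator, per-feature sorted unique observed values (the only
# admissible interval bounds) and the full fitness lookup table.
searchContext <- function(table, target) {
    vals <- featureValues(table)
    targ <- outcome(table) == target
    list(vals = vals, targ = targ, N = nrow(vals), K = sum(targ),
         P = ncol(vals), featNames = colnames(vals),
         uniq = lapply(seq_len(ncol(vals)), function(j)
             sort(unique(vals[, j]))),
         F = fitnessLookup(nrow(vals), sum(targ), directed = TRUE),
         Fraw = fitnessLookup(nrow(vals), sum(targ)),
         cache = new.env(parent = emptyenv()))
}

# Interval-by-subject membership matrix for one feature: row (i, j) of
# M marks the subjects whose value lies in [u_i, u_j] for every bound
# pair i <= j of the sorted unique observed values.  Cached per feature.
featIntervalMatrix <- function(ctx, f) {
    key <- as.character(f)
    hit <- ctx$cache[[key]]
    if (!is.null(hit)) return(hit)
    u <- ctx$uniq[[f]]
    L <- length(u)
    ii <- rep(seq_len(L), times = rev(seq_len(L)))
    jj <- unlist(lapply(seq_len(L), function(i) i:L))
    ge <- outer(u, ctx$vals[, f], "<=")
    le <- outer(u, ctx$vals[, f], ">=")
    out <- list(M = (ge[ii, , drop = FALSE] & le[jj, , drop = FALSE]) * 1,
                ii = ii, jj = jj)
    ctx$cache[[key]] <- out
    out
}

# Exact coordinate descent on interval bounds: holding the other
# conjuncts fixed, each conjunct's interval is replaced by the provably
# best bound pair for its feature; sweeps repeat until no conjunct
# improves.  Fitness never decreases.
refineBounds <- function(ind, ctx) {
    stats <- evalIndividual(ind, ctx)
    repeat {
        improved <- FALSE
        for (i in seq_along(ind$f)) {
            rest <- rep(TRUE, ctx$N)
            for (j in seq_along(ind$f)[-i]) {
                u <- ctx$uniq[[ind$f[j]]]
                v <- ctx$vals[, ind$f[j]]
                rest <- rest & v >= u[ind$lo[j]] & v <= u[ind$hi[j]]
            }
            fm <- featIntervalMatrix(ctx, ind$f[i])
            n <- as.vector(fm$M %*% rest)
            k <- as.vector(fm$M %*% (rest & ctx$targ))
            fit <- ctx$F[cbind(n + 1, k + 1)]
            h <- which.max(fit)
            if (fit[h] > stats[3] + 1e-12) {
                ind$lo[i] <- fm$ii[h]; ind$hi[i] <- fm$jj[h]
                stats <- c(n[h], k[h], fit[h])
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    list(ind = ind, stats = stats)
}

# Individuals are lists: f = feature indices, lo/hi = indices into the
# feature's sorted unique values.  Returns c(n, k, fitness).
evalIndividual <- function(ind, ctx) {
    m <- rep(TRUE, ctx$N)
    for (i in seq_along(ind$f)) {
        u <- ctx$uniq[[ind$f[i]]]
        v <- ctx$vals[, ind$f[i]]
        m <- m & v >= u[ind$lo[i]] & v <= u[ind$hi[i]]
    }
    n <- sum(m)
    k <- sum(m & ctx$targ)
    c(n, k, ctx$F[n + 1L, k + 1L])
}

indKey <- function(ind) {
    o <- sort.list(ind$f, method = "radix")
    paste(ind$f[o], ind$lo[o], ind$hi[o], sep = ":", collapse = "|")
}

randomConjunct <- function(ctx, exclude = integer()) {
    f <- sample(setdiff(seq_len(ctx$P), exclude), 1L)
    b <- sample.int(length(ctx$uniq[[f]]), 2L, replace = TRUE)
    list(f = f, lo = min(b), hi = max(b))
}

randomIndividual <- function(ctx, maxOrder) {
    ord <- sample.int(min(3L, maxOrder), 1L)
    ind <- list(f = integer(), lo = integer(), hi = integer())
    for (i in seq_len(ord)) {
        cj <- randomConjunct(ctx, exclude = ind$f)
        ind$f <- c(ind$f, cj$f); ind$lo <- c(ind$lo, cj$lo)
        ind$hi <- c(ind$hi, cj$hi)
    }
    ind
}

mutateIndividual <- function(ind, ctx, cfg) {
    op <- sample.int(4L, 1L, prob = c(cfg$mutAdd, cfg$mutDrop, cfg$mutMove,
                                      cfg$mutReplace))
    ord <- length(ind$f)
    if (op == 1L && ord < cfg$maxOrder && ord < ctx$P) {
        cj <- randomConjunct(ctx, exclude = ind$f)
        ind$f <- c(ind$f, cj$f); ind$lo <- c(ind$lo, cj$lo)
        ind$hi <- c(ind$hi, cj$hi)
    } else if (op == 2L && ord > 1L) {
        i <- sample.int(ord, 1L)
        ind$f <- ind$f[-i]; ind$lo <- ind$lo[-i]; ind$hi <- ind$hi[-i]
    } else if (op == 3L) {
        i <- sample.int(ord, 1L)
        L <- length(ctx$uniq[[ind$f[i]]])
        if (stats::runif(1) < 0.5) {
            ind$lo[i] <- max(1L, min(ind$hi[i],
                                     ind$lo[i] + sample(c(-1L, 1L), 1L)))
        } else {
            ind$hi[i] <- min(L, max(ind$lo[i],
                                    ind$hi[i] + sample(c(-1L, 1L), 1L)))
        }
    } else if (op == 4L && ctx$P > ord) {
        i <- sample.int(ord, 1L)
        cj <- randomConjunct(ctx, exclude = ind$f[-i])
        ind$f[i] <- cj$f; ind$lo[i] <- cj$lo; ind$hi[i] <- cj$hi
    }
    ind
}

# Uniform per-feature conjunct exchange between two parents.
crossoverPair <- function(p1, p2, ctx, cfg) {
    pool <- list(f = c(p1$f, p2$f), lo = c(p1$lo, p2$lo),
                 hi = c(p1$hi, p2$hi))
    take1 <- stats::runif(length(pool$f)) < 0.5
    # a feature present in both parents contributes both intervals; keep
    # at most one conjunct per feature per child
    mk <- function(sel) {
        idx <- which(sel)
        idx <- idx[!duplicated(pool$f[idx])]
        if (length(idx) > cfg$maxOrder)
            idx <- sample(idx, cfg$maxOrder)
        list(f = pool$f[idx], lo = pool$lo[idx], hi = pool$hi[idx])
    }
    c1 <- mk(take1); c2 <- mk(!take1)
    if (length(c1$f) == 0L) { c1 <- p1 }
    if (length(c2$f) == 0L) { c2 <- p2 }
    list(c1, c2)
}

indToClause <- function(ind, ctx) {
    conjunctiveClause(ctx$featNames[ind$f],
                      lower = vapply(seq_along(ind$f), function(i)
                          ctx$uniq[[ind$f[i]]][ind$lo[i]], numeric(1)),
                      upper = vapply(seq_along(ind$f), function(i)
                          ctx$uniq[[ind$f[i]]][ind$hi[i]], numeric(1)))
}

# Per-feature sensitivity on index representation (cheap: one reduced
# evaluation per conjunct).  Differences use the plain (undirected)
# fitness, matching featureSensitivity() on clause objects.
indSensitivity <- function(ind, fit, ctx) {
    ord <- length(ind$f)
    if (ord == 1L) {
        s <- fit
    } else {
        s <- vapply(seq_len(ord), function(i) {
            red <- list(f = ind$f[-i], lo = ind$lo[-i], hi = ind$hi[-i])
            st <- evalIndividual(red, ctx)
            fit - ctx$Fraw[st[1] + 1L, st[2] + 1L]
        }, numeric(1))
    }
    names(s) <- ctx$featNames[ind$f]
    s
}

# One evolutionary run; archive entries accumulate into `arc` (an
# environment holding per-order lists and a seen-key set).
cceaRun <- function(ctx, cfg, arc, run) {
    pop <- lapply(seq_len(cfg$populationSize), function(i)
        randomIndividual(ctx, cfg$maxOrder))
    for (gen in seq_len(cfg$generations)) {
        stats <- vapply(pop, evalIndividual, numeric(3), ctx = ctx)
        fits <- stats[3, ]
        archiveOffer(pop, stats, ctx, cfg, arc, run, gen)
        if (gen == cfg$generations) break
        best <- which.max(fits)
        # tournament selection (vectorized; sampling with replacement)
        cand <- matrix(sample.int(cfg$populationSize,
                                  cfg$populationSize * cfg$tournamentSize,
                                  replace = TRUE),
                       cfg$populationSize, cfg$tournamentSize)
        fitsM <- matrix(fits[cand], nrow(cand), ncol(cand))
        parents <- cand[cbind(seq_len(nrow(cand)),
                              max.col(fitsM, ties.method = "first"))]
        nxt <- vector("list", cfg$populationSize)
        i <- 1L
        while (i <= cfg$populationSize) {
            p1 <- pop[[parents[i]]]
            p2 <- pop[[parents[if (i < cfg$populationSize) i + 1L else 1L]]]
            if (stats::runif(1) < cfg$crossoverRate) {
                kids <- crossoverPair(p1, p2, ctx, cfg)
            } else {
                kids <- list(p1, p2)
            }
            nxt[[i]] <- mutateIndividual(kids[[1]], ctx, cfg)
            if (i < cfg$populationSize)
                nxt[[i + 1L]] <- mutateIndividual(kids[[2]], ctx, cfg)
            i <- i + 2L
        }
        nxt[[1L]] <- pop[[best]]          # elitism
        pop <- nxt
    }
    invisible(NULL)
}

# Offer the current population to the archive: candidates with positive
# fitness, not yet seen, that would improve (or fit into) their order's
# list are sensitivity-checked and inserted.  A cheap per-order fitness
# floor (arc$minFit) screens candidates before the costly key/sensitivity
# work; the floor only ever rises, so screened-out clauses stay out.
archiveOffer <- function(pop, stats, ctx, cfg, arc, run, gen) {
    ords <- vapply(pop, function(p) length(p$f), integer(1))
    worth <- which(stats[1, ] > 0 & stats[3, ] > 0 &
                   stats[3, ] > arc$minFit[ords])
    for (i in worth) {
        ind <- pop[[i]]
        rawKey <- indKey(ind)
        if (!is.null(arc$seen[[rawKey]])) next
        arc$seen[[rawKey]] <- TRUE
        # polish bounds to the exact per-conjunct optimum before judging
        ref <- refineBounds(ind, ctx)
        ind <- ref$ind
        fit <- ref$stats[3]
        key <- indKey(ind)
        if (!identical(key, rawKey)) {
            if (!is.null(arc$seen[[key]])) next
            arc$seen[[key]] <- TRUE
        }
        ord <- ords[i]
        if (fit <= arc$minFit[ord]) next
        sens <- indSensitivity(ind, fit, ctx)
        if (!all(sens > cfg$sensitivityThreshold)) next
        lst <- arc$orders[[ord]]
        lst[[length(lst) + 1L]] <- list(
            ind = ind, fitness = fit, n = ref$stats[1], k = ref$stats[2],
            sensitivity = sens, run = run, generation = gen, key = key)
        o <- base::order(-vapply(lst, `[[`, numeric(1), "fitness"),
                         vapply(lst, `[[`, character(1), "key"),
                         method = "radix")
        lst <- lst[o]
        if (length(lst) > cfg$archiveSize)
            lst <- lst[seq_len(cfg$archiveSize)]
        arc$orders[[ord]] <- lst
        if (length(lst) >= cfg$archiveSize)
            arc$minFit[ord] <- lst[[length(lst)]]$fitness
    }
}

#' Run the conjunctive clause evolutionary algorithm
#'
#' Executes \code{config$runs} independent generational evolutionary
#' searches (run r seeded with \code{seed + r}) over clauses whose
#' interval bounds snap to observed feature values, scores candidates
#' with the hypergeometric-PMF fitness, discards any clause in which
#' some feature contributes no fitness (the sensitivity criterion), and
#' merges the per-run elite archives with de-duplication.  Only clauses
#' positively associated with the target class (PPV above the class
#' prior) are archived: the hypergeometric improbability alone is
#' two-sided, and a clause matching exactly the controls is a model of
#' the wrong class.  Offered candidates are polished by an exact
#' per-conjunct bound refinement (coordinate descent over observed
#' values) before archiving.  The result is deterministic given the
#' table and configuration.
#'
#' @param table a [FeatureTable-class] (the discovery cohort).
#' @param target positive class label; defaults to
#'   \code{targetClass(table)}.
#' @param config a [cceaConfig()].
#' @return a [ClauseArchive-class]; entries sorted by descending
#'   fitness, ties broken by lower order then lexicographic canonical
#'   form.
#' @examples
#' rule <- plantedRule(c("noise_001", "noise_006"), lower = c(3500, 2.55),
#'                     upper = c(4600, 2.8), targetClass = "ASD")
#' syn <- generateCohort(rules = list(rule), nNoiseFeatures = 10, seed = 7)
#' arch <- runCCEA(syn$table,
#'                 config = cceaConfig(generations = 60, runs = 2))
#' head(archiveTable(arch))
#' @export
runCCEA <- function(table, target = targetClass(table),
                    config = cceaConfig()) {
    stopIf(!methods::is(table, "FeatureTable"),
           "'table' must be a FeatureTable")
    stopIf(!inherits(config, "cceaConfig"),
           "'config' must come from cceaConfig()")
    ctx <- searchContext(table, target)
    arc <- new.env(parent = emptyenv())
    arc$orders <- rep(list(list()), config$maxOrder)
    arc$minFit <- rep(-Inf, config$maxOrder)
    arc$seen <- new.env(parent = emptyenv())
    for (r in seq_len(config$runs))
        withSeed(config$seed + r, cceaRun(ctx, config, arc, r))
    entries <- list()
    for (ord in seq_along(arc$orders)) {
        for (e in arc$orders[[ord]]) {
            clause <- indToClause(e$ind, ctx)
            metrics <- metricsFromCounts(e$k, ctx$N, ctx$K, e$n,
                                         sensitivity = e$sensitivity)
            entries[[length(entries) + 1L]] <- list(
                clause = clause, metrics = metrics, order = ord,
                fitness = e$fitness, run = e$run,
                generation = e$generation, key = canonicalKey(clause))
        }
    }
    if (length(entries)) {
        o <- base::order(-vapply(entries, `[[`, numeric(1), "fitness"),
                   vapply(entries, `[[`, numeric(1), "order"),
                   vapply(entries, `[[`, character(1), "key"))
        entries <- entries[o]
    }
    methods::new("ClauseArchive", entries = entries,
                 maxOrder = config$maxOrder,
                 archiveSize = config$archiveSize,
                 sensitivityThreshold = config$sensitivityThreshold)
}

#' Tabulate a clause archive
#'
#' @param x a [ClauseArchive-class].
#' @param ... ignored.
#' @return data.frame with one row per archived clause: order, fitness,
#'   match counts, PPV, class coverage, clause text, run and generation
#'   of first discovery.
#' @export
setMethod("archiveTable", "ClauseArchive", function(x, ...) {
    if (length(x@entries) == 0L)
        return(data.frame(order = integer(), fitness = numeric(),
                          nMatch = integer(), kMatch = integer(),
                          ppv = numeric(), classCoverage = numeric(),
                          clause = character(), run = integer(),
                          generation = integer()))
    do.call(rbind, lapply(x@entries, function(e) data.frame(
        order = e$order, fitness = e$fitness,
        nMatch = e$metrics@nMatch, kMatch = e$metrics@kMatch,
        ppv = ppv(e$metrics), classCoverage = classCoverage(e$metrics),
        clause = canonicalKey(e$clause), run = e$run,
        generation = e$generation)))
})

#' @export
#' @describeIn ClauseArchive display summary per order.
setMethod("show", "ClauseArchive", function(object) {
    cat(sprintf("ClauseArchive: %d clauses (max order %d)\n",
                length(object@entries), object@maxOrder))
    tab <- archiveTable(object)
    if (nrow(tab))
        for (ord in sort(unique(tab$order))) {
            sub <- tab[tab$order == ord, ]
            cat(sprintf("  order %d: %d clauses, best fitness %.4f\n",
                        ord, nrow(sub), max(sub$fitness)))
        }
})

#' Best archived clause
#'
#' @param x a [ClauseArchive-class].
#' @param order restrict to clauses of exactly this order (default:
#'   any).
#' @param ... ignored.
#' @return list with \code{clause} and \code{metrics}, or NULL when the
#'   archive holds no clause of that order.
#' @export
setMethod("bestClause", "ClauseArchive", function(x, order = NULL, ...) {
    entries <- x@entries
    if (!is.null(order))
        entries <- Filter(function(e) e$order == order, entries)
    if (length(entries) == 0L) return(NULL)
    entries[[1L]][c("clause", "metrics")]
})

#' Select the most parsimonious high-fitness models
#'
#' Returns the \code{topM} highest-fitness archived clauses of exactly
#' the requested order — the "best performing models of lowest order"
#' selection step that precedes each KNN experiment.
#'
#' @param archive a [ClauseArchive-class].
#' @param order clause order to select (e.g. 2 for two-feature models).
#' @param topM number of models to return; when the archive holds
#'   fewer, all are returned.
#' @return list of \code{list(clause=, metrics=)}, possibly empty (with
#'   a warning) when no clause of that order was archived.
#' @export
selectParsimonious <- function(archive, order, topM) {
    stopIf(!methods::is(archive, "ClauseArchive"),
           "'archive' must be a ClauseArchive")
    entries <- Filter(function(e) e$order == order, archive@entries)
    if (length(entries) == 0L) {
        warning(sprintf("archive holds no clauses of order %d", order))
        return(list())
    }
    lapply(entries[seq_len(min(topM, length(entries)))],
           function(e) e[c("clause", "metrics")])
}
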