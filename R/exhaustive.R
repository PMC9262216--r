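#' Exhaustive clause search (test oracle)
#'
#' Enumerates every clause of order 1 and 2 whose interval bounds are
#' pairs of observed feature values — the same candidate space the
#' evolutionary search explores — and returns the provably
#' fitness-optimal clause(s) per order, under the same target-class
#' direction the search uses (clauses whose PPV does not exceed the
#' class prior score 0).  Tractable only for small tables, so guarded:
#' refuses more than \code{maxFeatures} features or an order above 2.
#'
#' @param table a [FeatureTable-class].
#' @param target positive class label (default the table's target
#'   class).
#' @param maxOrder 1 or 2.
#' @param maxFeatures guard on the number of features (default 12).
#' @param maxTies at most this many equally-optimal clauses are
#'   materialized per order (the full count is always reported).
#' @return list with one element per order: \code{list(order, fitness,
#'   nOptima, clauses)} where \code{clauses} holds up to \code{maxTies}
#'   optimal [ConjunctiveClause-class] objects.
#' @export
exhaustiveSearch <- function(table, target = targetClass(table),
                             maxOrder = 2, maxFeatures = 12,
                             maxTies = 25) {
    stopIf(maxOrder > 2, "exhaustive search supports order <= 2 only")
    stopIf(nFeatures(table) > maxFeatures,
           "refusing exhaustive search over %d features (guard: %d)",
           nFeatures(table), maxFeatures)
    ctx <- searchContext(table, target)
    tol <- 1e-9

    # per feature: logical interval-by-subject match matrices over all
    # bound pairs (i <= j) of the sorted unique observed values
    featM <- lapply(seq_len(ctx$P), function(f) {
        u <- ctx$uniq[[f]]
        L <- length(u)
        ii <- rep(seq_len(L), times = rev(seq_len(L)))
        jj <- unlist(lapply(seq_len(L), function(i) i:L))
        ge <- outer(u, ctx$vals[, f], "<=")   # u[i] <= value
        le <- outer(u, ctx$vals[, f], ">=")   # u[j] >= value
        M <- ge[ii, , drop = FALSE] & le[jj, , drop = FALSE]
        list(M = M * 1, ii = ii, jj = jj)
    })

    out <- list()
    # ---- order 1 ----
    best1 <- -Inf; opt1 <- list(); n1 <- 0L
    for (f in seq_len(ctx$P)) {
        fm <- featM[[f]]
        n <- rowSums(fm$M); k <- rowSums(fm$M[, ctx$targ, drop = FALSE])
        fit <- ctx$F[cbind(n + 1, k + 1)]
        mx <- max(fit)
        if (mx > best1 + tol) { best1 <- mx; opt1 <- list(); n1 <- 0L }
        if (mx >= best1 - tol) {
            hits <- which(fit >= best1 - tol)
            n1 <- n1 + length(hits)
            for (h in hits) {
                if (length(opt1) >= maxTies) break
                u <- ctx$uniq[[f]]
                opt1[[length(opt1) + 1L]] <- conjunctiveClause(
                    ctx$featNames[f], u[fm$ii[h]], u[fm$jj[h]])
            }
        }
    }
    out[["1"]] <- list(order = 1L, fitness = best1, nOptima = n1,
                       clauses = opt1)

    if (maxOrder >= 2 && ctx$P >= 2) {
        best2 <- -Inf; opt2 <- list(); n2 <- 0L
        targM <- which(ctx$targ)
        for (f in seq_len(ctx$P - 1L)) {
            Mf <- featM[[f]]$M
            Kf <- Mf[, targM, drop = FALSE]
            for (g in (f + 1L):ctx$P) {
                Mg <- featM[[g]]$M
                n <- Mf %*% t(Mg)
                k <- Kf %*% t(Mg[, targM, drop = FALSE])
                fit <- matrix(ctx$F[cbind(as.vector(n) + 1,
                                          as.vector(k) + 1)],
                              nrow(n), ncol(n))
                mx <- max(fit)
                if (mx > best2 + tol) {
                    best2 <- mx; opt2 <- list(); n2 <- 0L
                }
                if (mx >= best2 - tol) {
                    hits <- which(fit >= best2 - tol, arr.ind = TRUE)
                    n2 <- n2 + nrow(hits)
                    uf <- ctx$uniq[[f]]; ug <- ctx$uniq[[g]]
                    for (h in seq_len(nrow(hits))) {
                        if (length(opt2) >= maxTies) break
                        i <- hits[h, 1]; j <- hits[h, 2]
                        opt2[[length(opt2) + 1L]] <- conjunctiveClause(
                            ctx$featNames[c(f, g)],
                            lower = c(uf[featM[[f]]$ii[i]],
                                      ug[featM[[g]]$ii[j]]),
                            upper = c(uf[featM[[f]]$jj[i]],
                                      ug[featM[[g]]$jj[j]]))
                    }
                }
            }
        }
        out[["2"]] <- list(order = 2L, fitness = best2, nOptima = n2,
                           clauses = opt2)
    }
    out
}
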