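makeAvg <- function(lin) {
    avg <- log2(lin)
    attr(avg, "linear") <- lin
    avg
}

test_that("low-expression filter removes only genes at/below 30 in every cell", {
    lin <- rbind(allLow = rep(30, 4), oneUp = c(30, 30, 31, 30),
                 high = rep(100, 4))
    colnames(lin) <- paste0("c", 1:4)
    out <- filterLowExpression(makeAvg(lin))
    expect_setequal(rownames(out), c("oneUp", "high"))
    expect_error(filterLowExpression(makeAvg(lin), threshold = -1),
                 "non-negative")
    none <- filterLowExpression(makeAvg(lin[1, , drop = FALSE]))
    expect_equal(nrow(none), 0L)                 # empty result allowed
})

test_that("fuzzy memberships stay on the simplex and k = 1 is degenerate", {
    set.seed(31)
    prof <- matrix(rnorm(48), 8, 6)
    rownames(prof) <- paste0("g", 1:8)
    p1 <- fannyCluster(prof, k = 1)
    expect_true(all(membership(p1) == 1))
    p2 <- fannyCluster(prof, k = 3, seed = 2)
    expect_true(all(abs(rowSums(membership(p2)) - 1) < 1e-9))
    expect_true(all(membership(p2) >= 0))
    expect_error(fannyCluster(prof, k = 9), "more clusters")
})

test_that("well-separated duplicated profiles cluster crisply to the planted split", {
    base1 <- c(2, -1, 0, 1, -2, 0.5)
    base2 <- -base1
    prof <- rbind(a1 = base1, a2 = base1 + 1e-6, a3 = base1 - 1e-6,
                  b1 = base2, b2 = base2 + 1e-6, b3 = base2 - 1e-6)
    part <- fannyCluster(prof, k = 2, seed = 4)
    U <- membership(part)
    expect_true(all(apply(U, 1, max) > 0.99))
    top <- apply(U, 1, which.max)
    expect_equal(length(unique(top[1:3])), 1L)
    expect_equal(length(unique(top[4:6])), 1L)
    expect_false(top[1] == top[4])
})

test_that("objective is non-increasing as the sweep budget grows", {
    set.seed(17)
    prof <- matrix(rnorm(120), 20, 6)
    rownames(prof) <- paste0("g", 1:20)
    objs <- vapply(c(1, 2, 4, 8, 16, 50), function(it)
        suppressWarnings(fannyCluster(prof, k = 3, maxIter = it,
                                      nStarts = 1L)@objective),
        numeric(1))
    expect_true(all(diff(objs) <= 1e-10))
})

test_that("the fitted objective matches a multi-start numeric oracle (8 genes, k = 2)", {
    set.seed(1)
    prof <- matrix(rnorm(48), 8, 6)
    prof[1:4, ] <- prof[1:4, ] + rep(c(2, -2, 1, -1), 6)
    rownames(prof) <- paste0("g", 1:8)
    D <- 1 - stats::cor(t(prof)); diag(D) <- 0
    obj <- function(U) { X <- U^2; M <- D %*% X
        sum(colSums(X * M) / (2 * colSums(X))) }
    softmaxObj <- function(th) {
        U <- exp(matrix(th, 8, 2)); obj(U / rowSums(U)) }
    best <- Inf
    for (i in 1:200) {
        r <- stats::optim(rnorm(16), softmaxObj, method = "BFGS",
                          control = list(maxit = 400, reltol = 1e-13))
        best <- min(best, r$value)
    }
    fit <- fannyCluster(prof, k = 2, nStarts = 3L, seed = 5)
    expect_lt(abs(fit@objective - best), 1e-6)
    # independent reference implementation agrees
    cf <- cluster::fanny(stats::as.dist(D), k = 2, memb.exp = 2)
    expect_lt(abs(fit@objective - cf$objective[["objective"]]), 1e-6)
})

test_that("core membership uses the 0.44 gate with lowest-index tie-break", {
    U <- rbind(g1 = c(0.5, 0.5), g2 = c(0.43, 0.57), g3 = c(0.6, 0.4))
    part <- new("FuzzyPartition", membership = U, objective = 0,
                iterations = 1L, converged = TRUE)
    prof <- matrix(rnorm(6), 3, 2, dimnames = list(rownames(U), NULL))
    cg <- coreGenes(part, prof, m = 0.44)
    expect_setequal(cg$cores[[1]], c("g1", "g3"))  # tie goes to cluster 1
    expect_equal(cg$cores[[2]], "g2")
    # uniform memberships below the gate leave no cores
    U15 <- matrix(1 / 15, 2, 15,
                  dimnames = list(c("a", "b"), NULL))
    part15 <- new("FuzzyPartition", membership = U15, objective = 0,
                  iterations = 1L, converged = TRUE)
    expect_error(coreGenes(part15, matrix(0, 2, 4), m = 0.44), "lower")
})

test_that("prototype merging is greedy highest-r-first and respects the threshold", {
    p <- rbind(A = c(1, 0, -1, 0.5), B = c(1, 0, -1, 0.5))
    mg <- mergeClusters(p, mergeR = 0.9)
    expect_equal(nrow(mg$prototypes), 1L)        # identical pair merged
    expect_setequal(mg$provenance[[1]], c("A", "B"))
    anti <- rbind(A = c(1, -1, 1, -1), B = c(-1, 1, -1, 1))
    expect_equal(nrow(mergeClusters(anti, mergeR = 0.9)$prototypes), 2L)
    # chain case equals an explicit agglomerative oracle
    set.seed(3)
    base <- rnorm(6)
    pa <- base; pb <- base + rnorm(6, sd = 0.25)
    pc <- pb + rnorm(6, sd = 0.25)
    chain <- rbind(A = pa, B = pb, C = pc)
    thresh <- 0.8
    oracleCount <- local({
        protos <- chain; w <- rep(1, 3)
        repeat {
            if (nrow(protos) == 1L) break
            cc <- stats::cor(t(protos)); cc[lower.tri(cc, diag = TRUE)] <- -Inf
            mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
            if (cc[mx[1], mx[2]] < thresh) break
            protos[mx[1], ] <- (w[mx[1]] * protos[mx[1], ] +
                                w[mx[2]] * protos[mx[2], ]) /
                               (w[mx[1]] + w[mx[2]])
            w[mx[1]] <- w[mx[1]] + w[mx[2]]
            protos <- protos[-mx[2], , drop = FALSE]; w <- w[-mx[2]]
        }
        nrow(protos)
    })
    expect_equal(nrow(mergeClusters(chain, mergeR = thresh)$prototypes),
                 oracleCount)
})

test_that("gene assignment is correlation-gated, flagged for flat profiles,
           and scale/shift invariant", {
    protos <- rbind(DP01 = c(2, -1, 0, -1), DP02 = c(-2, 1, 0, 1))
    prof <- rbind(match = c(2, -1, 0, -1) * 3 + 5,    # scaled/shifted copy
                  flat = rep(4, 4),
                  far = c(0.1, 2, -2, 0.1))
    asn <- assignGenes(prof, protos, rMin = 0.85)
    expect_equal(asn$pattern[asn$gene == "match"], "DP01")
    expect_equal(asn$r[asn$gene == "match"], 1)
    expect_true(is.na(asn$pattern[asn$gene == "flat"]))
    expect_equal(asn$flag[asn$gene == "flat"], "undefined correlation")
    expect_true(is.na(asn$pattern[asn$gene == "far"]))
})

test_that("planted pattern sets are recovered by the full DP procedure", {
    for (s in 1:2) {
        d <- smallDesign(nGenes = 520L)
        tr <- simulateTruth(d, nPatterns = 13L, unassignedFraction = 0,
                            absentFraction = 0, dePerContrast = 0L,
                            seed = s)
        x <- simulateExpression(d, tr, noiseSd = 0.2, seed = 100 + s)
        dps <- dominantPatterns(x, seed = s)
        expect_equal(nrow(prototypes(dps)), 13L)
        cc <- stats::cor(t(prototypes(dps)), t(tr@prototypes))
        mapBack <- rownames(tr@prototypes)[apply(cc, 1, which.max)]
        names(mapBack) <- rownames(prototypes(dps))
        a <- as.data.frame(assignments(dps))
        acc <- mean(mapBack[a$pattern] ==
                    tr@patternAssignments[a$gene], na.rm = TRUE)
        expect_gte(acc, 0.95)
    }
})
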