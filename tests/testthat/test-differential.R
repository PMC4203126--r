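test_that("fold change is signed 2^|delta| with an inclusive boundary at 2", {
    m <- rbind(flat = c(5, 5, 5, 5), up1 = c(5, 5, 6, 6),
               up3 = c(5, 5, 8, 8), down = c(6, 6, 5, 5))
    fc <- foldChange(m, 1:2, 3:4)
    expect_equal(fc$fc[fc$gene == "flat"], 1)
    expect_equal(fc$fc[fc$gene == "up1"], 2)     # boundary passes ">= 2"
    expect_equal(fc$fc[fc$gene == "up3"], 8)
    expect_equal(fc$fc[fc$gene == "down"], -2)
})

test_that("SAM d follows the pooled standard error formula", {
    m <- rbind(g = c(1, 2, 3, 4), same = c(2, 3, 2, 3))
    d <- samStatistic(m, 1:2, 3:4, s0 = 0)
    expect_equal(unname(d["g"]), 2 / sqrt(0.5))
    expect_equal(unname(d["same"]), 0)
    # s0 -> infinity shrinks d to zero monotonically
    ds <- vapply(c(0, 0.5, 2, 10, 100), function(s0)
        abs(unname(samStatistic(m, 1:2, 3:4, s0 = s0)["g"])), numeric(1))
    expect_true(all(diff(ds) < 0))
    zv <- rbind(z = c(1, 1, 2, 2))
    expect_warning(dz <- samStatistic(zv, 1:2, 3:4, s0 = 0), "infinite")
    expect_true(is.infinite(dz[1]))
})

test_that("permutation q matches a brute-force 6-relabeling oracle on a toy set", {
    set.seed(5)
    m <- matrix(rnorm(80, 8, 0.3), 20, 4,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
    m[1:3, 3:4] <- m[1:3, 3:4] + 2.5
    got <- permutationFdr(m, 1:2, 3:4)

    # oracle: materialize all 6 balanced relabelings explicitly
    samD <- function(mat, a, b, s0) {
        A <- mat[, a, drop = FALSE]; B <- mat[, b, drop = FALSE]
        s <- sqrt(((1/2 + 1/2) / 2) *
                  (rowSums((A - rowMeans(A))^2) +
                   rowSums((B - rowMeans(B))^2)))
        (rowMeans(B) - rowMeans(A)) / (s + s0)
    }
    s <- sqrt(0.5 * (apply(m[, 1:2], 1, stats::var) +
                     apply(m[, 3:4], 1, stats::var)))
    s0 <- stats::median(s)
    dObs <- abs(samD(m, 1:2, 3:4, s0))
    relab <- utils::combn(4, 2, simplify = FALSE)
    qOracle <- rep(NA_real_, 20)
    thr <- sort(dObs, decreasing = TRUE)
    fdr <- vapply(seq_along(thr), function(i) {
        t <- thr[i]
        V <- stats::median(vapply(relab, function(a) {
            dStar <- abs(samD(m, a, setdiff(1:4, a), s0))
            sum(dStar[is.finite(dStar)] >= t)
        }, numeric(1)))
        min(V / i, 1)
    }, numeric(1))
    qSorted <- rev(cummin(rev(fdr)))
    qOracle[order(dObs, decreasing = TRUE)] <- qSorted
    expect_equal(got$q, qOracle, tolerance = 1e-12)
})

test_that("q values are deterministic and invariant to gene order", {
    set.seed(9)
    m <- matrix(rnorm(60, 8, 0.4), 15, 4,
                dimnames = list(sprintf("g%02d", 1:15), paste0("s", 1:4)))
    q1 <- permutationFdr(m, 1:2, 3:4)
    q2 <- permutationFdr(m, 1:2, 3:4)
    expect_identical(q1, q2)                     # full enumeration
    perm <- sample(15)
    q3 <- permutationFdr(m[perm, ], 1:2, 3:4)
    expect_equal(q3$q[match(q1$gene, q3$gene)], q1$q)
    # duplicated rows get identical q
    md <- rbind(m, m[1, , drop = FALSE])
    rownames(md)[16] <- "dup"
    q4 <- permutationFdr(md, 1:2, 3:4)
    expect_equal(q4$q[q4$gene == "dup"], q4$q[q4$gene == rownames(m)[1]])
})

test_that("BH adjustment equals the brute-force step-up definition", {
    p <- c(0.003, 0.04, 0.19, 0.002, 0.5, 0.048)
    perms <- NULL
    # all 720 orderings of the same six p-values
    idx <- 1:6
    allPerms <- as.matrix(expand.grid(rep(list(idx), 6)))
    allPerms <- allPerms[apply(allPerms, 1, function(r)
        length(unique(r)) == 6), ]
    for (i in seq_len(nrow(allPerms))) {
        pp <- p[allPerms[i, ]]
        expect_equal(bhAdjust(pp), bruteBH(pp), tolerance = 1e-12)
    }
})

test_that("selection gate applies both the q and inclusive fold-change rules", {
    res <- data.frame(gene = c("a", "b", "c", "d"),
                      fc = c(1.9, 2.0, -8, 2.5),
                      q = c(0.001, 0.04, 0.20, 0.01))
    sel <- selectDeg(res)
    expect_false("a" %in% sel$up)                # fails FC gate
    expect_true("b" %in% sel$up)                 # boundary FC included
    expect_false("c" %in% sel$down)              # fails q gate
    expect_equal(unname(sel$counts), c(2L, 0L))
})

test_that("multiclass F-like SAM separates a group-structured gene", {
    set.seed(2)
    m <- matrix(rnorm(300, 8, 0.2), 50, 6)
    rownames(m) <- sprintf("g%02d", 1:50)
    groups <- rep(c("a", "b", "c"), each = 2)
    m[1, groups == "c"] <- m[1, groups == "c"] + 3
    d <- samMulticlass(m, groups)
    expect_gt(unname(d[1]), unname(max(d[-1])))
    expect_error(samMulticlass(m[, 1:2], groups[1:2]), "two groups")
})

test_that("per-stage differential run recovers planted effects cleanly", {
    d <- smallDesign(nGenes = 300L)
    tr <- simulateTruth(d, nPatterns = 0L, dePerContrast = 10L,
                        deEffect = 3, seed = 13)
    x <- simulateExpression(d, tr, noiseSd = 0.25, seed = 14)
    res <- runDifferential(x, seed = 13)
    for (st in names(res)) {
        sel <- selectDeg(res[[st]])
        planted <- tr@deGenes[[st]]
        expect_setequal(sel$up, names(planted)[planted > 0])
        expect_setequal(sel$down, names(planted)[planted < 0])
    }
})
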