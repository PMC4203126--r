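test_that("quantile normalization maps columns to shared rank means", {
    out <- quantileNormalize(cbind(s1 = c(5, 2, 3), s2 = c(4, 1, 9)))
    expect_equal(unname(out[, "s1"]), c(7, 1.5, 3.5))
    expect_equal(unname(out[, "s2"]), c(3.5, 1.5, 7))
    # identical columns and single columns are fixed points
    m <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
    expect_equal(quantileNormalize(m), m)
    one <- cbind(a = c(9, 4, 6))
    expect_equal(quantileNormalize(one), one)
    expect_error(quantileNormalize(cbind(c(1, NA))), "missing")
})

test_that("quantile normalization is idempotent with equal column multisets", {
    set.seed(42)
    m <- matrix(rlnorm(200), 40, 5)
    q1 <- quantileNormalize(m)
    expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)
    sorted <- apply(q1, 2L, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
    # row order preserved: ranks unchanged within each column
    expect_equal(apply(m, 2, rank), apply(q1, 2, rank))
})

test_that("median polish recovers additive structure exactly", {
    const <- matrix(7, 4, 3)
    fit <- medianPolish(const)
    expect_equal(fit$overall + fit$col, rep(7, 3))
    expect_equal(max(abs(fit$residuals)), 0)
    add <- outer(c(0.5, -1, 2, 0), c(4, 6, 5), "+")
    fit2 <- medianPolish(add)
    expect_lt(max(abs(fit2$residuals)), 1e-12)
    expect_equal(diff(fit2$overall + fit2$col), c(2, -1))
})

test_that("median polish matches the stats::medpolish oracle on an outlier matrix", {
    m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 50), 3, 3)
    ours <- medianPolish(m, tol = 1e-10)
    oracle <- stats::medpolish(m, eps = 1e-10, maxiter = 200, trace.iter = FALSE)
    expect_lt(max(abs((ours$overall + ours$col) -
                      (oracle$overall + oracle$col))), 1e-8)
    expect_lt(max(abs(ours$residuals - oracle$residuals)), 1e-8)
})

test_that("median polish absolute-residual objective is non-increasing in sweeps", {
    set.seed(7)
    m <- matrix(rnorm(30), 6, 5) + outer(rnorm(6), rnorm(5), "+")
    objs <- vapply(1:6, function(k)
        sum(abs(medianPolish(m, tol = 0, maxIter = k)$residuals)),
        numeric(1))
    expect_true(all(diff(objs) <= 1e-12))
})

test_that("replicate correlation reports hand-computable values and flags", {
    v <- cbind(a1 = c(1, 2, 3), a2 = c(1, 3, 2), b1 = c(1, 2, 3),
               b2 = c(3, 2, 1))
    x <- handExpression(v)
    qc <- replicateCorrelation(x)
    expect_equal(qc$r[qc$stage == "s1"], 0.5)   # hand: cov/sd arithmetic
    expect_equal(qc$r[qc$stage == "s2"], -1)
    v2 <- cbind(a1 = c(1, 2, 3), a2 = c(2, 2, 2), b1 = c(1, 2, 3),
                b2 = c(1, 2, 3))
    qc2 <- replicateCorrelation(handExpression(v2))
    expect_equal(qc2$flag[qc2$stage == "s1"], "undefined")
    expect_true(is.na(qc2$r[qc2$stage == "s1"]))
    expect_equal(qc2$r[qc2$stage == "s2"], 1)
})

test_that("bootstrap supports are 100% for well-separated duplicated groups", {
    set.seed(3)
    base1 <- rnorm(60); base2 <- rnorm(60)
    v <- cbind(a1 = base1, a2 = base1, b1 = base2, b2 = base2)
    x <- handExpression(v + matrix(rnorm(240, sd = 1e-3), 60, 4))
    dend <- bootstrapHclust(x, nBoot = 30L, seed = 5)
    expect_true(all(supportValues(dend) == 100))
})

test_that("three samples yield a single non-root split and n_boot=0 is rejected", {
    set.seed(4)
    v <- matrix(rnorm(30), 10, 3,
                dimnames = list(NULL, c("a1", "a2", "b1")))
    sheet <- data.frame(sample_id = colnames(v), genotype = "WT",
                        stage = c("s1", "s1", "s2"), replicate = c(1, 2, 1))
    x <- newExpressionMatrix(v, sheet)
    dend <- bootstrapHclust(x, nBoot = 5L, seed = 1)
    merges <- nrow(dend@hclust$merge)
    expect_equal(merges - 1L, 1L)         # root is trivial, one real split
    expect_error(bootstrapHclust(x, nBoot = 0L), "nBoot")
})

test_that("bootstrap supports equal an ape bipartition oracle sharing resample indices", {
    set.seed(9)
    v <- matrix(rnorm(80), 20, 4) +
        cbind(rep(2, 20), rep(2, 20), rep(-2, 20), rep(-2, 20)) *
        matrix(rnorm(20), 20, 4)
    colnames(v) <- c("a1", "a2", "b1", "b2")
    x <- handExpression(v)
    nb <- 25L
    dend <- bootstrapHclust(x, nBoot = nb, seed = 77)
    # oracle: same RNG stream, trees rebuilt and clades counted via ape
    treeOf <- function(mat) stats::hclust(
        stats::as.dist(1 - stats::cor(mat)), "average")
    set.seed(77)
    phys <- vector("list", nb)
    for (b in seq_len(nb)) {
        rows <- sample(nrow(v), nrow(v), replace = TRUE)
        phys[[b]] <- ape::as.phylo(treeOf(v[rows, ]))
    }
    orig <- ape::as.phylo(treeOf(v))
    pp <- ape::prop.part(phys)
    ppSets <- lapply(pp, function(ix) sort(attr(pp, "labels")[ix]))
    ppCount <- attr(pp, "number")
    origPP <- ape::prop.part(list(orig))
    origSets <- lapply(origPP, function(ix) sort(orig$tip.label[ix]))
    oracleSupport <- vapply(origSets, function(cs) {
        j <- which(vapply(ppSets, identical, logical(1), cs))
        if (length(j)) 100 * ppCount[j] / nb else 0
    }, numeric(1))
    implSets <- DominantPatterns:::clusterLeafSets(dend@hclust)
    matched <- 0L
    for (i in seq_along(origSets)) {
        j <- which(vapply(implSets, identical, logical(1), origSets[[i]]))
        if (length(j)) {
            expect_equal(supportValues(dend)[j], oracleSupport[i])
            matched <- matched + 1L
        }
    }
    expect_gte(matched, 2L)
})

test_that("newick export carries support labels and sample topology is gene-order invariant", {
    set.seed(11)
    v <- matrix(rnorm(120), 30, 4,
                dimnames = list(sprintf("g%02d", 1:30),
                                c("a1", "a2", "b1", "b2")))
    x <- handExpression(v)
    dend <- bootstrapHclust(x, nBoot = 10L, seed = 3)
    f <- tempfile(fileext = ".nwk")
    writeNewick(dend, f)
    phy <- ape::read.tree(f)
    expect_setequal(phy$tip.label, colnames(v))
    expect_true(any(nzchar(phy$node.label)))
    # permuting genes leaves the sample dendrogram topology unchanged
    xp <- handExpression(v[sample(30), ])
    expect_equal(bootstrapHclust(xp, nBoot = 1L, seed = 1)@hclust$merge,
                 dend@hclust$merge)
})
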