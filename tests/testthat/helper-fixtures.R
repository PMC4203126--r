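# Shared fixture builders; everything is generated in code, nothing on disk.

smallDesign <- function(nGenes = 120L, genotypes = c("WT", "vtc2"))
    studyDesign(genotypes = genotypes, nGenes = nGenes, nProbes = 11L)

# expression matrix with explicit values for hand-checkable cases
handExpression <- function(values) {
    n <- ncol(values)
    sheet <- data.frame(
        sample_id = colnames(values),
        genotype = rep(c("WT", "vtc2"), each = n / 2)[seq_len(n)],
        stage = rep(rep(c("s1", "s2"), each = 2), 2)[seq_len(n)],
        replicate = rep(1:2, n / 2)[seq_len(n)])
    newExpressionMatrix(values, sheet)
}

# independent naive IUPAC scanner: expand the code at every offset
naiveMotifCount <- function(seqs, motif) {
    iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
              H = "D", V = "B", N = "N")
    matchAt <- function(seqChars, pos, motChars) {
        for (j in seq_along(motChars)) {
            allowed <- iupac[[motChars[j]]]
            if (!seqChars[pos + j - 1L] %in% allowed) return(FALSE)
        }
        TRUE
    }
    rcMotif <- rev(unname(comp[strsplit(motif, "")[[1]]]))
    vapply(seqs, function(s) {
        sc <- strsplit(s, "")[[1]]
        m1 <- strsplit(motif, "")[[1]]
        L <- length(sc); W <- length(m1)
        if (L < W) return(0L)
        hits <- 0L
        for (pos in seq_len(L - W + 1L)) {
            if (matchAt(sc, pos, m1)) hits <- hits + 1L
            if (matchAt(sc, pos, rcMotif)) hits <- hits + 1L
        }
        hits
    }, integer(1))
}

# independent exhaustive hypergeometric upper tail by draw enumeration
enumHyper <- function(k, K, n, N) {
    total <- choose(N, n)
    sum(vapply(k:min(n, K), function(j)
        choose(K, j) * choose(N - K, n - j), numeric(1))) / total
}

# independent brute-force BH step-up per its definition
bruteBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) adj[i] <- min(1, min(m / seq(i, m) * p[ord][i:m]))
    out <- numeric(m)
    out[ord] <- adj
    out
}

# four-measurement Ct table for ddCt identity checks
mkCt <- function(tTarget, tRef, cTarget, cRef) {
    data.frame(sample = c("t1", "t1", "c1", "c1"),
               condition = c("mut", "mut", "wt", "wt"),
               gene = c("tgt", "ref", "tgt", "ref"),
               Ct = c(tTarget, tRef, cTarget, cRef),
               stringsAsFactors = FALSE)
}

# independent exact signed-rank p by 2^n sign enumeration (ties included)
enumSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    rk <- rank(abs(d))
    wObs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- signs %*% rk
    mean(w >= wObs - 1e-9)
}
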