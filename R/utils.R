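#' @include AllClasses.R
NULL

# Ordered (genotype, stage) cell labels, genotype-major, stage order fixed.
cellLabels <- function(design) {
    as.vector(vapply(design@genotypes, function(g)
        paste(g, design@stages, sep = "."), character(length(design@stages))))
}

cellOf <- function(genotype, stage) paste(genotype, stage, sep = ".")

# z-score each row; rows with zero variance come back as all-zero and are
# reported in the "flat" attribute.
standardizeRows <- function(x) {
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    flat <- sd == 0 | !is.finite(sd)
    sd[flat] <- 1
    z <- (x - mu) / sd
    z[flat, ] <- 0
    attr(z, "flat") <- flat
    z
}

# Pearson correlation with (n-1) denominators (stats::cor convention),
# returning NA for zero-variance input rather than propagating NaN noise.
pearson <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
}

# Derive a per-stage 32-bit seed from the master seed, deterministically.
deriveSeed <- function(seed, offset) {
    (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
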