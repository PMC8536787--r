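# internal helpers shared across modules

# minimum that tolerates dgCMatrix and empty input
min0 <- function(x) {
    if (length(x) == 0) return(0)
    if (inherits(x, "sparseMatrix")) min(0, min(x@x, 0)) else min(x)
}

allIntegral <- function(x, tol = 1e-8) {
    v <- if (inherits(x, "sparseMatrix")) x@x else as.vector(x)
    if (length(v) == 0) return(TRUE)
    all(abs(v - round(v)) <= tol)
}

asDense <- function(x) {
    if (inherits(x, "Matrix")) as.matrix(x) else x
}

# library-size normalization to counts-per-10k followed by log1p; used only
# for the marker rank test, never for NB fitting
logNormalize <- function(counts, scale = 1e4) {
    counts <- asDense(counts)
    libs <- colSums(counts)
    libs[libs == 0] <- 1
    log1p(sweep(counts, 2, libs, "/") * scale)
}

# tie-corrected one-vs-rest Wilcoxon rank-sum with normal approximation and
# continuity correction, vectorized over the rows of `mat`; matches
# stats::wilcox.test(exact = FALSE, correct = TRUE) two-sided p-values
rankSumOneVsRest <- function(mat, inGroup) {
    n1 <- sum(inGroup)
    n2 <- sum(!inGroup)
    N <- n1 + n2
    ranks <- t(apply(mat, 1L, rank))
    W <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
    tieTerm <- apply(mat, 1L, function(x) {
        tt <- tabulate(match(x, unique(x)))
        sum(tt^3 - tt)
    })
    sigma <- sqrt((n1 * n2 / 12) * ((N + 1) - tieTerm / (N * (N - 1))))
    z <- W - n1 * n2 / 2
    corr <- sign(z) * 0.5
    z <- (z - corr) / sigma
    p <- 2 * pnorm(-abs(z))
    p[sigma == 0] <- 1
    pmin(1, p)
}

isMito <- function(geneIds, prefixes = c("mt-", "MT-", "Mt-")) {
    hit <- rep(FALSE, length(geneIds))
    for (p in prefixes) hit <- hit | startsWith(geneIds, p)
    hit
}

# derive a stream of sub-seeds (< 2^31) from a master seed
deriveSeeds <- function(seed, n) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    force(expr)
}

checkCountVector <- function(x) {
    if (!is.numeric(x) || length(x) < 1)
        stop("count vector must be numeric with length >= 1")
    if (any(!is.finite(x)) || any(x < 0))
        stop("counts must be finite and non-negative")
    if (any(abs(x - round(x)) > 1e-8))
        stop("counts must be integral")
    invisible(round(x))
}
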