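# shared fixtures built in code; all randomness under fixed seeds

# tiny annotated reference with a hand-planted structure:
#  - geneA: strongly enriched in type A
#  - mt-Nd1: enriched in type B (should always be filtered as mitochondrial)
#  - remaining genes: flat Poisson noise
makeTinyRef <- function(nFlat = 20, cellsPerType = 30, seed = 11) {
    withr::with_seed(seed, {
        types <- c("A", "B", "C")
        N <- cellsPerType * length(types)
        labels <- rep(types, each = cellsPerType)
        genes <- c("geneA", "mt-Nd1", sprintf("flat%02d", seq_len(nFlat)))
        cnt <- matrix(rpois(length(genes) * N, 2), length(genes), N,
                      dimnames = list(genes, sprintf("c%03d", seq_len(N))))
        cnt["geneA", labels == "A"] <- rpois(cellsPerType, 20)
        cnt["mt-Nd1", labels == "B"] <- rpois(cellsPerType, 40)
        ScReference(cnt, cellType = labels,
                    subject = rep(c("s1", "s2", "s3"), length.out = N))
    })
}

# minimal ReferencePanel straight from a mean matrix (nb_ok bookkeeping is
# fabricated consistently: var = 2*mu, p = 0.5, lambda = mu)
makeMatrixPanel <- function(M, wS = NULL) {
    I <- nrow(M); K <- ncol(M)
    if (is.null(rownames(M))) rownames(M) <- paste0("g", seq_len(I))
    if (is.null(colnames(M))) colnames(M) <- paste0("T", seq_len(K))
    if (is.null(wS)) wS <- rep(0.5, I)
    new("ReferencePanel", genes = rownames(M), cellTypes = colnames(M),
        mu = M, var = 2 * M, dispersion = M,
        successProb = matrix(0.5, I, K), fitFlag = matrix("nb_ok", I, K),
        specificityWeight = wS, geneMode = "custom", metadata = list())
}

# independent coarse grid search for the NB MLE (oracle; never shares code
# with fitNbProfile)
gridNbMle <- function(x, nLambda = 80, nP = 80) {
    lams <- exp(seq(log(0.05), log(100), length.out = nLambda))
    ps <- seq(0.01, 0.99, length.out = nP)
    ux <- sort(unique(x))
    wts <- tabulate(match(x, ux), nbins = length(ux))
    best <- c(ll = -Inf, lambda = NA, p = NA)
    for (l in lams) {
        lls <- vapply(ps, function(p)
            sum(wts * dnbinom(ux, size = l, prob = 1 - p, log = TRUE)),
            numeric(1))
        j <- which.max(lls)
        if (lls[j] > best["ll"]) best <- c(ll = lls[j], lambda = l, p = ps[j])
    }
    best
}

# exhaustive Mann-Whitney pair statistic (ties count one half)
pairAuc <- function(score, truth) {
    pos <- score[truth]; neg <- score[!truth]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}
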