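test_that("marker selection finds planted markers and drops mitochondria", {
    ref <- makeTinyRef()
    sel <- selectMarkerGenes(ref, topN = 5)
    expect_true("geneA" %in% sel)
    expect_false("mt-Nd1" %in% sel)
    # deterministic: repeated calls agree
    expect_identical(sel, selectMarkerGenes(ref, topN = 5))
})

test_that("the vectorized rank-sum test matches wilcox.test", {
    withr::with_seed(21, {
        mat <- matrix(rpois(300, 3), 10, 30)
        grp <- rep(c(TRUE, FALSE), c(12, 18))
        mine <- NBDecon:::rankSumOneVsRest(mat, grp)
        for (i in 1:10) {
            w <- wilcox.test(mat[i, grp], mat[i, !grp], exact = FALSE,
                             correct = TRUE)
            expect_equal(mine[i], w$p.value, tolerance = 1e-10)
        }
    })
})

test_that("genes topping too many per-type lists are excluded", {
    # gene H is high in 6 of 8 types (one-vs-rest significance comes from
    # the two large H-negative types), gene S in exactly 1
    withr::with_seed(31, {
        types <- paste0("T", 1:8)
        labels <- rep(types, c(rep(25, 6), 75, 75))
        N <- length(labels)
        genes <- c("geneH", "geneS", sprintf("flat%02d", 1:15))
        cnt <- matrix(rpois(length(genes) * N, 2), length(genes), N,
                      dimnames = list(genes, paste0("c", seq_len(N))))
        cnt["geneH", labels %in% types[1:6]] <- rpois(25 * 6, 30)
        cnt["geneH", !labels %in% types[1:6]] <- 0
        cnt["geneS", labels == "T7"] <- rpois(75, 25)
        ref <- ScReference(cnt, cellType = labels)
        sel5 <- selectMarkerGenes(ref, topN = 3, maxTypes = 5)
        expect_false("geneH" %in% sel5)
        expect_true("geneS" %in% sel5)
        sel8 <- selectMarkerGenes(ref, topN = 3, maxTypes = 8)
        expect_true("geneH" %in% sel8)
    })
})

test_that("marker selection requires two cell types and informative genes", {
    cnt <- matrix(rpois(50, 2), 5, 10,
                  dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
    one <- ScReference(cnt, cellType = rep("A", 10))
    expect_error(selectMarkerGenes(one), "at least 2 cell types")
    flat <- ScReference(cnt, cellType = rep(c("A", "B"), each = 5))
    expect_error(selectMarkerGenes(flat, pCutoff = 1e-12),
                 "no informative genes")
})

test_that("balanced HVG selection ranks a planted high-variance gene first", {
    withr::with_seed(41, {
        labels <- rep(c("A", "B", "C"), c(10, 30, 50))
        N <- length(labels)
        genes <- c("wild", sprintf("dull%03d", 1:200))
        # Poisson genes spread over a mean range anchor the mean-variance
        # trend; "wild" is grossly overdispersed at a mid-range mean
        mus <- exp(seq(log(0.5), log(50), length.out = 200))
        cnt <- rbind(
            wild = rnbinom(N, size = 0.5, mu = 20),
            t(vapply(mus, function(m) rpois(N, m), numeric(N))))
        dimnames(cnt) <- list(genes, paste0("c", seq_len(N)))
        ref <- ScReference(cnt, cellType = labels)
        expect_identical(selectBalancedHVGs(ref, nTop = 1, seed = 5), "wild")
        # same seed -> identical list; capping warns
        expect_identical(selectBalancedHVGs(ref, nTop = 10, seed = 9),
                         selectBalancedHVGs(ref, nTop = 10, seed = 9))
        expect_warning(selectBalancedHVGs(ref, nTop = 1000, seed = 9),
                       "capped")
    })
})

test_that("specificity weights are the best type's mean-to-variance ratio", {
    M <- matrix(c(4, 1,
                  2, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("A", "B")))
    V <- matrix(c(8, 2,
                  4, 5), 2, 2, byrow = TRUE, dimnames = dimnames(M))
    fl <- matrix(c("nb_ok", "nb_ok",
                   "nb_ok", "poisson_fallback"), 2, 2, byrow = TRUE,
                 dimnames = dimnames(M))
    panel <- makeMatrixPanel(M)
    panel@var <- V; panel@fitFlag <- fl
    panel@successProb <- 1 - M / V
    w <- computeSpecificityWeights(panel)
    expect_equal(unname(w["g1"]), 0.5)   # best type A: 4/8
    expect_equal(unname(w["g2"]), 1)     # best type B is a Poisson fallback
})

test_that("specificity equals 1 - p for nb_ok fits (analytic identity)", {
    sim <- generateSyntheticReference(nGenes = 60, nTypes = 3,
                                      cellsPerType = 60, seed = 7)
    panel <- buildReference(sim$ref, genes = rownames(counts(sim$ref)),
                            minCellsPerType = 10)
    w <- specificityWeights(panel)
    best <- apply(nbMeans(panel), 1, which.max)
    for (i in seq_along(w)) {
        k <- best[i]
        if (fitFlags(panel)[i, k] == "nb_ok")
            expect_lt(abs(w[i] - (1 - nbSuccessProbs(panel)[i, k])), 1e-6)
    }
})

test_that("buildReference is deterministic and cell-order invariant", {
    sim <- generateSyntheticReference(nGenes = 80, nTypes = 3,
                                      cellsPerType = 40, seed = 13)
    ref <- sim$ref
    p1 <- buildReference(ref, geneMode = "marker", topN = 10)
    p2 <- buildReference(ref, geneMode = "marker", topN = 10)
    expect_identical(nbMeans(p1), nbMeans(p2))
    # permute cells: fits on raw counts per type must be unchanged
    perm <- withr::with_seed(3, sample(ncol(ref)))
    refPerm <- ScReference(counts(ref)[, perm],
                           cellType = cellTypes(ref)[perm])
    p3 <- buildReference(refPerm, genes = selectedGenes(p1))
    expect_equal(nbMeans(p3), nbMeans(p1), tolerance = 1e-12)
})

test_that("buildReference recovers generator means within 5%", {
    sim <- generateSyntheticReference(nGenes = 50, nTypes = 2,
                                      cellsPerType = 500, markerFrac = 0.2,
                                      markerFold = 4, typeScaleRange = c(1, 2),
                                      dispersionRange = c(10, 30),
                                      baseMeanLog = log(30), baseMeanSd = 0.2,
                                      cellSd = 0.05, seed = 17)
    panel <- buildReference(sim$ref, genes = rownames(counts(sim$ref)))
    muTrue <- sim$truth$muTrue[selectedGenes(panel), cellTypeNames(panel)]
    relErr <- abs(nbMeans(panel) - muTrue) / muTrue
    expect_lt(max(relErr), 0.05)
})

test_that("buildReference enforces the per-type cell minimum", {
    cnt <- matrix(rpois(60, 3), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
    ref <- ScReference(cnt, cellType = rep(c("A", "B"), c(8, 2)))
    expect_error(buildReference(ref, genes = paste0("g", 1:6)),
                 "below 10 cells")
})

test_that("a single-type panel deconvolutes to theta = 1", {
    sim <- generateSyntheticReference(nGenes = 40, nTypes = 1,
                                      cellsPerType = 50, seed = 19)
    panel <- buildReference(sim$ref, genes = rownames(counts(sim$ref)))
    expect_identical(length(cellTypeNames(panel)), 1L)
    y <- rowSums(as.matrix(counts(sim$ref))[selectedGenes(panel), 1:5])
    res <- solveProportions(unname(y), panel)
    expect_equal(unname(proportions(res)[1, 1]), 1)
})
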