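test_that("coarse estimate solves exact representations", {
    M <- matrix(c(5, 0, 2,
                  0, 4, 1), 3, 2,
                dimnames = list(paste0("g", 1:3), c("A", "B")))
    tau <- coarseEstimate(M[, 2] * 3, M)
    expect_equal(as.numeric(tau), c(0, 1))
    expect_error(coarseEstimate(rep(0, 3), M), "degenerate")
})

test_that("coarse estimate matches an exhaustive simplex grid search", {
    M <- matrix(c(1, 0,
                  0, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("A", "B")))
    y <- c(3, 7)
    tau <- coarseEstimate(y, M)
    # oracle: grid over the 2-simplex at step 0.001, prediction scaled
    # optimally for each candidate
    grid <- seq(0, 1, by = 0.001)
    sse <- vapply(grid, function(a) {
        m <- M %*% c(a, 1 - a)
        s <- sum(y * m) / sum(m^2)
        sum((y - s * m)^2)
    }, numeric(1))
    best <- grid[which.min(sse)]
    expect_equal(as.numeric(tau), c(best, 1 - best), tolerance = 1e-6)
    expect_equal(as.numeric(tau), c(0.3, 0.7), tolerance = 1e-9)
})

test_that("robust coarse refinement keeps exact fits and resists outliers", {
    withr::with_seed(55, {
        M <- matrix(runif(200, 0, 10), 100, 2,
                    dimnames = list(sprintf("g%03d", 1:100), c("A", "B")))
        y <- as.numeric(M %*% c(3, 7))
        # exact data: robust refinement must agree with plain NNLS
        expect_equal(as.numeric(coarseEstimate(y, M, robust = TRUE)),
                     as.numeric(coarseEstimate(y, M)), tolerance = 1e-9)
        # corrupt a few genes grossly: robust gets closer to the truth
        yc <- y; yc[1:5] <- yc[1:5] * 20
        truth <- c(0.3, 0.7)
        errPlain <- max(abs(coarseEstimate(yc, M) - truth))
        errRobust <- max(abs(coarseEstimate(yc, M, robust = TRUE) - truth))
        expect_lt(errRobust, errPlain)
    })
})

test_that("correction factors hit the Eq. fixed points", {
    M <- matrix(c(10, 7, 3), 3, 1,
                dimnames = list(paste0("g", 1:3), "A"))
    tau <- c(A = 1)
    # observed = predicted -> r = 1; observed 0 -> r = 0; 30 vs 10 -> r = 2
    r <- computeCorrectionFactors(c(10, 0, 30), M,
                                  tau, scale = 1)
    expect_equal(unname(r[1]), 1)
    expect_equal(unname(r[2]), 0)
    r3 <- computeCorrectionFactors(c(30, 7, 3), M, tau, scale = 1)
    expect_equal(unname(r3[1]), 2)
    # zero predicted denominator -> NA (excluded)
    M0 <- rbind(M, g4 = 0)
    r0 <- computeCorrectionFactors(c(10, 7, 3, 5), M0, tau, scale = 1)
    expect_true(is.na(r0["g4"]))
})

test_that("loss and gradient match hand arithmetic", {
    M <- matrix(c(2, 3), 2, 1)
    lg <- lossAndGradient(1, c(4, 6), M, wC = 1, wS = 1, r = 1, lambda = 0)
    expect_equal(lg$loss, 13)
    expect_equal(lg$gradient, -26)
    # beta = 0 plug-in
    lg0 <- lossAndGradient(0, c(4, 6), M, wC = 1, wS = 1, r = 1, lambda = 5)
    expect_equal(lg0$loss, 16 + 36)
    expect_equal(lg0$gradient, -2 * (2 * 4 + 3 * 6))
})

test_that("analytic gradient matches central finite differences", {
    withr::with_seed(66, {
        for (t in 1:25) {
            I <- sample(5:40, 1); K <- sample(1:5, 1)
            M <- matrix(runif(I * K, 0, 5), I, K)
            y <- runif(I, 0, 20)
            wC <- runif(I); wS <- runif(I)
            r <- runif(I, 0, 2); r[sample(I, 1)] <- NA
            lambda <- runif(1, 0, 2)
            beta <- runif(K, 0, 3)
            g <- lossAndGradient(beta, y, M, wC, wS, r, lambda)$gradient
            h <- 1e-5
            fd <- vapply(seq_len(K), function(k) {
                e <- rep(0, K); e[k] <- h
                (lossAndGradient(beta + e, y, M, wC, wS, r, lambda)$loss -
                 lossAndGradient(beta - e, y, M, wC, wS, r, lambda)$loss) /
                    (2 * h)
            }, numeric(1))
            expect_lt(max(abs(g - fd)) / max(1, max(abs(g))), 1e-5)
        }
    })
})

test_that("noiseless mixtures are recovered exactly", {
    withr::with_seed(77, {
        M <- matrix(runif(120, 0, 10), 60, 2,
                    dimnames = list(sprintf("g%02d", 1:60), c("A", "B")))
        panel <- makeMatrixPanel(M)
        y <- as.numeric(M %*% c(2, 8))
        res <- solveProportions(y, panel, wC = rep(1, 60), lambda = 0,
                                platformCorrection = FALSE)
        expect_equal(unname(proportions(res)[1, ]), c(0.2, 0.8),
                     tolerance = 1e-3)
        # closed-form weighted LS oracle on the two-column design
        oracle <- solve(crossprod(M), crossprod(M, y))
        expect_equal(unname(proportions(res)[1, ]),
                     as.numeric(oracle / sum(oracle)), tolerance = 1e-6)
    })
})

test_that("with unit weights, r = 1 and lambda = 0 the solver is NNLS", {
    withr::with_seed(88, {
        for (t in 1:20) {
            I <- sample(10:50, 1); K <- sample(2:5, 1)
            M <- matrix(runif(I * K, 0, 10), I, K,
                        dimnames = list(paste0("g", seq_len(I)),
                                        paste0("T", seq_len(K))))
            panel <- makeMatrixPanel(M)
            y <- as.numeric(M %*% runif(K, 0, 3)) * exp(rnorm(I, 0, 0.3))
            th <- proportions(solveProportions(y, panel, wC = rep(1, I),
                wS = rep(1, I), lambda = 0, platformCorrection = FALSE))[1, ]
            cf <- pracma::lsqnonneg(M, y)$x
            expect_lt(max(abs(th - cf / sum(cf))), 1e-6)
        }
    })
})

test_that("theta is scale-equivariant at lambda = 0", {
    withr::with_seed(99, {
        M <- matrix(runif(90, 0, 8), 30, 3)
        panel <- makeMatrixPanel(M)
        y <- as.numeric(M %*% c(1, 2, 3)) * exp(rnorm(30, 0, 0.2))
        th1 <- proportions(solveProportions(y, panel, wC = rep(1, 30),
            lambda = 0, platformCorrection = FALSE))[1, ]
        th2 <- proportions(solveProportions(y * 511.7, panel,
            wC = rep(1, 30), lambda = 0, platformCorrection = FALSE))[1, ]
        expect_equal(th1, th2, tolerance = 1e-8)
    })
})

test_that("regularization shrinks the coefficient norm monotonically", {
    withr::with_seed(111, {
        M <- matrix(runif(80, 0, 5), 20, 4)
        panel <- makeMatrixPanel(M)
        y <- as.numeric(M %*% c(4, 1, 2, 3)) * exp(rnorm(20, 0, 0.2))
        lams <- c(0, 10^seq(-2, 6, length.out = 9)) * sum(y^2) / 100
        norms <- vapply(lams, function(l) {
            b <- rawCoefficients(solveProportions(y, panel, wC = rep(1, 20),
                lambda = l, platformCorrection = FALSE))[1, ]
            sum(b^2)
        }, numeric(1))
        expect_true(all(diff(norms) <= 1e-8 * norms[1]))
    })
})

test_that("every theta closes to the simplex", {
    withr::with_seed(123, {
        for (t in 1:10) {
            I <- 25; K <- 4
            M <- matrix(runif(I * K, 0, 6), I, K)
            panel <- makeMatrixPanel(M)
            y <- pmax(as.numeric(M %*% runif(K)) + rnorm(I, 0, 2), 0)
            th <- proportions(solveProportions(y, panel))[1, ]
            expect_true(all(th >= 0))
            expect_lt(abs(sum(th) - 1), 1e-9)
        }
    })
})

test_that("deconvolute treats samples independently and respects order", {
    sim <- generateSyntheticReference(nGenes = 120, nTypes = 3,
                                      cellsPerType = 60, seed = 31)
    panel <- buildReference(sim$ref, geneMode = "marker", topN = 20)
    th <- c(type1 = 0.2, type2 = 0.3, type3 = 0.5)
    s1 <- simulateSpot(sim$ref, th, nCellsPerType = 20, seed = 1)$counts
    s2 <- simulateSpot(sim$ref, th, nCellsPerType = 20, seed = 2)$counts
    ys <- cbind(a = s1, b = s1, c = s2)
    res <- deconvolute(CompoundSamples(ys), panel)
    expect_equal(proportions(res)["a", ], proportions(res)["b", ])
    resPerm <- deconvolute(CompoundSamples(ys[, c("c", "a", "b")]), panel)
    expect_equal(proportions(resPerm)["a", ], proportions(res)["a", ])
    expect_equal(proportions(resPerm)["c", ], proportions(res)["c", ])
})

test_that("replicate groups share coarse estimates and corrections", {
    sim <- generateSyntheticReference(nGenes = 120, nTypes = 3,
                                      cellsPerType = 60, seed = 37)
    panel <- buildReference(sim$ref, geneMode = "marker", topN = 20)
    th <- c(type1 = 0.5, type2 = 0.25, type3 = 0.25)
    ys <- sapply(1:4, function(i)
        simulateSpot(sim$ref, th, nCellsPerType = 20, seed = i)$counts)
    colnames(ys) <- paste0("s", 1:4)
    res <- deconvolute(CompoundSamples(ys, groups = rep("g1", 4)), panel)
    expect_identical(colnames(correctionFactors(res)), "g1")
    expect_equal(coarseProportions(res)[1, ], coarseProportions(res)[4, ])
})

test_that("insufficient gene overlap is a hard error", {
    M <- matrix(runif(40, 1, 5), 20, 2,
                dimnames = list(paste0("g", 1:20), c("A", "B")))
    panel <- makeMatrixPanel(M)
    y <- matrix(5, 5, 1, dimnames = list(paste0("g", 1:5), "s1"))
    expect_error(deconvolute(CompoundSamples(y), panel), "50%")
})
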