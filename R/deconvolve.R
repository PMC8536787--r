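#' Coarse proportion estimate by non-negative least squares
#'
#' Regresses the compound sample's per-gene mean expression on the panel's
#' cell-type mean profiles under non-negativity, then normalizes the
#' coefficients to the simplex (the overall scale constant of the
#' regression is absorbed by this normalization). Used to seed the
#' gene-wise platform-bias correction and the full weighted fit.
#'
#' @param muCompound length-I vector of per-gene means of the sample's
#'   replicate group (the sample itself if ungrouped), aligned to
#'   \code{selectedGenes(panel)}.
#' @param panel a [ReferencePanel-class] or a plain I x K matrix of
#'   cell-type mean profiles.
#' @param weights optional per-gene weights (the pipeline passes
#'   \eqn{w^C w^S} so the coarse fit sees the same gene importance as the
#'   final fit; errors in the coarse estimate propagate into the
#'   correction factors, so a well-weighted coarse fit matters).
#' @param robust logical; refine the NNLS solution by iteratively
#'   reweighted least squares under a multiplicative-plus-count variance
#'   model (\eqn{s^2 \cdot pred^2 + pred}) with Huber downweighting of
#'   outlying log-ratios. Platform bias perturbs genes multiplicatively, so
#'   this refinement estimates the mixture far more efficiently than plain
#'   NNLS when such bias is present; the pipeline enables it because the
#'   coarse estimate's error propagates directly into the gene-wise
#'   correction factors.
#' @param maxIter IRLS iterations when \code{robust = TRUE}.
#' @param huberK Huber tuning constant (1.345 is the conventional 95%%
#'   efficiency value).
#' @return Named K-vector tau on the simplex, with the absorbed scale
#'   constant attached as attribute \code{"scale"}.
#' @export
coarseEstimate <- function(muCompound, panel, weights = NULL,
                           robust = FALSE, maxIter = 4, huberK = 1.345) {
    M <- if (is(panel, "ReferencePanel")) panel@mu else panel
    if (length(muCompound) != nrow(M))
        stop("muCompound must align with the panel's genes")
    if (all(muCompound == 0))
        stop("degenerate input: compound mean expression is all zero")
    y <- as.numeric(muCompound)
    nnlsW <- function(wt) {
        if (is.null(wt)) pracma::lsqnonneg(M, y)$x
        else {
            sw <- sqrt(rep_len(wt, nrow(M)))
            pracma::lsqnonneg(M * sw, y * sw)$x
        }
    }
    coef <- nnlsW(weights)
    if (robust && sum(coef) > 0) {
        for (it in seq_len(maxIter)) {
            pred <- as.numeric(M %*% coef)
            pos <- pred > 0 & y > 0
            if (sum(pos) < 2 * ncol(M)) break
            lr <- log(y[pos] / pred[pos])
            # variance estimated on the better-measured half of the genes,
            # where the log-ratio is not dominated by count noise
            hi <- pred[pos] >= median(pred[pos])
            s <- max(mad(lr[hi]), 0.05)
            s2 <- max(var(lr[hi]), 1e-4)
            hub <- rep(0, length(y))
            hub[pos] <- pmin(1, huberK / pmax(abs(lr) / s, 1e-9))
            newCoef <- nnlsW(hub / (s2 * pred^2 + pmax(pred, 1e-12)))
            if (sum(newCoef) <= 0) break
            coef <- newCoef
        }
    }
    if (sum(coef) <= 0) {
        warning("NNLS returned an all-zero solution; using uniform tau")
        coef <- rep(1, ncol(M))
    }
    tau <- setNames(coef / sum(coef), colnames(M))
    # the scale constant absorbed by the normalization; carried along so
    # the correction factors can be computed on the compound scale
    attr(tau, "scale") <- sum(coef)
    tau
}

#' Gene-wise platform-bias correction factors
#'
#' The ratio of observed to predicted mean expression (prediction = mixture
#' of the panel means under the coarse proportions tau) measures how much
#' each gene deviates between the compound and single-cell platforms. The
#' correction is the log of the ratio plus one:
#' \eqn{r_i = \log_2(\mu_i / \sum_k \hat\tau_k \mu_{ik} + 1)}. A ratio of 1
#' gives r = 1 (no effective correction); an observed zero gives r = 0,
#' zeroing the gene's model prediction. Genes with a zero predicted
#' denominator cannot be corrected and are returned as NA (excluded from
#' the loss by the solver).
#'
#' The prediction must live on the compound sample's scale: when
#' \code{tau} comes from [coarseEstimate()], its \code{"scale"} attribute
#' (the scale constant the simplex normalization absorbed, i.e. the sum of
#' the raw NNLS coefficients) multiplies the mixture so that the ratio is
#' the NNLS fitted value's deviation, close to 1 for unbiased genes. A
#' plain simplex vector (no attribute, or \code{scale = 1}) uses the
#' mixture as-is.
#'
#' @param muCompound length-I vector of observed group means.
#' @param panel a [ReferencePanel-class] or I x K matrix of means.
#' @param tau coarse proportions on the simplex, optionally carrying a
#'   \code{"scale"} attribute.
#' @param scale overall scale of the prediction; defaults to
#'   \code{attr(tau, "scale")} when present, else 1.
#' @return Length-I vector r with NA for excluded genes.
#' @export
computeCorrectionFactors <- function(muCompound, panel, tau,
                                     scale = NULL) {
    M <- if (is(panel, "ReferencePanel")) panel@mu else panel
    if (is.null(scale)) scale <- attr(tau, "scale") %||% 1
    if (abs(sum(tau) - 1) > 1e-6 || any(tau < 0))
        stop("tau must lie on the simplex")
    pred <- as.numeric(M %*% as.numeric(tau)) * scale
    r <- rep(NA_real_, nrow(M))
    ok <- pred > 0
    r[ok] <- log2(muCompound[ok] / pred[ok] + 1)
    if (!is.null(rownames(M))) names(r) <- rownames(M)
    r
}

#' Weighted regularized loss and its analytic gradient
#'
#' The deconvolution objective for one compound sample:
#' \deqn{L(\beta) = \sum_i w^C_i w^S_i (y_i - r_i \sum_k \beta_k
#'   \mu_{ik})^2 + \lambda \sum_k \beta_k^2}
#' with gradient
#' \eqn{G_k = -2 \sum_i r_i \mu_{ik} w^C_i w^S_i (y_i - r_i \sum_k \beta_k
#' \mu_{ik}) + 2 \lambda \beta_k}. Genes with zero combined weight or NA
#' correction contribute nothing.
#'
#' @param beta K-vector of non-negative coefficients.
#' @param y length-I observed expression vector.
#' @param panel a [ReferencePanel-class] or I x K matrix of means.
#' @param wC,wS length-I weight vectors (recycled scalars allowed).
#' @param r length-I correction factors (NA = excluded gene).
#' @param lambda regularization strength (>= 0).
#' @return list(loss = scalar, gradient = K-vector).
#' @export
lossAndGradient <- function(beta, y, panel, wC = 1, wS = 1, r = 1,
                            lambda = 0) {
    M <- if (is(panel, "ReferencePanel")) panel@mu else panel
    I <- nrow(M); K <- ncol(M)
    if (length(beta) != K) stop("beta must have one entry per cell type")
    if (length(y) != I) stop("y must align with the panel's genes")
    wC <- rep_len(wC, I); wS <- rep_len(wS, I); r <- rep_len(r, I)
    w <- wC * wS
    w[is.na(r)] <- 0
    r[is.na(r)] <- 0
    resid <- y - r * as.numeric(M %*% beta)
    loss <- sum(w * resid^2) + lambda * sum(beta^2)
    grad <- -2 * as.numeric(crossprod(M, r * w * resid)) + 2 * lambda * beta
    list(loss = loss, gradient = grad)
}

# exact minimizer of the quadratic objective on the non-negative orthant
# for a fixed active set, iterated Lawson-Hanson style; polishes the
# L-BFGS-B solution to machine precision
activeSetPolish <- function(beta, A, b, tol = 1e-12) {
    K <- length(b)
    P <- beta > tol
    scale <- max(abs(b), 1)
    for (iter in seq_len(50 * K + 50)) {
        bt <- numeric(K)
        if (any(P)) {
            sol <- tryCatch(solve(A[P, P, drop = FALSE], b[P]),
                            error = function(e) NULL)
            if (is.null(sol)) return(list(beta = beta, ok = FALSE))
            if (any(sol < -tol * scale)) {
                drop <- which(P)[which.min(sol)]
                P[drop] <- FALSE
                next
            }
            bt[P] <- pmax(sol, 0)
        }
        g <- 2 * (as.numeric(A %*% bt) - b)
        viol <- which(!P & g < -1e-10 * scale)
        if (!length(viol)) return(list(beta = bt, ok = TRUE))
        P[viol[which.min(g[viol])]] <- TRUE
    }
    list(beta = beta, ok = FALSE)
}

#' Solve cell-type proportions for a single compound sample
#'
#' Full pipeline for one sample: coarse NNLS estimate, gene-wise
#' platform-bias correction factors, then box-constrained quasi-Newton
#' (L-BFGS-B) minimization of the weighted regularized loss starting from
#' the coarse solution scaled to the sample's signal, followed by an exact
#' active-set polish of the quadratic objective. The proportions are the
#' rescaled coefficients \eqn{\theta_k = \hat\beta_k / \sum_k \hat\beta_k}.
#'
#' @param y length-I expression vector aligned to
#'   \code{selectedGenes(panel)} (names checked when present).
#' @param panel a [ReferencePanel-class].
#' @param wC,wS optional weight vectors; defaults: wC = 1,
#'   wS = the panel's specificity weights.
#' @param lambda regularization strength; \code{"auto"} (default) sets the
#'   penalty to a fixed \eqn{10^{-3}} fraction of the data term at the
#'   scaled coarse solution (\eqn{\lambda = 10^{-3} L_0 / \sum_k
#'   \beta_{0k}^2}), which is invariant to rescaling the counts.
#' @param platformCorrection logical; \code{FALSE} forces r = 1
#'   (no gene-wise correction).
#' @param muGroup optional group mean to use for the coarse estimate and
#'   correction (defaults to \code{y} itself).
#' @param tau,r optional precomputed coarse estimate / correction factors
#'   (shared across a replicate group by [deconvolute()]).
#' @param control optimizer settings: \code{maxit} (500) and \code{factr}
#'   (1e3) for L-BFGS-B.
#' @return A [DeconvolutionResult-class] with one row.
#' @export
solveProportions <- function(y, panel, wC = NULL, wS = NULL,
                             lambda = "auto", platformCorrection = TRUE,
                             muGroup = NULL, tau = NULL, r = NULL,
                             control = list()) {
    M <- panel@mu
    I <- nrow(M); K <- ncol(M)
    if (length(y) != I) stop("y must align with the panel's genes")
    if (!is.null(names(y)) && !identical(names(y), panel@genes))
        stop("names(y) do not match the panel's gene order")
    if (is.null(wS)) wS <- panel@specificityWeight
    if (is.null(wC)) wC <- rep(1, I)
    wC <- rep_len(wC, I); wS <- rep_len(wS, I)
    if (is.null(muGroup)) muGroup <- y
    if (is.null(tau)) tau <- coarseEstimate(muGroup, panel,
                                            weights = wC * wS,
                                            robust = TRUE)
    if (is.null(r)) {
        r <- if (platformCorrection)
            computeCorrectionFactors(muGroup, panel, tau)
        else rep(1, I)
    }
    w <- wC * wS
    excl <- is.na(r) | w <= 0
    w[excl] <- 0
    rr <- ifelse(is.na(r), 0, r)
    D <- M * rr                     # design: column k is r_i * mu_ik
    # scale coarse tau to the sample's signal for initialization
    denom <- sum(w * (D %*% tau)^2)
    s <- if (denom > 0) sum(w * y * (D %*% tau)) / denom else 0
    beta0 <- pmax(s, 0) * tau
    loss0 <- lossAndGradient(beta0, y, M, wC, wS, rr, 0)$loss
    # the penalty at the coarse solution is a fixed 1e-3 fraction of the
    # data term, which makes lambda dimensionless in the data scale
    # (lambda*sum(beta^2) and the loss both scale with the squared counts)
    lambdaUsed <- if (identical(lambda, "auto")) {
        if (sum(beta0^2) > 0) 1e-3 * loss0 / sum(beta0^2) else 0
    } else as.numeric(lambda)
    maxit <- control$maxit %||% 500
    factr <- control$factr %||% 1e3
    fn <- function(b) lossAndGradient(b, y, M, wC, wS, rr, lambdaUsed)$loss
    gr <- function(b) lossAndGradient(b, y, M, wC, wS, rr,
                                      lambdaUsed)$gradient
    opt <- tryCatch(
        optim(beta0, fn, gr, method = "L-BFGS-B", lower = 0,
              control = list(maxit = maxit, factr = factr)),
        error = function(e) NULL)
    converged <- !is.null(opt) && opt$convergence == 0
    beta <- if (!is.null(opt)) opt$par else beta0
    nIter <- if (!is.null(opt)) opt$counts[["function"]] else 0
    # exact polish on the quadratic objective
    A <- crossprod(D, w * D) + diag(lambdaUsed, K)
    bvec <- as.numeric(crossprod(D, w * y))
    pol <- activeSetPolish(beta, A, bvec)
    if (pol$ok && fn(pol$beta) <= fn(beta) + 1e-12 * max(1, fn(beta))) {
        beta <- pol$beta
        converged <- TRUE
    }
    sb <- sum(beta)
    if (sb <= 0) {
        theta <- rep(1 / K, K)
        converged <- FALSE
    } else theta <- beta / sb
    sampleId <- "sample1"
    new("DeconvolutionResult",
        theta = matrix(theta, 1, K,
                       dimnames = list(sampleId, panel@cellTypes)),
        betaRaw = matrix(beta, 1, K,
                         dimnames = list(sampleId, panel@cellTypes)),
        tauCoarse = matrix(tau, 1, K,
                           dimnames = list(sampleId, panel@cellTypes)),
        correctionFactors = matrix(r, I, 1,
                                   dimnames = list(panel@genes, "group1")),
        sampleGroups = setNames("group1", sampleId),
        lossValue = fn(beta), nIter = as.numeric(nIter),
        converged = converged, lambdaUsed = lambdaUsed,
        genes = panel@genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deconvolute a set of compound samples
#'
#' Each sample is estimated independently; samples sharing a replicate
#' group share the coarse estimate and gene-wise correction factors, both
#' computed from the group's mean expression.
#'
#' @param samples a [CompoundSamples-class] (or genes x samples matrix).
#' @param panel a [ReferencePanel-class].
#' @param weights optional [CrossSampleWeights-class]; genes absent from it
#'   get weight 1, genes with \eqn{w^C = 0} are excluded.
#' @param lambda \code{"auto"} or a numeric regularization strength.
#' @param platformCorrection logical, gene-wise correction on/off.
#' @param minOverlap minimum fraction of panel genes that must be present
#'   in the sample matrix (default 0.5; below is an error).
#' @param control optimizer settings, see [solveProportions()].
#' @return A [DeconvolutionResult-class].
#' @export
deconvolute <- function(samples, panel, weights = NULL, lambda = "auto",
                        platformCorrection = TRUE, minOverlap = 0.5,
                        control = list()) {
    if (!is(samples, "CompoundSamples")) samples <- CompoundSamples(samples)
    cnt <- asDense(counts(samples))
    common <- intersect(panel@genes, rownames(cnt))
    if (length(common) < minOverlap * length(panel@genes))
        stop(sprintf(
            "only %d of %d panel genes found in the samples (< %.0f%%)",
            length(common), length(panel@genes), 100 * minOverlap))
    if (length(common) < length(panel@genes))
        message(sprintf("using %d of %d panel genes present in the samples",
                        length(common), length(panel@genes)))
    idx <- match(common, panel@genes)
    panelSub <- subsetPanel(panel, idx)
    cnt <- cnt[common, , drop = FALSE]
    wC <- rep(1, length(common))
    if (!is.null(weights)) {
        wv <- setNames(weights@wC, weights@genes)
        hit <- common %in% names(wv)
        wC[hit] <- wv[common[hit]]
    }
    groups <- sampleGroups(samples)
    if (is.null(groups)) groups <- colnames(cnt)
    groups <- setNames(as.character(groups), colnames(cnt))
    ug <- unique(groups)
    K <- length(panel@cellTypes)
    S <- ncol(cnt)
    theta <- betaRaw <- tauC <- matrix(NA_real_, S, K,
        dimnames = list(colnames(cnt), panelSub@cellTypes))
    rMat <- matrix(NA_real_, length(common), length(ug),
                   dimnames = list(common, ug))
    lossValue <- nIter <- lambdaUsed <- numeric(S)
    converged <- logical(S)
    for (g in ug) {
        members <- names(groups)[groups == g]
        muG <- rowMeans(cnt[, members, drop = FALSE])
        tau <- coarseEstimate(muG, panelSub,
                              weights = wC * panelSub@specificityWeight,
                              robust = TRUE)
        r <- if (platformCorrection)
            computeCorrectionFactors(muG, panelSub, tau)
        else rep(1, length(common))
        rMat[, g] <- r
        for (s in members) {
            res <- solveProportions(unname(cnt[, s]), panelSub, wC = wC,
                                    lambda = lambda, muGroup = muG,
                                    tau = tau, r = r, control = control)
            j <- match(s, colnames(cnt))
            theta[j, ] <- res@theta
            betaRaw[j, ] <- res@betaRaw
            tauC[j, ] <- tau
            lossValue[j] <- res@lossValue
            nIter[j] <- res@nIter
            converged[j] <- res@converged
            lambdaUsed[j] <- res@lambdaUsed
        }
    }
    new("DeconvolutionResult", theta = theta, betaRaw = betaRaw,
        tauCoarse = tauC, correctionFactors = rMat,
        sampleGroups = groups, lossValue = lossValue, nIter = nIter,
        converged = converged, lambdaUsed = lambdaUsed, genes = common)
}
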