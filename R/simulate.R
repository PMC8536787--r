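#' Synthesize a pseudo-bulk sample from one subject
#'
#' Adds up the raw UMI counts per gene over all of the subject's cells. The
#' ground-truth proportion of each cell type is the fraction of the
#' subject's cells annotated with it, so the truth is exact by construction
#' and the column total of the output equals the subject's total UMIs.
#'
#' @param ref a [ScReference-class] with subject labels.
#' @param subject subject id to pool.
#' @param types optional subset of cell types to include (others excluded
#'   from the pool and given truth 0 only if listed in \code{allTypes}).
#' @param allTypes optional full type universe for the truth vector
#'   (defaults to the types present in \code{ref}); excluded types get an
#'   exact 0.
#' @return list(counts = named numeric vector, truth = [MixingTruth-class]).
#' @export
synthesizeBulk <- function(ref, subject, types = NULL, allTypes = NULL) {
    subj <- subjects(ref)
    if (is.null(subj)) stop("reference has no subject labels")
    if (!subject %in% subj) stop("unknown subject: ", subject)
    labels <- cellTypes(ref)
    if (is.null(allTypes)) allTypes <- sort(unique(labels))
    if (is.null(types)) types <- allTypes
    use <- subj == subject & labels %in% types
    if (!any(use)) stop("subject has no cells of the requested types")
    cnt <- asDense(counts(ref))
    y <- rowSums(cnt[, use, drop = FALSE])
    Tk <- table(factor(labels[use], levels = allTypes))
    theta0 <- as.numeric(Tk) / sum(Tk)
    truth <- new("MixingTruth", theta0 = setNames(theta0, allTypes),
                 provenance = "cell_counts")
    list(counts = y, truth = truth)
}

#' Simulate a spatial transcriptomics spot
#'
#' Samples \code{nCellsPerType} cells without replacement from each named
#' cell type, then weighs each type's pooled counts by its mixing
#' proportion and adds them up. Proportions are normalized to sum to one
#' before use (so printed schemes such as 0.33:0.33:0.33 are valid input);
#' the output is real-valued because it is a weighted sum.
#'
#' @param ref a [ScReference-class].
#' @param proportions named non-negative K'-vector of mixing proportions
#'   (names are cell types present in \code{ref}).
#' @param nCellsPerType cells sampled per type (default 10).
#' @param seed sampling seed.
#' @param schemeId optional scheme label recorded in the truth.
#' @return list(counts = named numeric vector, truth = [MixingTruth-class]).
#' @export
simulateSpot <- function(ref, proportions, nCellsPerType = 10, seed = 1,
                         schemeId = NA_character_) {
    if (is.null(names(proportions)))
        stop("proportions must be named by cell type")
    if (any(proportions < 0)) stop("proportions must be non-negative")
    labels <- cellTypes(ref)
    cnt <- asDense(counts(ref))
    p <- proportions / sum(proportions)
    y <- numeric(nrow(cnt))
    withSeed(seed, {
        for (k in names(p)) {
            cells <- which(labels == k)
            if (length(cells) < nCellsPerType)
                stop(sprintf("cell type '%s' has %d cells; %d required",
                             k, length(cells), nCellsPerType))
            take <- sample(cells, nCellsPerType)
            y <- y + p[[k]] * rowSums(cnt[, take, drop = FALSE])
        }
    })
    names(y) <- rownames(cnt)
    truth <- new("MixingTruth", theta0 = setNames(as.numeric(p), names(p)),
                 provenance = "scheme", schemeId = schemeId,
                 schemeAsPrinted = proportions, seed = as.integer(seed))
    list(counts = y, truth = truth)
}

#' Simulate a rare-cell dilution series of spots
#'
#' For each fraction f in \code{fractions}, \code{nReps} spots are
#' simulated in which the rare type contributes f and the companion types
#' split the remaining 1 - f evenly. Cells are re-sampled for every
#' repetition; per-spot seeds are derived deterministically from
#' \code{seed}.
#'
#' @param ref a [ScReference-class].
#' @param rareType rare cell type name.
#' @param companionTypes other cell types sharing 1 - f equally.
#' @param fractions rare-type fractions (default 0.01 to 0.10 by 0.01).
#' @param nReps repetitions per fraction (default 100).
#' @param nCellsPerType cells sampled per type per spot (default 10).
#' @param seed master seed.
#' @return list of length |fractions| * nReps, each element a
#'   list(counts, truth, fraction, rep).
#' @export
rareCellSeries <- function(ref, rareType, companionTypes,
                           fractions = seq(0.01, 0.10, by = 0.01),
                           nReps = 100, nCellsPerType = 10, seed = 1) {
    types <- c(rareType, companionTypes)
    bad <- setdiff(types, unique(cellTypes(ref)))
    if (length(bad)) stop("unknown cell types: ", paste(bad, collapse = ", "))
    seeds <- deriveSeeds(seed, length(fractions) * nReps)
    out <- vector("list", length(fractions) * nReps)
    i <- 0L
    for (f in fractions) {
        p <- setNames(c(f, rep((1 - f) / length(companionTypes),
                               length(companionTypes))), types)
        for (rep in seq_len(nReps)) {
            i <- i + 1L
            sp <- simulateSpot(ref, p, nCellsPerType = nCellsPerType,
                               seed = seeds[i])
            out[[i]] <- list(counts = sp$counts, truth = sp$truth,
                             fraction = f, rep = rep)
        }
    }
    out
}

#' Generate a fully synthetic single-cell reference with known truth
#'
#' Emulates the statistical structure the deconvolution model assumes:
#' negative-binomially distributed UMI counts per (gene, cell type),
#' disjoint marker blocks upweighted by \code{markerFold}, cell-type-level
#' differences in total transcript content (\code{typeScaleRange}; real
#' tissues show up to ~10-fold differences), per-cell lognormal size
#' factors with unit mean, and optional subjects with a mild lognormal
#' depth jitter.
#'
#' @param nGenes,nTypes,cellsPerType dataset dimensions.
#' @param markerFrac fraction of genes assigned to marker blocks, split
#'   evenly over types (default 0.2).
#' @param markerFold fold upweighting of a marker in its own type
#'   (default 8; 1 disables marker structure).
#' @param typeScaleRange range of per-type total-transcript scale factors.
#' @param dispersionRange range of NB size (dispersion) parameters.
#' @param nSubjects number of subjects (cells assigned round-robin).
#' @param subjectSd lognormal sd of the per-subject depth jitter.
#' @param cellSd lognormal sd of per-cell size factors (unit mean).
#' @param baseMeanLog,baseMeanSd lognormal parameters of baseline gene
#'   means (per-cell scale).
#' @param seed master seed; identical seeds give identical datasets.
#' @return list(ref = [ScReference-class], truth = list with muTrue,
#'   dispersionTrue, markerBlocks, typeScales, subjectScales, seed).
#' @export
generateSyntheticReference <- function(nGenes = 1000, nTypes = 8,
        cellsPerType = 300, markerFrac = 0.2, markerFold = 8,
        typeScaleRange = c(0.5, 5), dispersionRange = c(1, 10),
        nSubjects = 1, subjectSd = 0.05, cellSd = 0.3,
        baseMeanLog = log(0.5), baseMeanSd = 1, seed = 1) {
    stopifnot(nGenes > 0, nTypes > 0, cellsPerType > 0,
              markerFrac > 0, markerFrac < 1, markerFold >= 1,
              nSubjects >= 1)
    withSeed(seed, {
        genes <- sprintf("gene%04d", seq_len(nGenes))
        types <- paste0("type", seq_len(nTypes))
        base <- exp(rnorm(nGenes, baseMeanLog, baseMeanSd))
        nMark <- floor(nGenes * markerFrac / nTypes)
        markerBlocks <- setNames(vector("list", nTypes), types)
        muTrue <- matrix(rep(base, nTypes), nGenes, nTypes,
                         dimnames = list(genes, types))
        for (k in seq_len(nTypes)) {
            block <- ((k - 1) * nMark + 1):(k * nMark)
            markerBlocks[[k]] <- genes[block]
            muTrue[block, k] <- muTrue[block, k] * markerFold
        }
        typeScales <- setNames(
            runif(nTypes, typeScaleRange[1], typeScaleRange[2]), types)
        muTrue <- sweep(muTrue, 2, typeScales, "*")
        dispTrue <- matrix(
            runif(nGenes * nTypes, dispersionRange[1], dispersionRange[2]),
            nGenes, nTypes, dimnames = list(genes, types))
        subjectScales <- exp(rnorm(nSubjects, 0, subjectSd))
        # exact mean 1 so the recorded muTrue stays the marginal truth
        subjectScales <- setNames(subjectScales / mean(subjectScales),
                                  paste0("subject", seq_len(nSubjects)))
        N <- nTypes * cellsPerType
        cellType <- rep(types, each = cellsPerType)
        # subjects receive type-dependent shares of cells so that their
        # compositions differ (Dirichlet(5) weights per type); with one
        # subject this reduces to all cells in subject1
        subject <- unlist(lapply(seq_len(nTypes), function(k) {
            g <- rgamma(nSubjects, 5)
            sample(names(subjectScales), cellsPerType, replace = TRUE,
                   prob = g / sum(g))
        }))
        sizeFactor <- exp(rnorm(N, -cellSd^2 / 2, cellSd))
        cnt <- matrix(0L, nGenes, N, dimnames = list(
            genes, sprintf("cell%05d", seq_len(N))))
        for (j in seq_len(N)) {
            k <- match(cellType[j], types)
            m <- muTrue[, k] * sizeFactor[j] *
                subjectScales[[subject[j]]]
            cnt[, j] <- rnbinom(nGenes, size = dispTrue[, k], mu = m)
        }
        ref <- ScReference(cnt, cellType = cellType, subject = subject)
        list(ref = ref,
             truth = list(muTrue = muTrue, dispersionTrue = dispTrue,
                          markerBlocks = markerBlocks,
                          typeScales = typeScales,
                          subjectScales = subjectScales,
                          cellSd = cellSd, seed = seed))
    })
}

#' Apply multiplicative per-gene platform bias
#'
#' Multiplies each gene's count by \eqn{\exp(N(0, \sigma^2))}, emulating a
#' gene-specific systematic difference between measurement platforms. The
#' multipliers are returned for diagnostics.
#'
#' @param counts named numeric vector.
#' @param biasSigma standard deviation of the log-normal bias (0 = none).
#' @param seed seed for the multipliers.
#' @return list(counts = biased vector, multipliers = per-gene factors).
#' @export
injectPlatformBias <- function(counts, biasSigma, seed = 1) {
    stopifnot(biasSigma >= 0)
    if (biasSigma == 0) {
        mult <- rep(1, length(counts))
    } else {
        mult <- withSeed(seed, exp(rnorm(length(counts), 0, biasSigma)))
    }
    names(mult) <- names(counts)
    list(counts = counts * mult, multipliers = mult)
}
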