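#' Concordance between estimated and true proportions
#'
#' Computes the mean absolute difference
#' \eqn{mAD = \sum_k |\theta_k - \theta^0_k| / K}, the root mean square
#' deviation \eqn{RMSD = \sqrt{\sum_k (\theta_k - \theta^0_k)^2 / K}}
#' (the un-rooted mean-squared variant is reported alongside as
#' \code{rmsd_literal}), and Pearson / Spearman correlations (Spearman with
#' average ranks for ties). Zero-variance inputs make the correlations
#' undefined; they are returned as NA with a warning.
#'
#' @param theta,theta0 estimated and true proportion vectors (equal
#'   length; >= 2 for correlations).
#' @return Named numeric: mad, rmsd, rmsd_literal, pearson, spearman.
#' @export
concordanceMetrics <- function(theta, theta0) {
    if (length(theta) != length(theta0))
        stop("theta and theta0 must have equal length")
    d <- theta - theta0
    mad <- mean(abs(d))
    msd <- mean(d^2)
    pear <- spear <- NA_real_
    if (length(theta) >= 2) {
        if (var(theta) == 0 || var(theta0) == 0) {
            warning("zero-variance input: correlations undefined")
        } else {
            pear <- cor(theta, theta0, method = "pearson")
            spear <- cor(theta, theta0, method = "spearman")
        }
    }
    c(mad = mad, rmsd = sqrt(msd), rmsd_literal = msd,
      pearson = pear, spearman = spear)
}

#' ROC curve and AUC over cell-type presence calls
#'
#' Sweeps a detection threshold over all distinct estimated proportions
#' (plus 0 and 1); at each threshold, a (sample, type) pair is called
#' present when its estimate exceeds the threshold. Pairs are pooled
#' globally; equal scores move together (one threshold step), and the AUC
#' is the trapezoid area, which equals the Mann-Whitney probability of
#' correct ordering with ties counted one half.
#'
#' @param estimates samples x types numeric matrix (or vector) of
#'   estimated proportions.
#' @param presenceTruth logical matrix/vector of the same shape; TRUE where
#'   the type is truly present.
#' @return list(roc = data.frame(threshold, fpr, tpr), auc = scalar).
#' @export
rocAuc <- function(estimates, presenceTruth) {
    score <- as.numeric(estimates)
    truth <- as.logical(presenceTruth)
    if (length(score) != length(truth))
        stop("estimates and presenceTruth must have the same shape")
    nPos <- sum(truth); nNeg <- sum(!truth)
    if (nPos == 0 || nNeg == 0)
        stop("presence truth must contain at least one positive and one ",
             "negative")
    thr <- sort(unique(c(0, 1, score)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(score[truth] >= t) / nPos,
                  numeric(1))
    fpr <- vapply(thr, function(t) sum(score[!truth] >= t) / nNeg,
                  numeric(1))
    # prepend the all-negative point
    roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
    auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
    list(roc = roc, auc = auc)
}

#' Detection rate of a rare cell type
#'
#' Fraction of repetitions whose estimated proportion strictly exceeds the
#' detection threshold (an inferred percent greater than the cutoff is a
#' positive detection).
#'
#' @param estimates numeric vector of estimated proportions over reps.
#' @param threshold detection cutoff (default 0.005, i.e. 0.5%).
#' @return Scalar rate in [0, 1].
#' @export
detectionRate <- function(estimates, threshold = 0.005) {
    if (!length(estimates)) stop("estimates must be non-empty")
    mean(estimates > threshold)
}

#' Leave-one-out pseudo-bulk benchmark
#'
#' For each subject in the reference: a panel is rebuilt from the other
#' subjects' cells, a pseudo-bulk sample is synthesized from the held-out
#' subject, deconvoluted, and scored against the cell-count truth. The
#' pooled row concatenates all (subject, type) pairs.
#'
#' @param ref a [ScReference-class] with >= 3 subjects.
#' @param lambda regularization passed to [deconvolute()].
#' @param geneMode gene selection mode for the rebuilt panels.
#' @param vmrMode cross-sample weight mode (default bootstrap on the
#'   training cells).
#' @param B bootstrap pseudo-sample count.
#' @param seed seed for gene selection / bootstrap.
#' @param platformCorrection gene-wise correction on/off.
#' @param ... passed to [buildReference()].
#' @return An [EvaluationReport-class]; \code{perSample} has one row per
#'   subject, \code{details$theta} and \code{details$truth} the matrices.
#' @export
leaveOneOutBenchmark <- function(ref, lambda = "auto", geneMode = "marker",
                                 vmrMode = "bootstrap", B = 20, seed = 1,
                                 platformCorrection = TRUE, ...) {
    subj <- subjects(ref)
    if (is.null(subj) || length(unique(subj)) < 3)
        stop("leave-one-out requires >= 3 subjects")
    subjectsAll <- sort(unique(subj))
    allTypes <- sort(unique(cellTypes(ref)))
    rows <- list(); thetas <- list(); truths <- list()
    for (s in subjectsAll) {
        train <- ref[, subj != s]
        train <- new("ScReference", train)
        panel <- buildReference(train, geneMode = geneMode, seed = seed,
                                ...)
        wts <- computeCrossSampleWeights(train, mode = vmrMode, B = B,
                                         seed = seed,
                                         genes = selectedGenes(panel))
        bulk <- synthesizeBulk(ref, s, allTypes = allTypes)
        cs <- CompoundSamples(matrix(bulk$counts,
                                     dimnames = list(names(bulk$counts), s)))
        res <- deconvolute(cs, panel, weights = wts, lambda = lambda,
                           platformCorrection = platformCorrection)
        th <- proportions(res)[1, allTypes]
        tr <- proportions(bulk$truth)[allTypes]
        m <- concordanceMetrics(th, tr)
        rows[[s]] <- data.frame(subject = s, t(m))
        thetas[[s]] <- th; truths[[s]] <- tr
    }
    perSample <- do.call(rbind, c(rows, make.row.names = FALSE))
    thetaM <- do.call(rbind, thetas)
    truthM <- do.call(rbind, truths)
    pooled <- concordanceMetrics(as.numeric(thetaM), as.numeric(truthM))
    new("EvaluationReport", perSample = perSample, pooled = pooled,
        details = list(theta = thetaM, truth = truthM,
                       subjects = subjectsAll, seed = seed))
}
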