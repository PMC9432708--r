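#' Per-iteration removal count of percentage-based RFE
#'
#' Number of features eliminated in one step of %-RFE when the current
#' feature space holds \code{currentP} features:
#' \code{max(1, floor(pct * currentP))}. At a 1\% rate this removes 4730
#' features from a 473,035-feature array and 1 feature from 100 — the
#' step size scales dynamically with the shrinking feature space, which
#' is what makes recursive elimination tractable on array-scale data.
#' The caller ([pctRfeSelect()]) additionally clips the count so the
#' survivor count never drops below the target.
#'
#' @param currentP current number of features (positive integer).
#' @param pct removal fraction in (0, 1), default 0.01.
#' @return integer removal count, at least 1.
#' @examples
#' removalCount(473035, 0.01)  # 4730
#' removalCount(100, 0.01)     # 1
#' @export
removalCount <- function(currentP, pct = 0.01) {
    if (currentP < 1)
        stop("currentP must be positive", call. = FALSE)
    if (pct <= 0 || pct >= 1)
        stop("pct must lie in (0, 1)", call. = FALSE)
    max(1L, as.integer(floor(pct * currentP)))
}

#' Percentage-based recursive feature elimination (\%-RFE)
#'
#' Recursive feature elimination whose per-iteration step removes a
#' fixed fraction of the \emph{current} feature space rather than a
#' fixed count: aggressive while the space is large, and down to
#' single-feature steps (classic RFE) once few features remain. Each
#' iteration fits the estimator on the surviving features, computes
#' importances, and eliminates the [removalCount()] lowest-importance
#' features — clipped so the survivor count never undershoots
#' \code{targetN}. The loop terminates with exactly \code{targetN}
#' survivors.
#'
#' Elimination uses the package-wide ranking (importance descending,
#' ties by lexicographic CpG id): the features at the bottom of that
#' ranking are removed, so results are invariant to input column order.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param targetN number of features to keep (typical presets: 100,
#'   1500, 10000).
#' @param pct per-iteration removal fraction, default 0.01.
#' @param estimator importance backend, as in [selectFromModel()];
#'   default penalized-linear.
#' @param nTrees tree count for the ensemble backend.
#' @param seed RNG seed (used by the ensemble backend).
#' @return a \linkS4class{FeatureSet} of exactly \code{targetN} CpGs;
#'   scores are the survivors' importances from the final fitted model
#'   (\code{NULL} when \code{targetN} equals the input size and no model
#'   was fitted). The iteration count is recorded in the provenance.
#' @seealso [removalCount()] for the step-size rule.
#' @export
pctRfeSelect <- function(m, targetN, pct = 0.01,
                         estimator = c("penalized-linear",
                                       "tree-ensemble"),
                         nTrees = 100L, seed = 1L) {
    estimator <- match.arg(estimator)
    stopIfMissingBetas(m, "pctRfeSelect")
    x <- betas(m)
    targetN <- as.integer(targetN)
    if (targetN < 1L || targetN > ncol(x))
        stop("targetN must lie in [1, ", ncol(x), "], got ", targetN,
             call. = FALSE)
    surviving <- sort(colnames(x))
    iter <- 0L
    lastImp <- NULL
    while (length(surviving) > targetN) {
        iter <- iter + 1L
        imp <- tryCatch(
            .fitImportance(x[, surviving, drop = FALSE], unname(ages(m)),
                           estimator, nTrees = as.integer(nTrees),
                           seed = mixSeed(seed, iter)),
            error = function(e)
                stop("estimator failed at %-RFE iteration ", iter,
                     " with ", length(surviving), " surviving features: ",
                     conditionMessage(e), call. = FALSE))
        nDrop <- min(removalCount(length(surviving), pct),
                     length(surviving) - targetN)
        ranking <- scoreOrder(imp, surviving)
        drop <- ranking[seq(length(surviving) - nDrop + 1L,
                            length(surviving))]
        surviving <- surviving[-drop]
        lastImp <- imp[surviving]
    }
    scores <- if (is.null(lastImp)) NULL else unname(lastImp)
    fs <- featureSet(surviving, scores = scores,
                     provenance = sprintf(
                         "pct_rfe(target=%d, pct=%g, %s, iterations=%d)",
                         targetN, pct, estimator, iter))
    if (!is.null(scores)) {
        ord <- scoreOrder(scores, surviving)
        fs <- featureSet(surviving[ord], scores = scores[ord],
                         provenance = provenance(fs))
    }
    fs
}

#' @rdname selectorConstructors
#' @param targetN,pct parameters of [pctRfeSelect()].
#' @export
pctRfeSelector <- function(targetN, pct = 0.01,
                           estimator = "penalized-linear",
                           nTrees = 100L, seed = 1L)
    new("PctRfeSelector", targetN = as.integer(targetN),
        pct = as.numeric(pct), estimator = estimator,
        nTrees = as.integer(nTrees), seed = as.integer(seed))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "PctRfeSelector",
    function(selector, m, ...)
        pctRfeSelect(m, selector@targetN, selector@pct,
                     selector@estimator, selector@nTrees, selector@seed))
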