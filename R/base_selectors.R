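#' Univariate correlation ranking (KBest)
#'
#' Ranks every CpG by the absolute Pearson correlation between its beta
#' values and chronological age and returns the top \code{k}. A
#' zero-variance column has correlation defined as 0. Ties are broken by
#' lexicographic CpG identifier (larger score first, then id), the
#' package-wide rule, so the result is invariant to input column order.
#'
#' This single-pass ranking is the cheapest selector in the toolkit and
#' the canonical pre-reduction step before the more expensive
#' all-relevant methods (e.g. keep the top 2000, then run
#' [borutaSelect()]).
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param k number of CpGs to keep, \code{1 <= k <=} number of CpGs.
#' @return a \linkS4class{FeatureSet} with \code{scores = |r|}, sorted
#'   descending.
#' @export
selectKBest <- function(m, k) {
    stopIfMissingBetas(m, "selectKBest")
    x <- betas(m)
    k <- as.integer(k)
    if (k < 1L || k > ncol(x))
        stop("k must lie in [1, ", ncol(x), "], got ", k, call. = FALSE)
    a <- unname(ages(m))
    r <- suppressWarnings(as.numeric(stats::cor(x, a)))
    r[is.na(r)] <- 0
    s <- abs(r)
    ord <- scoreOrder(s, colnames(x))[seq_len(k)]
    featureSet(colnames(x)[ord], scores = s[ord],
               provenance = sprintf("kbest(k=%d)", k))
}

#' Variance-threshold filtering
#'
#' Retains CpGs whose population variance (denominator \code{n}) is
#' strictly greater than \code{threshold}. With \code{threshold = 0}
#' this removes exactly the constant columns. Output order follows the
#' package-wide rule: descending variance, ties by CpG id.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param threshold non-negative variance cutoff, default 0.
#' @return a \linkS4class{FeatureSet} with \code{scores} = population
#'   variance.
#' @export
varianceThreshold <- function(m, threshold = 0) {
    stopIfMissingBetas(m, "varianceThreshold")
    if (threshold < 0)
        stop("threshold must be non-negative", call. = FALSE)
    x <- betas(m)
    n <- nrow(x)
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    keep <- which(v > threshold)
    ord <- keep[scoreOrder(v[keep], colnames(x)[keep])]
    featureSet(colnames(x)[ord], scores = v[ord],
               provenance = sprintf("variance_threshold(t=%g)", threshold))
}

#' Model-threshold selection (select-from-model)
#'
#' Fits one estimator on the full matrix and keeps every CpG whose
#' importance reaches \code{threshold}. Importance is the absolute
#' (unstandardized) coefficient for the penalized-linear estimator, and
#' the mean impurity importance for the extremely-randomized-trees
#' ensemble. An empty result is returned, not an error: thresholds above
#' the maximum importance legitimately yield zero features.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param estimator \code{"penalized-linear"} (elastic net) or
#'   \code{"tree-ensemble"} (extra-trees).
#' @param threshold non-negative importance cutoff; default 0.01.
#' @param nTrees tree count for the ensemble estimator, default 100.
#' @param seed RNG seed for the ensemble estimator.
#' @return a \linkS4class{FeatureSet} (possibly empty) with importances
#'   as scores, sorted descending.
#' @export
selectFromModel <- function(m,
                            estimator = c("penalized-linear",
                                          "tree-ensemble"),
                            threshold = 0.01, nTrees = 100L,
                            seed = 1L) {
    estimator <- match.arg(estimator)
    stopIfMissingBetas(m, "selectFromModel")
    if (threshold < 0)
        stop("threshold must be non-negative", call. = FALSE)
    x <- betas(m)
    imp <- .fitImportance(x, unname(ages(m)), estimator,
                          nTrees = as.integer(nTrees), seed = seed)
    keep <- which(imp >= threshold)
    ord <- keep[scoreOrder(imp[keep], names(imp)[keep])]
    featureSet(names(imp)[ord], scores = unname(imp[ord]),
               provenance = sprintf("sfm(%s, threshold=%g)", estimator,
                                    threshold))
}

## selector-object methods ---------------------------------------------------

#' Selector constructors
#'
#' Build selector objects for use with [selectFeatures()], selector
#' chains ([chainSelectors()]) and the cross-validated workflow
#' ([runCvSelection()]). Each constructor mirrors the functional
#' interface of the corresponding module: [selectKBest()],
#' [varianceThreshold()], [selectFromModel()], [pctRfeSelect()],
#' [borutaSelect()], [gaSelect()], [nnPerturbationSelect()].
#' \code{functionSelector()} wraps an arbitrary
#' \code{function(m) -> FeatureSet}.
#'
#' @param k,threshold,estimator,nTrees,seed,fn,label parameters of the
#'   corresponding selector function; see its help page.
#' @return a \linkS4class{CpgSelector}.
#' @examples
#' sel <- kBestSelector(25)
#' ds <- generateClockDataset(syntheticSpec(nSamples = 60, nCpgs = 40,
#'                                          nInformative = 2, seed = 3))
#' length(selectFeatures(sel, ds$matrix))
#' @name selectorConstructors
NULL

#' @rdname selectorConstructors
#' @export
kBestSelector <- function(k) new("KBestSelector", k = as.integer(k))

#' @rdname selectorConstructors
#' @export
varianceSelector <- function(threshold = 0)
    new("VarianceSelector", threshold = as.numeric(threshold))

#' @rdname selectorConstructors
#' @export
sfmSelector <- function(estimator = "penalized-linear", threshold = 0.01,
                        nTrees = 100L, seed = 1L)
    new("SfmSelector", estimator = estimator,
        threshold = as.numeric(threshold), nTrees = as.integer(nTrees),
        seed = as.integer(seed))

#' @rdname selectorConstructors
#' @export
functionSelector <- function(fn, label = "custom")
    new("FunctionSelector", fn = fn, label = label)

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "KBestSelector",
    function(selector, m, ...) selectKBest(m, selector@k))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "VarianceSelector",
    function(selector, m, ...) varianceThreshold(m, selector@threshold))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "SfmSelector",
    function(selector, m, ...)
        selectFromModel(m, selector@estimator, selector@threshold,
                        selector@nTrees, selector@seed))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "FunctionSelector",
    function(selector, m, ...) {
        fs <- selector@fn(m)
        if (!is(fs, "FeatureSet"))
            stop("FunctionSelector '", selector@label,
                 "' did not return a FeatureSet", call. = FALSE)
        fs
    })
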