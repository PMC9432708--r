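#' Augment a matrix with shadow features
#'
#' Appends to every real CpG a "shadow": an independent row-permutation
#' of its beta column. Shadows preserve each column's marginal
#' distribution while destroying any association with age, which makes
#' them the importance null that [borutaSelect()] competes real features
#' against. Shadow identifiers are the real id prefixed with
#' \code{"shadow__"} and can never collide with CpG ids.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param seed integer RNG seed; the permutations are seed-deterministic.
#' @return a \linkS4class{MethylationExperiment} with \code{2p} features
#'   (all real CpGs followed by their shadows).
#' @export
makeShadowFeatures <- function(m, seed = 1L) {
    stopIfMissingBetas(m, "makeShadowFeatures")
    x <- betas(m)
    withSeed(seed, {
        sh <- apply(x, 2L, function(col) col[sample.int(length(col))])
        colnames(sh) <- paste0("shadow__", colnames(x))
        MethylationExperiment(cbind(x, sh), ages = unname(ages(m)),
                              sampleIds = rownames(x))
    })
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' Identifies every CpG carrying predictive information about age by
#' repeated competition against permuted shadow copies. Each iteration
#' regenerates fresh shadows, fits a random-forest regressor on the
#' doubled matrix, and records a "hit" for every real CpG whose impurity
#' importance exceeds the competition benchmark — by default the maximum
#' importance over all shadows (\code{compare = "max"}, the canonical
#' construction), or the CpG's own shadow (\code{compare = "own"}).
#' After \code{nIterations} rounds, a CpG is selected when its hit count
#' is significantly above the Binomial(\code{nIterations}, 0.5) null by
#' a one-sided binomial test at level \code{alpha} with Bonferroni
#' correction across the \code{p} real features. There is no "tentative"
#' category: unconfirmed features are rejected.
#'
#' Doubling the matrix makes this expensive on array-scale inputs; the
#' intended de-novo configuration there is a reduced forest
#' (\code{nTrees} of 7-8 with 100 iterations), while after a cheap
#' pre-reduction (e.g. [selectKBest()] to 2000) the default 100-tree
#' forest is affordable — chaining a fast selector into this one is the
#' toolkit's flagship combination.
#'
#' @param m a complete \linkS4class{MethylationExperiment} (pre-reduce
#'   first when \code{p} is huge).
#' @param nTrees trees per forest, default 100.
#' @param nIterations competition rounds, default 100.
#' @param alpha significance level of the hit-count test, default 0.05.
#' @param compare \code{"max"} (beat the best shadow) or \code{"own"}
#'   (beat your own shadow).
#' @param seed integer RNG seed driving shadows and forests.
#' @return a \linkS4class{FeatureSet} of confirmed CpGs with
#'   \code{scores} = hit fraction, sorted descending.
#' @export
borutaSelect <- function(m, nTrees = 100L, nIterations = 100L,
                         alpha = 0.05, compare = c("max", "own"),
                         seed = 1L) {
    compare <- match.arg(compare)
    stopIfMissingBetas(m, "borutaSelect")
    if (alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)", call. = FALSE)
    nIterations <- as.integer(nIterations)
    nTrees <- as.integer(nTrees)
    x <- betas(m)
    a <- unname(ages(m))
    real <- colnames(x)
    p <- length(real)
    hits <- stats::setNames(integer(p), real)
    n <- nrow(x)
    for (it in seq_len(nIterations)) {
        itSeed <- mixSeed(seed, it)
        sh <- withSeed(itSeed, {
            apply(x, 2L, function(col) col[sample.int(n)])
        })
        colnames(sh) <- paste0("shadow__", real)
        imp <- .fitImportance(cbind(x, sh), a, "tree-ensemble",
                              nTrees = nTrees, seed = itSeed + 1L,
                              splitrule = "variance")
        realImp <- imp[real]
        shImp <- imp[paste0("shadow__", real)]
        beat <- if (compare == "max") realImp > max(shImp)
                else realImp > unname(shImp)
        hits <- hits + as.integer(beat)
    }
    pval <- stats::pbinom(hits - 1L, nIterations, 0.5,
                          lower.tail = FALSE)
    sel <- names(hits)[pval <= alpha / p]
    frac <- hits[sel] / nIterations
    ord <- scoreOrder(frac, sel)
    featureSet(sel[ord], scores = unname(frac[ord]),
               provenance = sprintf(
                   "boruta(trees=%d, iterations=%d, alpha=%g, %s)",
                   nTrees, nIterations, alpha, compare))
}

#' @rdname selectorConstructors
#' @param nIterations,alpha,compare parameters of [borutaSelect()].
#' @export
borutaSelector <- function(nTrees = 100L, nIterations = 100L,
                           alpha = 0.05, compare = "max", seed = 1L)
    new("BorutaSelector", nTrees = as.integer(nTrees),
        nIterations = as.integer(nIterations), alpha = as.numeric(alpha),
        compare = compare, seed = as.integer(seed))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "BorutaSelector",
    function(selector, m, ...)
        borutaSelect(m, selector@nTrees, selector@nIterations,
                     selector@alpha, selector@compare, selector@seed))
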