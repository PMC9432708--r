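#' Neural-network perturbation feature selection
#'
#' Ranks a pre-reduced feature space by how much forcing each CpG to the
#' extremes of the beta scale changes a feed-forward regressor's
#' held-out accuracy. One benchmark network is trained on the unmodified
#' data; then, for every CpG, the network is retrained twice on modified
#' copies — the CpG's column set entirely to 1 (fully methylated) and
#' entirely to 0 (fully unmethylated), in both the training and
#' validation parts — and the perturbation score is
#' \code{delta = |benchmark - mean(score_ones, score_zeros)|}. A large
#' delta means the network's accuracy depends on that CpG's actual
#' values. The \code{topN} CpGs by delta are returned.
#'
#' The method presumes a prior reduction of the feature space (the
#' canonical route is [pctRfeSelect()] down to \code{prefilterTarget}
#' features; compose the two with [chainSelectors()]): training
#' \code{1 + 2p} networks is only tractable for small \code{p}. The
#' network is deliberately rudimentary — a single hidden layer
#' (default 32 logistic units, linear output) trained by BFGS on
#' range-scaled ages with weight decay — the smallest architecture that
#' ranks informative against null CpGs reliably. All trainings reuse the
#' same initialisation seed so deltas reflect the perturbation, not
#' initialisation noise.
#'
#' @param m a complete \linkS4class{MethylationExperiment} with at most
#'   \code{prefilterTarget} CpGs.
#' @param topN number of features to return; default 65. With
#'   \code{strict = TRUE} it must lie in [50, 75] (the intended
#'   operating band after a 100-feature pre-reduction).
#' @param prefilterTarget maximum admissible feature count, default 100.
#' @param hidden width of the single hidden layer, default 32.
#' @param epochs optimiser iteration budget, default 200.
#' @param decay weight-decay regulariser, default 1e-4.
#' @param validationFraction held-out fraction for scoring, default 0.2.
#' @param strict enforce the [50, 75] band on \code{topN}.
#' @param seed integer seed for the split and all network
#'   initialisations.
#' @return a \linkS4class{FeatureSet} of exactly \code{topN} CpGs,
#'   \code{scores = delta}, sorted descending.
#' @export
nnPerturbationSelect <- function(m, topN = 65L, prefilterTarget = 100L,
                                 hidden = 32L, epochs = 200L,
                                 decay = 1e-4, validationFraction = 0.2,
                                 strict = FALSE, seed = 1L) {
    stopIfMissingBetas(m, "nnPerturbationSelect")
    topN <- as.integer(topN)
    prefilterTarget <- as.integer(prefilterTarget)
    hidden <- as.integer(hidden)
    if (length(hidden) != 1L)
        stop("a single hidden layer is supported; give one width",
             call. = FALSE)
    x <- betas(m)
    p <- ncol(x)
    if (p > prefilterTarget)
        stop("matrix has ", p, " CpGs; pre-reduce to at most ",
             prefilterTarget, " (e.g. with pctRfeSelect) first",
             call. = FALSE)
    if (strict && (topN < 50L || topN > 75L))
        stop("strict mode requires topN in [50, 75], got ", topN,
             call. = FALSE)
    if (topN > p)
        stop("topN (", topN, ") exceeds the feature count (", p, ")",
             call. = FALSE)
    a <- unname(ages(m))
    n <- nrow(x)
    withSeed(seed, {
        nVal <- max(1L, as.integer(floor(validationFraction * n)))
        valIdx <- sort(sample.int(n, nVal))
    })
    trainIdx <- setdiff(seq_len(n), valIdx)
    aMin <- min(a[trainIdx]); aRange <- max(a[trainIdx]) - aMin
    if (aRange == 0) aRange <- 1
    initSeed <- mixSeed(seed, 777L)

    trainScore <- function(xMat, what) {
        .cpgSieveState$nnFits <- .cpgSieveState$nnFits + 1L
        fit <- withSeed(initSeed,
            nnet::nnet(x = xMat[trainIdx, , drop = FALSE],
                       y = (a[trainIdx] - aMin) / aRange,
                       size = hidden, linout = TRUE, trace = FALSE,
                       maxit = as.integer(epochs), decay = decay,
                       MaxNWts = (p + 1L) * hidden + hidden + 1L + 10L))
        if (!is.finite(fit$value))
            stop("network training diverged (non-finite loss) for ",
                 what, call. = FALSE)
        pred <- as.numeric(stats::predict(
            fit, xMat[valIdx, , drop = FALSE])) * aRange + aMin
        rSquared(a[valIdx], pred)
    }

    benchmark <- trainScore(x, "benchmark")
    delta <- stats::setNames(numeric(p), colnames(x))
    for (j in seq_len(p)) {
        x1 <- x; x1[, j] <- 1
        x0 <- x; x0[, j] <- 0
        s1 <- trainScore(x1, paste0(colnames(x)[j], " (all ones)"))
        s0 <- trainScore(x0, paste0(colnames(x)[j], " (all zeros)"))
        delta[j] <- abs(benchmark - mean(c(s1, s0)))
    }
    ord <- scoreOrder(delta, names(delta))[seq_len(topN)]
    featureSet(names(delta)[ord], scores = unname(delta[ord]),
               provenance = sprintf(
                   "nn_perturbation(topN=%d, hidden=%d, benchmark=%.4f)",
                   topN, hidden, benchmark))
}

#' @rdname selectorConstructors
#' @param topN,prefilterTarget,hidden,epochs,decay,strict parameters of
#'   [nnPerturbationSelect()].
#' @export
nnSelector <- function(topN = 65L, prefilterTarget = 100L, hidden = 32L,
                       epochs = 200L, decay = 1e-4,
                       validationFraction = 0.2, strict = FALSE,
                       seed = 1L)
    new("NnSelector", topN = as.integer(topN),
        prefilterTarget = as.integer(prefilterTarget),
        hidden = as.integer(hidden), epochs = as.integer(epochs),
        decay = as.numeric(decay),
        validationFraction = as.numeric(validationFraction),
        strict = strict, seed = as.integer(seed))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "NnSelector",
    function(selector, m, ...)
        nnPerturbationSelect(m, selector@topN, selector@prefilterTarget,
                             selector@hidden, selector@epochs,
                             selector@decay,
                             selector@validationFraction,
                             selector@strict, selector@seed))
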