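#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("numeric_OR_NULL", c("numeric", "NULL"))

#' MethylationExperiment: beta values plus chronological age
#'
#' Container for a methylation beta-value matrix with per-sample
#' chronological ages, extending
#' \linkS4class{SummarizedExperiment}. CpG sites are stored in rows and
#' samples in columns (the Bioconductor convention); the \code{betas()}
#' accessor returns the transposed samples-by-CpGs design view that the
#' selectors and clock models consume. Ages live in \code{colData(x)$age}.
#'
#' Validity requires: all non-missing betas in [0, 1]; unique CpG and
#' sample identifiers; a numeric, non-negative \code{age} column.
#'
#' @seealso [MethylationExperiment()] for construction from a
#'   samples-by-CpGs matrix, [loadMethylationTable()] for reading
#'   delimited exports.
#' @exportClass MethylationExperiment
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!"betas" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'betas' is required")
    else {
        b <- SummarizedExperiment::assay(object, "betas")
        if (!is.numeric(b))
            msg <- c(msg, "betas must be numeric")
        else {
            bad <- b[!is.na(b)]
            if (length(bad) && (min(bad) < 0 || max(bad) > 1))
                msg <- c(msg, "non-missing beta values must lie in [0, 1]")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "CpG identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"age" %in% colnames(cd))
        msg <- c(msg, "colData must contain an 'age' column")
    else {
        a <- cd$age
        if (!is.numeric(a))
            msg <- c(msg, "ages must be numeric")
        else if (any(!is.na(a) & a < 0))
            msg <- c(msg, "ages must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' FeatureSet: an ordered set of selected CpG sites
#'
#' Result type shared by every selector: an ordered, duplicate-free vector
#' of CpG identifiers, optionally with aligned importance scores, plus a
#' free-text provenance describing the method that produced it.
#'
#' @slot cpgIds character vector of unique CpG identifiers, in rank order.
#' @slot scores optional numeric importances aligned 1:1 with
#'   \code{cpgIds}, or \code{NULL}.
#' @slot provenance character(1) method descriptor.
#' @exportClass FeatureSet
setClass("FeatureSet",
    representation(cpgIds = "character",
                   scores = "numeric_OR_NULL",
                   provenance = "character"),
    prototype(cpgIds = character(), scores = NULL, provenance = ""))

setValidity("FeatureSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@cpgIds))
        msg <- c(msg, "cpgIds must be unique")
    if (!is.null(object@scores) &&
        length(object@scores) != length(object@cpgIds))
        msg <- c(msg, "scores must align 1:1 with cpgIds")
    if (length(object@provenance) != 1L)
        msg <- c(msg, "provenance must be a single string")
    if (length(msg)) msg else TRUE
})

#' ClockModel: a fitted elastic-net epigenetic clock
#'
#' Linear age predictor \eqn{\hat y = b + \sum_j \beta_j x_j} over a panel
#' of CpG sites, fitted by minimising
#' \eqn{\sum_i (y_i - \hat y_i)^2 + \lambda_1 \sum_j |\beta_j| +
#' \lambda_2 \sum_j \beta_j^2}.
#'
#' @slot cpgIds CpG identifiers of the model features.
#' @slot beta per-feature coefficients (years per unit methylation).
#' @slot intercept intercept \eqn{b} in years.
#' @slot lambdaL1,lambdaL2 the L1/L2 penalty weights of the objective
#'   (both \eqn{\ge 0}).
#' @slot provenance list recording seed, tuning grid and fit details.
#' @exportClass ClockModel
setClass("ClockModel",
    representation(cpgIds = "character",
                   beta = "numeric",
                   intercept = "numeric",
                   lambdaL1 = "numeric",
                   lambdaL2 = "numeric",
                   provenance = "list"),
    prototype(cpgIds = character(), beta = numeric(),
              intercept = 0, lambdaL1 = 0, lambdaL2 = 0,
              provenance = list()))

setValidity("ClockModel", function(object) {
    msg <- character()
    if (length(object@beta) != length(object@cpgIds))
        msg <- c(msg, "beta must align with cpgIds")
    if (length(object@intercept) != 1L)
        msg <- c(msg, "intercept must be a single number")
    if (object@lambdaL1 < 0 || object@lambdaL2 < 0)
        msg <- c(msg, "penalties must be non-negative")
    if (length(msg)) msg else TRUE
})

#' EvaluationReport: clock accuracy summary
#'
#' Accuracy of a CpG panel over repeated train/test splits: mean and
#' standard deviation of the coefficient of determination (R squared), and
#' mean / median absolute prediction error in years. Per-split metrics are
#' retained in \code{perSplit}.
#'
#' @slot meanR2,r2Sd mean and SD of R squared across splits (NA when the
#'   test-set age variance is zero).
#' @slot maeYears,medianAeYears mean and median absolute error (years).
#' @slot perSplit data.frame with one row per split (r2, mae, medianAe).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(meanR2 = "numeric", r2Sd = "numeric",
                   maeYears = "numeric", medianAeYears = "numeric",
                   perSplit = "data.frame"),
    prototype(meanR2 = NA_real_, r2Sd = NA_real_,
              maeYears = NA_real_, medianAeYears = NA_real_,
              perSplit = data.frame()))

#' SyntheticSpec: parameters of the synthetic methylation generator
#'
#' @slot nSamples,nCpgs,nInformative dataset dimensions; the first
#'   \code{nInformative} CpGs carry a planted age signal.
#' @slot effectSizes slope of mean methylation per year of age for each
#'   informative CpG (beta units / year); recycled to length
#'   \code{nInformative}.
#' @slot noiseSd standard deviation of additive Gaussian beta noise.
#' @slot ageRange (min, max) of the uniform age distribution, years.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nSamples = "integer", nCpgs = "integer",
                   nInformative = "integer", effectSizes = "numeric",
                   noiseSd = "numeric", ageRange = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
    if (object@nCpgs < 1L) msg <- c(msg, "nCpgs must be positive")
    if (object@nInformative < 0L || object@nInformative > object@nCpgs)
        msg <- c(msg, "nInformative must lie in [0, nCpgs]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (length(object@ageRange) != 2L ||
        object@ageRange[1] >= object@ageRange[2])
        msg <- c(msg, "ageRange must be (min, max) with min < max")
    if (object@nInformative > 0L &&
        length(object@effectSizes) != object@nInformative)
        msg <- c(msg, "effectSizes must have length nInformative")
    if (length(msg)) msg else TRUE
})

#' SelectionRecord: one selector run on one CV training fold
#'
#' @slot methodName name of the selector configuration.
#' @slot foldIndex integer fold index (1-based).
#' @slot selected the \linkS4class{FeatureSet} chosen on that fold's
#'   training samples.
#' @exportClass SelectionRecord
setClass("SelectionRecord",
    representation(methodName = "character", foldIndex = "integer",
                   selected = "FeatureSet"))

## ---- selector classes -----------------------------------------------------

#' Virtual parent of all CpG selectors
#'
#' Every selector implements the generic
#' \code{selectFeatures(selector, m)} returning a
#' \linkS4class{FeatureSet}, which is what makes selectors freely
#' chainable and usable inside the cross-validated workflow.
#'
#' @exportClass CpgSelector
setClass("CpgSelector", representation("VIRTUAL"))

#' @describeIn CpgSelector univariate ranking by absolute Pearson
#'   correlation with age; keeps the top \code{k}.
#' @exportClass KBestSelector
setClass("KBestSelector", contains = "CpgSelector",
    representation(k = "integer"))

#' @describeIn CpgSelector drops CpGs whose population variance does not
#'   exceed \code{threshold}.
#' @exportClass VarianceSelector
setClass("VarianceSelector", contains = "CpgSelector",
    representation(threshold = "numeric"))

#' @describeIn CpgSelector model-threshold selection: fits a
#'   penalized-linear or tree-ensemble estimator once and keeps CpGs whose
#'   importance is at least \code{threshold}.
#' @exportClass SfmSelector
setClass("SfmSelector", contains = "CpgSelector",
    representation(estimator = "character", threshold = "numeric",
                   nTrees = "integer", seed = "integer"))

#' @describeIn CpgSelector percentage-based recursive feature elimination
#'   down to \code{targetN} features.
#' @exportClass PctRfeSelector
setClass("PctRfeSelector", contains = "CpgSelector",
    representation(targetN = "integer", pct = "numeric",
                   estimator = "character", nTrees = "integer",
                   seed = "integer"))

#' @describeIn CpgSelector shadow-feature (Boruta-style) all-relevant
#'   selection under a random-forest regressor.
#' @exportClass BorutaSelector
setClass("BorutaSelector", contains = "CpgSelector",
    representation(nTrees = "integer", nIterations = "integer",
                   alpha = "numeric", compare = "character",
                   seed = "integer"))

#' @describeIn CpgSelector genetic-algorithm search over fixed-size
#'   feature subsets.
#' @exportClass GaSelector
setClass("GaSelector", contains = "CpgSelector",
    representation(populationSize = "integer", subsetSize = "integer",
                   cullFraction = "numeric",
                   mutationFeatureFraction = "numeric",
                   mutationProbability = "numeric",
                   generations = "integer",
                   validationFraction = "numeric",
                   polygamy = "logical", litterScaling = "logical",
                   fitnessThreshold = "numeric_OR_NULL",
                   seed = "integer"))

#' @describeIn CpgSelector neural-network perturbation ranking of a
#'   pre-reduced feature space.
#' @exportClass NnSelector
setClass("NnSelector", contains = "CpgSelector",
    representation(topN = "integer", prefilterTarget = "integer",
                   hidden = "integer", epochs = "integer",
                   decay = "numeric", validationFraction = "numeric",
                   strict = "logical", seed = "integer"))

#' @describeIn CpgSelector ordered chain of selectors; each stage sees
#'   only the features its predecessor kept.
#' @exportClass ChainSelector
setClass("ChainSelector", contains = "CpgSelector",
    representation(stages = "list", label = "character"))

#' @describeIn CpgSelector wraps an arbitrary
#'   \code{function(m) -> FeatureSet}; mainly for testing and
#'   prototyping custom selectors.
#' @exportClass FunctionSelector
setClass("FunctionSelector", contains = "CpgSelector",
    representation(fn = "function", label = "character"))
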