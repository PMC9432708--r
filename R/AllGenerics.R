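#' @rdname MethylationExperiment
#' @param x,object a \linkS4class{MethylationExperiment} (or, for
#'   \code{featureIds}/\code{featureScores}, a \linkS4class{FeatureSet}).
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname MethylationExperiment
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname MethylationExperiment
#' @export
setGeneric("cpgIds", function(x) standardGeneric("cpgIds"))

#' @rdname MethylationExperiment
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname featureSet
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname featureSet
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname featureSet
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Run a selector on a methylation matrix
#'
#' The uniform contract shared by every selector: given a complete
#' (no missing betas) \linkS4class{MethylationExperiment}, return a
#' \linkS4class{FeatureSet}. Chains, the cross-validated workflow and the
#' command-line runner all drive selectors exclusively through this
#' generic.
#'
#' @param selector a \linkS4class{CpgSelector}.
#' @param m a \linkS4class{MethylationExperiment}.
#' @param ... passed to methods.
#' @return a \linkS4class{FeatureSet}.
#' @export
setGeneric("selectFeatures",
    function(selector, m, ...) standardGeneric("selectFeatures"))

#' @rdname predictAge
#' @export
setGeneric("predictAge", function(clock, m) standardGeneric("predictAge"))

#' @rdname nonzeroFeatures
#' @export
setGeneric("nonzeroFeatures", function(clock) standardGeneric("nonzeroFeatures"))

#' @rdname externalValidate
#' @export
setGeneric("externalValidate",
    function(clock, mExternal) standardGeneric("externalValidate"))
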