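#' Create and inspect FeatureSets
#'
#' A \linkS4class{FeatureSet} is the common currency of the package: an
#' ordered, duplicate-free list of CpG identifiers with optional aligned
#' importance scores and a provenance string naming the method that
#' produced it.
#'
#' @param cpgIds character vector of unique CpG identifiers, rank order
#'   preserved.
#' @param scores optional numeric importances aligned with \code{cpgIds}.
#' @param provenance character(1) descriptor of the producing method.
#' @param x a \linkS4class{FeatureSet}.
#' @return \code{featureSet()} returns a \linkS4class{FeatureSet};
#'   \code{featureIds()} its identifiers; \code{featureScores()} its
#'   scores (or \code{NULL}); \code{provenance()} its descriptor.
#' @examples
#' fs <- featureSet(c("cg16867657", "cg10501210"), scores = c(0.9, 0.8),
#'                  provenance = "kbest(k=2)")
#' featureIds(fs)
#' length(fs)
#' @name featureSet
NULL

#' @rdname featureSet
#' @export
featureSet <- function(cpgIds, scores = NULL, provenance = "") {
    new("FeatureSet", cpgIds = as.character(cpgIds),
        scores = if (is.null(scores)) NULL else as.numeric(scores),
        provenance = provenance)
}

#' @rdname featureSet
#' @export
setMethod("featureIds", "FeatureSet", function(x) x@cpgIds)

#' @rdname featureSet
#' @export
setMethod("featureScores", "FeatureSet", function(x) {
    if (is.null(x@scores)) NULL
    else stats::setNames(x@scores, x@cpgIds)
})

#' @rdname featureSet
#' @export
setMethod("provenance", "FeatureSet", function(x) x@provenance)

#' @rdname featureSet
#' @export
setMethod("length", "FeatureSet", function(x) length(x@cpgIds))

setMethod("show", "FeatureSet", function(object) {
    cat("FeatureSet of", length(object@cpgIds), "CpG sites",
        if (nzchar(object@provenance))
            paste0("[", object@provenance, "]") else "", "\n")
    shown <- utils::head(object@cpgIds, 6)
    cat(" ", paste(shown, collapse = ", "),
        if (length(object@cpgIds) > 6) "..." else "", "\n")
})

#' @describeIn featureSet coerce to a data.frame of (cpg_id, score).
#' @param row.names,optional,... ignored; present for the S3 generic.
#' @export
as.data.frame.FeatureSet <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
    data.frame(cpg_id = x@cpgIds,
               score = if (is.null(x@scores)) NA_real_ else x@scores,
               stringsAsFactors = FALSE)
}
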