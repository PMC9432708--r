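#' Construct a MethylationExperiment
#'
#' Builds the package's central container from a samples-by-CpGs matrix of
#' beta values and a vector of chronological ages. Internally the betas
#' are stored CpGs-by-samples as the \code{"betas"} assay of a
#' \linkS4class{SummarizedExperiment}; \code{betas()} hands back the
#' samples-by-CpGs orientation.
#'
#' @param betas numeric matrix, samples in rows and CpG sites in columns,
#'   values in [0, 1] with \code{NA} marking missing entries. Row and
#'   column names supply sample and CpG identifiers unless given
#'   explicitly.
#' @param ages numeric vector of chronological ages (years), one per
#'   sample, non-negative.
#' @param sampleIds,cpgIds optional identifier vectors overriding the
#'   dimnames of \code{betas}.
#' @return a \linkS4class{MethylationExperiment}.
#' @examples
#' b <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("cg01", "cg02")))
#' me <- MethylationExperiment(b, ages = c(25, 50, 75))
#' ages(me)
#' dim(betas(me))
#' @export
MethylationExperiment <- function(betas, ages,
                                  sampleIds = rownames(betas),
                                  cpgIds = colnames(betas)) {
    betas <- as.matrix(betas)
    if (is.null(sampleIds))
        sampleIds <- paste0("sample_", seq_len(nrow(betas)))
    if (is.null(cpgIds))
        cpgIds <- paste0("cg_", seq_len(ncol(betas)))
    if (length(ages) != nrow(betas))
        stop("ages must have one entry per sample (", nrow(betas),
             " samples, ", length(ages), " ages)", call. = FALSE)
    storage.mode(betas) <- "double"
    assay <- t(betas)
    dimnames(assay) <- list(as.character(cpgIds), as.character(sampleIds))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(betas = assay),
        colData = S4Vectors::DataFrame(age = as.numeric(ages),
                                       row.names = as.character(sampleIds)))
    new("MethylationExperiment", se)
}

#' @rdname MethylationExperiment
#' @export
setMethod("betas", "MethylationExperiment", function(x) designMatrix(x))

#' @rdname MethylationExperiment
#' @export
setMethod("ages", "MethylationExperiment", function(x) {
    a <- SummarizedExperiment::colData(x)$age
    names(a) <- colnames(x)
    a
})

#' @rdname MethylationExperiment
#' @export
setMethod("cpgIds", "MethylationExperiment", function(x) rownames(x))

#' @rdname MethylationExperiment
#' @export
setMethod("sampleIds", "MethylationExperiment", function(x) colnames(x))

setMethod("show", "MethylationExperiment", function(object) {
    a <- SummarizedExperiment::colData(object)$age
    cat("MethylationExperiment:", ncol(object), "samples x",
        nrow(object), "CpG sites\n")
    nMiss <- sum(is.na(SummarizedExperiment::assay(object, "betas")))
    cat("  ages:",
        if (all(is.na(a))) "all missing"
        else sprintf("%.1f-%.1f years", min(a, na.rm = TRUE),
                     max(a, na.rm = TRUE)),
        "| missing betas:", nMiss, "\n")
})

#' Restrict a MethylationExperiment to a set of CpG sites
#'
#' Subsets the container to the given CpGs, in the given order. All
#' samples are kept.
#'
#' @param m a \linkS4class{MethylationExperiment}.
#' @param features a character vector of CpG identifiers or a
#'   \linkS4class{FeatureSet}.
#' @return a \linkS4class{MethylationExperiment} whose CpG set equals
#'   \code{features}.
#' @export
restrictFeatures <- function(m, features) {
    ids <- if (is(features, "FeatureSet")) featureIds(features)
           else as.character(features)
    missing <- setdiff(ids, cpgIds(m))
    if (length(missing))
        stop("CpG sites absent from the matrix: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)",
                                              length(missing) - 5) else "",
             call. = FALSE)
    m[ids, ]
}
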