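## Reading/writing methylation tables in the style of GEO series-matrix
## exports, plus the common-complete-CpG filter applied before any
## cross-dataset comparison.

.MISSING_TOKENS <- c("", "NA", "NaN", "na", "nan", "NULL")

.parseNumericCells <- function(chr, rowLabels, colLabels, what) {
    x <- suppressWarnings(as.numeric(chr))
    miss <- chr %in% .MISSING_TOKENS | is.na(chr)
    bad <- which(is.na(x) & !miss)
    if (length(bad)) {
        i <- bad[1]
        stop("cannot parse ", what, " value '", chr[i], "' at row '",
             rowLabels[(i - 1) %% length(rowLabels) + 1], "', column '",
             colLabels[(i - 1) %/% length(rowLabels) + 1], "'",
             call. = FALSE)
    }
    x[miss] <- NA_real_
    x
}

.validateBetaRange <- function(b) {
    bad <- which(!is.na(b) & (b < 0 | b > 1))
    if (length(bad)) {
        i <- bad[1]
        stop("beta value out of [0, 1]: ", b[i], " for CpG '",
             colnames(b)[(i - 1) %/% nrow(b) + 1], "', sample '",
             rownames(b)[(i - 1) %% nrow(b) + 1], "'", call. = FALSE)
    }
    invisible(b)
}

.readDelimited <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    ## fread silently mangles duplicate header names, which would turn a
    ## duplicated CpG/sample label into two distinct columns; check the
    ## raw header first
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
    fields <- strsplit(hdr, sep, fixed = TRUE)[[1]]
    if (anyDuplicated(fields))
        stop("duplicate column label(s) in header: ",
             paste(unique(fields[duplicated(fields)])[1], collapse = ", "),
             call. = FALSE)
    dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                            na.strings = NULL, data.table = FALSE)
    if (nrow(dt) == 0L || ncol(dt) < 2L)
        stop("table at ", path, " is empty or has fewer than 2 columns",
             call. = FALSE)
    dt
}

.tableToExperiment <- function(dt, layout, ageField, requireAges, path) {
    layout <- match.arg(layout, c("samples-in-rows", "cpgs-in-rows"))
    if (layout == "samples-in-rows") {
        sampleIds <- dt[[1]]
        body <- dt[, -1, drop = FALSE]
        if (requireAges && !ageField %in% colnames(body))
            stop("age column '", ageField, "' not found in ", path,
                 call. = FALSE)
        hasAges <- ageField %in% colnames(body)
        agesChr <- if (hasAges) body[[ageField]] else NULL
        body <- body[, setdiff(colnames(body), ageField), drop = FALSE]
        cpgs <- colnames(body)
        b <- matrix(NA_real_, nrow(body), ncol(body),
                    dimnames = list(sampleIds, cpgs))
        for (j in seq_along(cpgs))
            b[, j] <- .parseNumericCells(body[[j]], sampleIds, cpgs[j],
                                         "beta")
        agesNum <- if (hasAges)
            .parseNumericCells(agesChr, sampleIds, ageField, "age")
            else rep(NA_real_, length(sampleIds))
    } else {
        cpgsAll <- dt[[1]]
        sampleIds <- colnames(dt)[-1]
        isAge <- cpgsAll == ageField
        if (requireAges && !any(isAge))
            stop("age row '", ageField, "' not found in ", path,
                 call. = FALSE)
        agesNum <- if (any(isAge)) {
            .parseNumericCells(unlist(dt[which(isAge)[1], -1],
                                      use.names = FALSE),
                               ageField, sampleIds, "age")
        } else rep(NA_real_, length(sampleIds))
        body <- dt[!isAge, , drop = FALSE]
        cpgs <- body[[1]]
        b <- matrix(NA_real_, length(sampleIds), length(cpgs),
                    dimnames = list(sampleIds, cpgs))
        for (i in seq_along(cpgs))
            b[, i] <- .parseNumericCells(unlist(body[i, -1],
                                                use.names = FALSE),
                                         cpgs[i], sampleIds, "beta")
    }
    if (anyDuplicated(cpgs))
        stop("duplicate CpG label(s): ",
             paste(unique(cpgs[duplicated(cpgs)])[1:min(3, sum(duplicated(cpgs)))],
                   collapse = ", "), call. = FALSE)
    if (anyDuplicated(sampleIds))
        stop("duplicate sample label(s): ",
             paste(unique(sampleIds[duplicated(sampleIds)])[1], collapse = ", "),
             call. = FALSE)
    .validateBetaRange(b)
    if (requireAges && anyNA(agesNum))
        stop("missing age value(s) in ", path, call. = FALSE)
    MethylationExperiment(b, ages = agesNum)
}

#' Read a methylation beta-value table with sample ages
#'
#' Reads a delimited (TSV/CSV, autodetected) table of beta values plus a
#' chronological-age field into a \linkS4class{MethylationExperiment}.
#' Two layouts are supported and must be named explicitly — the reader
#' never guesses orientation, because a silently transposed methylation
#' matrix is a classic analysis bug:
#' \describe{
#'   \item{\code{"samples-in-rows"}}{first column holds sample
#'     identifiers, remaining columns are CpG sites, and one column
#'     (named by \code{ageField}) holds ages.}
#'   \item{\code{"cpgs-in-rows"}}{GEO series-matrix style: first column
#'     holds CpG identifiers, remaining columns are samples, and one row
#'     (whose identifier equals \code{ageField}) holds ages.}
#' }
#' Empty cells and the tokens \code{NA}/\code{NaN}/\code{NULL} are read
#' as missing. Betas outside [0, 1], unparseable cells, and duplicate
#' CpG or sample labels are rejected with errors naming the offending
#' row/column.
#'
#' @param path path to the delimited file.
#' @param layout \code{"samples-in-rows"} or \code{"cpgs-in-rows"}.
#' @param ageField label of the age column (or row), default
#'   \code{"age"}.
#' @return a \linkS4class{MethylationExperiment} with ages set.
#' @seealso [loadPredictionMatrix()] for unlabeled matrices,
#'   [saveMethylationTable()] for the inverse operation.
#' @export
loadMethylationTable <- function(path,
                                 layout = c("samples-in-rows",
                                            "cpgs-in-rows"),
                                 ageField = "age") {
    layout <- match.arg(layout)
    dt <- .readDelimited(path)
    .tableToExperiment(dt, layout, ageField, requireAges = TRUE, path)
}

#' Read a methylation table without ages (prediction only)
#'
#' Same formats as [loadMethylationTable()] but the age field is
#' optional; absent ages are recorded as \code{NA}. Matrices loaded this
#' way can be fed to [predictAge()] but not to the supervised selectors.
#'
#' @inheritParams loadMethylationTable
#' @return a \linkS4class{MethylationExperiment}, possibly with
#'   \code{NA} ages.
#' @export
loadPredictionMatrix <- function(path,
                                 layout = c("samples-in-rows",
                                            "cpgs-in-rows"),
                                 ageField = "age") {
    layout <- match.arg(layout)
    dt <- .readDelimited(path)
    .tableToExperiment(dt, layout, ageField, requireAges = FALSE, path)
}

#' Write a methylation table
#'
#' Inverse of [loadMethylationTable()]: writes the betas and ages of a
#' \linkS4class{MethylationExperiment} as a delimited text table in
#' either layout. Round-trips are cell-exact (missing betas are written
#' as \code{NA}).
#'
#' @param m a \linkS4class{MethylationExperiment}.
#' @param path output file path.
#' @param layout orientation, as in [loadMethylationTable()].
#' @param ageField label under which ages are written.
#' @param sep field separator, default tab.
#' @return \code{path}, invisibly.
#' @export
saveMethylationTable <- function(m, path,
                                 layout = c("samples-in-rows",
                                            "cpgs-in-rows"),
                                 ageField = "age", sep = "\t") {
    layout <- match.arg(layout)
    b <- betas(m)
    a <- ages(m)
    if (ageField %in% cpgIds(m))
        stop("age field '", ageField, "' collides with a CpG id",
             call. = FALSE)
    if (layout == "samples-in-rows") {
        df <- data.frame(sample_id = sampleIds(m), age = unname(a),
                         b, check.names = FALSE,
                         stringsAsFactors = FALSE)
        colnames(df)[2] <- ageField
    } else {
        body <- t(b)
        df <- data.frame(ID_REF = c(ageField, rownames(body)),
                         rbind(matrix(unname(a), nrow = 1), body),
                         check.names = FALSE, stringsAsFactors = FALSE)
        colnames(df)[-1] <- sampleIds(m)
    }
    data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
    invisible(path)
}

#' Restrict matrices to their common complete CpG set
#'
#' Implements the pre-analysis filter applied when several datasets (or a
#' dataset and a published clock) must be compared fairly: a CpG site is
#' kept only if it is present, with no missing beta values, in every
#' input matrix. Sample sets are untouched. The retained CpG order is
#' that of the first matrix, so the operation is deterministic and
#' commutative in content (the retained \emph{set} does not depend on
#' argument order).
#'
#' @param ... one or more \linkS4class{MethylationExperiment}s, or a
#'   single list of them.
#' @return if one matrix was supplied, the filtered matrix; otherwise a
#'   list of filtered matrices in input order.
#' @examples
#' b1 <- matrix(runif(12), 3, 4,
#'              dimnames = list(paste0("s", 1:3), paste0("cg", 1:4)))
#' b2 <- b1; b2[2, "cg3"] <- NA
#' m1 <- MethylationExperiment(b1, c(30, 40, 50))
#' m2 <- MethylationExperiment(b2, c(30, 40, 50))
#' filtered <- dropIncompleteCpgs(m1, m2)
#' cpgIds(filtered[[1]])  # cg3 dropped from both
#' @export
dropIncompleteCpgs <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1]]) &&
        !is(args[[1]], "MethylationExperiment"))
        args <- args[[1]]
    if (!length(args))
        stop("at least one matrix is required", call. = FALSE)
    if (!all(vapply(args, is, logical(1), "MethylationExperiment")))
        stop("all inputs must be MethylationExperiment objects",
             call. = FALSE)
    completeSets <- lapply(args, function(m) {
        b <- SummarizedExperiment::assay(m, "betas")
        rownames(b)[rowSums(is.na(b)) == 0L]
    })
    keep <- Reduce(intersect, completeSets)
    keep <- cpgIds(args[[1]])[cpgIds(args[[1]]) %in% keep]
    if (!length(keep))
        stop("no CpG site is complete across all matrices ",
             "(empty feature space)", call. = FALSE)
    out <- lapply(args, restrictFeatures, features = keep)
    if (length(out) == 1L) out[[1]] else out
}

#' Read a CpG-to-gene annotation table
#'
#' Reads a two-column delimited table (cpg_id, gene_symbol) into a named
#' character vector. A CpG appearing twice with conflicting symbols is an
#' error; exact duplicate rows are collapsed.
#'
#' @param path path to the delimited file (header required).
#' @return named character vector mapping CpG id to gene symbol.
#' @export
loadAnnotationTable <- function(path) {
    dt <- .readDelimited(path)
    if (ncol(dt) < 2L)
        stop("annotation table needs two columns (cpg_id, gene_symbol)",
             call. = FALSE)
    dt <- unique(dt[, 1:2])
    if (anyDuplicated(dt[[1]]))
        stop("conflicting gene symbols for CpG(s): ",
             paste(unique(dt[[1]][duplicated(dt[[1]])]), collapse = ", "),
             call. = FALSE)
    stats::setNames(as.character(dt[[2]]), dt[[1]])
}

#' Attach gene symbols to a FeatureSet
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param annotation named character vector from
#'   [loadAnnotationTable()] (or built in code).
#' @return data.frame with columns \code{cpg_id} and \code{gene_symbol}
#'   (empty string where no annotation exists), one row per feature, in
#'   feature order.
#' @examples
#' ann <- c(cg16867657 = "ELOVL2")
#' annotateFeatures(featureSet(c("cg16867657", "cg9999999")), ann)
#' @export
annotateFeatures <- function(fs, annotation) {
    ids <- featureIds(fs)
    gene <- unname(annotation[ids])
    gene[is.na(gene)] <- ""
    data.frame(cpg_id = ids, gene_symbol = gene,
               stringsAsFactors = FALSE)
}
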