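#' Chain selectors into a composite
#'
#' Composes selectors left to right: the matrix is restricted to stage
#' \code{i}'s output before stage \code{i+1} runs, and the composite's
#' output is the last stage's output. Chaining a cheap reducer into an
#' expensive all-relevant method (e.g. \code{chainSelectors(kbest =
#' kBestSelector(2000), boruta = borutaSelector())}) is the toolkit's
#' flagship construction. A stage returning an empty set aborts with an
#' error identifying the stage.
#'
#' @param ... selectors (\linkS4class{CpgSelector} objects), optionally
#'   named; or a single list of them.
#' @param label optional composite name used in provenance.
#' @return a \linkS4class{ChainSelector}.
#' @export
chainSelectors <- function(..., label = NULL) {
    stages <- list(...)
    if (length(stages) == 1L && is.list(stages[[1]]) &&
        !is(stages[[1]], "CpgSelector"))
        stages <- stages[[1]]
    if (!length(stages))
        stop("at least one stage is required", call. = FALSE)
    if (!all(vapply(stages, is, logical(1), "CpgSelector")))
        stop("all stages must be CpgSelector objects", call. = FALSE)
    if (is.null(names(stages)))
        names(stages) <- paste0("stage", seq_along(stages))
    new("ChainSelector", stages = stages,
        label = label %||% paste(names(stages), collapse = " > "))
}

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "ChainSelector",
    function(selector, m, ...) {
        current <- m
        fs <- NULL
        for (i in seq_along(selector@stages)) {
            fs <- selectFeatures(selector@stages[[i]], current)
            if (!length(fs))
                stop("chain stage ", i, " ('",
                     names(selector@stages)[i],
                     "') returned an empty feature set", call. = FALSE)
            current <- restrictFeatures(current, fs)
        }
        featureSet(featureIds(fs), scores = fs@scores,
                   provenance = paste0(selector@label, ": ",
                                       provenance(fs)))
    })

#' Per-fold feature selection under cross-validation
#'
#' Splits the samples into \code{folds} seed-deterministic folds and
#' runs every named selector on each fold's \emph{training} portion
#' only — held-out samples are never visible to a selector, so the
#' downstream evaluation is leakage-free. A selector failing on a fold
#' is recorded and skipped with a warning; the run continues.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param methods named list of \linkS4class{CpgSelector} objects.
#' @param folds number of folds, default 10.
#' @param seed integer seed pinning the fold assignment.
#' @return list of \linkS4class{SelectionRecord} objects, one per
#'   (method, fold) pair that succeeded; failures are summarised in the
#'   \code{"failures"} attribute.
#' @export
runCvSelection <- function(m, methods, folds = 10L, seed = 1L) {
    stopIfMissingBetas(m, "runCvSelection")
    folds <- as.integer(folds)
    n <- ncol(m)
    if (folds < 2L)
        stop("folds must be at least 2", call. = FALSE)
    if (n < folds)
        stop("need at least as many samples as folds", call. = FALSE)
    if (is.null(names(methods)) || any(!nzchar(names(methods))))
        stop("methods must be a named list", call. = FALSE)
    foldId <- withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
    records <- list()
    failures <- character()
    for (f in seq_len(folds)) {
        mTrain <- m[, foldId != f]
        for (nm in names(methods)) {
            fs <- tryCatch(selectFeatures(methods[[nm]], mTrain),
                           error = function(e) e)
            if (inherits(fs, "error")) {
                failures <- c(failures,
                              sprintf("%s/fold%d: %s", nm, f,
                                      conditionMessage(fs)))
                next
            }
            records[[length(records) + 1L]] <-
                new("SelectionRecord", methodName = nm,
                    foldIndex = f, selected = fs)
        }
    }
    if (length(failures))
        warning("selector failures (excluded from aggregation): ",
                paste(failures, collapse = "; "), call. = FALSE)
    attr(records, "failures") <- failures
    attr(records, "foldId") <- foldId
    records
}

.recordsByMethod <- function(records)
    split(records, vapply(records, function(r) r@methodName,
                          character(1)))

#' Build and inspect SelectionRecords
#'
#' A \linkS4class{SelectionRecord} ties a selector name and a CV fold
#' index to the \linkS4class{FeatureSet} chosen on that fold's training
#' samples. [runCvSelection()] produces them; these helpers construct
#' (for tests and custom drivers) and inspect them.
#'
#' @param methodName selector name.
#' @param foldIndex 1-based fold index.
#' @param selected a \linkS4class{FeatureSet} (or character vector of
#'   CpG ids).
#' @param record a \linkS4class{SelectionRecord}.
#' @return \code{selectionRecord()} a record; the accessors its
#'   components.
#' @export
selectionRecord <- function(methodName, foldIndex, selected) {
    if (!is(selected, "FeatureSet"))
        selected <- featureSet(selected)
    new("SelectionRecord", methodName = methodName,
        foldIndex = as.integer(foldIndex), selected = selected)
}

#' @rdname selectionRecord
#' @export
recordMethod <- function(record) record@methodName

#' @rdname selectionRecord
#' @export
recordFold <- function(record) record@foldIndex

#' @rdname selectionRecord
#' @export
recordFeatures <- function(record) record@selected

#' Aggregate unique features per method across folds
#'
#' For each method, the union of the CpGs it selected over all folds,
#' deduplicated in first-appearance order (fold order, then rank order
#' within a fold) — the per-method columns of the workflow's results
#' table.
#'
#' @param records list of \linkS4class{SelectionRecord}s from
#'   [runCvSelection()].
#' @return named list mapping method name to a
#'   \linkS4class{FeatureSet} of its unique features.
#' @export
aggregateUnique <- function(records) {
    byMethod <- .recordsByMethod(records)
    out <- lapply(names(byMethod), function(nm) {
        rs <- byMethod[[nm]]
        rs <- rs[order(vapply(rs, function(r) r@foldIndex, integer(1)))]
        ids <- unique(unlist(lapply(rs, function(r)
            featureIds(r@selected)), use.names = FALSE))
        featureSet(ids, provenance = sprintf("aggregate_unique(%s)", nm))
    })
    names(out) <- names(byMethod)
    out
}

#' Intersect methods within each fold, then refine with shadow features
#'
#' For every fold, intersects all methods' selections; unions the
#' per-fold intersections across folds; and refines that candidate set
#' by running [borutaSelect()] on it. Captures CpGs that every method
#' agrees on in at least one fold, then keeps only those that survive
#' shadow competition.
#'
#' @param records list of \linkS4class{SelectionRecord}s covering every
#'   method in every fold.
#' @param m the \linkS4class{MethylationExperiment} the records were
#'   computed from (needed for the refinement fit).
#' @param nTrees,nIterations,alpha,compare,seed parameters of the
#'   refining [borutaSelect()] run.
#' @return the refined \linkS4class{FeatureSet}.
#' @export
intersectPerFoldThenRefine <- function(records, m, nTrees = 100L,
                                       nIterations = 100L, alpha = 0.05,
                                       compare = "max", seed = 1L) {
    foldIdx <- vapply(records, function(r) r@foldIndex, integer(1))
    methodsAll <- unique(vapply(records, function(r) r@methodName,
                                character(1)))
    byFold <- split(records, foldIdx)
    perFold <- lapply(byFold, function(rs) {
        present <- vapply(rs, function(r) r@methodName, character(1))
        if (!all(methodsAll %in% present))
            stop("every method must be present in every fold",
                 call. = FALSE)
        Reduce(intersect, lapply(rs, function(r) featureIds(r@selected)))
    })
    candidate <- unique(unlist(perFold, use.names = FALSE))
    if (!length(candidate))
        stop("per-fold intersections are all empty ",
             "(no CpG shared by every method)", call. = FALSE)
    borutaSelect(restrictFeatures(m, sort(candidate)), nTrees = nTrees,
                 nIterations = nIterations, alpha = alpha,
                 compare = compare, seed = seed)
}

#' Most frequently selected features
#'
#' Counts, over all (method, fold) records, how many records each CpG
#' appears in, and returns the \code{n} most frequent (ties broken by
#' lexicographic CpG id). With \code{perMethod = TRUE} a CpG is counted
#' at most once per method instead.
#'
#' @param records list of \linkS4class{SelectionRecord}s.
#' @param n number of features to return.
#' @param perMethod count each CpG once per method rather than once per
#'   record; default \code{FALSE}.
#' @return a \linkS4class{FeatureSet} with \code{scores} = counts.
#' @export
topFrequent <- function(records, n, perMethod = FALSE) {
    n <- as.integer(n)
    if (n < 1L)
        stop("n must be positive", call. = FALSE)
    idLists <- lapply(records, function(r) featureIds(r@selected))
    if (perMethod) {
        nm <- vapply(records, function(r) r@methodName, character(1))
        idLists <- lapply(split(idLists, nm), function(l)
            unique(unlist(l, use.names = FALSE)))
    }
    counts <- table(unlist(idLists, use.names = FALSE))
    if (length(counts) < n)
        stop("only ", length(counts), " distinct features were ever ",
             "selected; cannot return top ", n, call. = FALSE)
    cnt <- as.numeric(counts)
    ids <- names(counts)
    ord <- scoreOrder(cnt, ids)[seq_len(n)]
    featureSet(ids[ord], scores = cnt[ord],
               provenance = sprintf("top_frequent(n=%d)", n))
}

#' Intersection of all methods' aggregated selections
#'
#' Intersects the per-method unique feature sets of
#' [aggregateUnique()]. An empty intersection is a legitimate result and
#' is returned (not an error).
#'
#' @param table named list of \linkS4class{FeatureSet}s (at least 2
#'   methods).
#' @return a \linkS4class{FeatureSet}, sorted lexicographically.
#' @export
postSelectionIntersection <- function(table) {
    if (length(table) < 2L)
        stop("at least two methods are required", call. = FALSE)
    common <- Reduce(intersect, lapply(table, featureIds))
    featureSet(sort(common),
               provenance = "post_selection_intersection")
}

#' Evaluate a CpG panel with repeated train/test clocks
#'
#' Measures how well a feature set supports age prediction: for each of
#' \code{repeats} seeded splits, the matrix is restricted to the panel,
#' an elastic-net clock is fitted on the training part
#' ([fitClock()], internally tuned), and R squared plus absolute errors
#' are scored on the held-out part. The default protocol is repeated
#' 80/20 splits; \code{mode = "kfold"} instead partitions the samples
#' into \code{repeats} folds (90/10 at the default 10) and holds each
#' out once.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param fs a non-empty \linkS4class{FeatureSet} or character vector,
#'   all present in \code{m}.
#' @param repeats number of splits, default 10.
#' @param testFraction held-out fraction for \code{mode = "split"},
#'   default 0.2.
#' @param seed integer seed; split \code{i} uses a seed derived from it.
#' @param mode \code{"split"} (repeated 80/20) or \code{"kfold"}.
#' @return an \linkS4class{EvaluationReport}: mean and SD of R squared,
#'   mean and median absolute error (years), per-split metrics in
#'   \code{perSplit}.
#' @export
evaluateFeatureSet <- function(m, fs, repeats = 10L, testFraction = 0.2,
                               seed = 1L, mode = c("split", "kfold")) {
    mode <- match.arg(mode)
    ids <- if (is(fs, "FeatureSet")) featureIds(fs)
           else as.character(fs)
    if (!length(ids))
        stop("feature set is empty", call. = FALSE)
    mR <- restrictFeatures(m, ids)
    stopIfMissingBetas(mR, "evaluateFeatureSet")
    n <- ncol(mR)
    repeats <- as.integer(repeats)
    foldId <- if (mode == "kfold")
        withSeed(seed, sample(rep(seq_len(repeats), length.out = n)))
        else NULL
    rows <- vector("list", repeats)
    allAe <- numeric()
    for (i in seq_len(repeats)) {
        testIdx <- if (mode == "split") {
            withSeed(mixSeed(seed, i),
                sort(sample.int(n, max(1L,
                    as.integer(round(testFraction * n))))))
        } else which(foldId == i)
        trainIdx <- setdiff(seq_len(n), testIdx)
        clock <- fitClock(mR[, trainIdx], seed = mixSeed(seed, 1000L + i))
        yp <- predictAge(clock, mR[, testIdx])
        ya <- unname(ages(mR))[testIdx]
        ae <- abs(ya - unname(yp))
        allAe <- c(allAe, ae)
        rows[[i]] <- data.frame(split = i, r2 = rSquared(ya, unname(yp)),
                                mae = mean(ae),
                                medianAe = stats::median(ae))
    }
    perSplit <- do.call(rbind, rows)
    r2s <- perSplit$r2[!is.na(perSplit$r2)]
    new("EvaluationReport",
        meanR2 = if (length(r2s)) mean(r2s) else NA_real_,
        r2Sd = if (length(r2s) > 1L) stats::sd(r2s) else 0,
        maeYears = mean(allAe),
        medianAeYears = stats::median(allAe),
        perSplit = perSplit)
}

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf(paste0("EvaluationReport (%d splits): mean R2 %.3f ",
                       "(SD %.3f), MAE %.2f years, median AE %.2f ",
                       "years\n"),
                nrow(object@perSplit), object@meanR2, object@r2Sd,
                object@maeYears, object@medianAeYears))
})

#' @rdname evaluationReport
#' @param x an \linkS4class{EvaluationReport}.
#' @export
reportMetrics <- function(x) {
    c(meanR2 = x@meanR2, r2Sd = x@r2Sd, maeYears = x@maeYears,
      medianAeYears = x@medianAeYears)
}

#' EvaluationReport accessors
#'
#' \code{reportMetrics()} returns the four headline numbers (mean R
#' squared, its SD, mean and median absolute error in years);
#' \code{perSplitMetrics()} the underlying per-split data.frame.
#'
#' @name evaluationReport
NULL

#' @rdname evaluationReport
#' @export
perSplitMetrics <- function(x) x@perSplit

#' Run the full selection-and-evaluation workflow
#'
#' End-to-end pipeline: per-fold selection under cross-validation
#' ([runCvSelection()]), per-method aggregation of unique features
#' ([aggregateUnique()]), the post-selection operations (per-fold
#' intersection refined by shadow competition, all-method intersection,
#' top-frequency ranking), and evaluation of every resulting panel with
#' [evaluateFeatureSet()].
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param methods named list of selectors.
#' @param folds CV folds for the selection stage, default 10.
#' @param repeats,testFraction,mode evaluation protocol, as in
#'   [evaluateFeatureSet()].
#' @param topCounts frequency-ranking sizes, default \code{c(5, 10)}.
#' @param refine run the per-fold-intersection + shadow-refinement
#'   branch (requires every method to succeed on every fold); default
#'   \code{TRUE}.
#' @param seed integer master seed.
#' @return a list with components \code{records}, \code{aggregated}
#'   (named list of FeatureSets), \code{panels} (all evaluated panels,
#'   including \code{top5}-style entries and
#'   \code{post_selection_intersection} when non-empty), and
#'   \code{reports} (named list of \linkS4class{EvaluationReport}s).
#' @export
runWorkflow <- function(m, methods, folds = 10L, repeats = 10L,
                        testFraction = 0.2, mode = "split",
                        topCounts = c(5L, 10L), refine = TRUE,
                        seed = 1L) {
    records <- runCvSelection(m, methods, folds = folds, seed = seed)
    aggregated <- aggregateUnique(records)
    panels <- aggregated
    if (refine && !length(attr(records, "failures"))) {
        refined <- tryCatch(
            intersectPerFoldThenRefine(records, m,
                                       seed = mixSeed(seed, 31L)),
            error = function(e) NULL)
        if (!is.null(refined) && length(refined))
            panels$fold_intersection_refined <- refined
    }
    for (k in topCounts) {
        fs <- tryCatch(topFrequent(records, k), error = function(e) NULL)
        if (!is.null(fs))
            panels[[sprintf("top%d_frequent", k)]] <- fs
    }
    if (length(aggregated) >= 2L) {
        psi <- postSelectionIntersection(aggregated)
        if (length(psi))
            panels$post_selection_intersection <- psi
    }
    reports <- lapply(panels, function(fs)
        evaluateFeatureSet(m, fs, repeats = repeats,
                           testFraction = testFraction,
                           seed = mixSeed(seed, 77L), mode = mode))
    list(records = records, aggregated = aggregated, panels = panels,
         reports = reports)
}
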