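# Internal helpers shared across modules.

.cpgSieveState <- new.env(parent = emptyenv())
.cpgSieveState$nnFits <- 0L

# Evaluate expr with a locally pinned RNG stream, restoring the caller's
# .Random.seed afterwards so seeded package entry points never disturb the
# session RNG. seed = NULL means "use the ambient stream".
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
mixSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729 + 1) %%
               2147483647)
}

# samples x CpGs design view used by all estimators.
designMatrix <- function(m) {
    t(SummarizedExperiment::assay(m, "betas"))
}

stopIfMissingBetas <- function(m, what) {
    if (anyNA(SummarizedExperiment::assay(m, "betas")))
        stop(what, " requires a complete matrix (no missing betas); ",
             "run dropIncompleteCpgs() first", call. = FALSE)
    invisible(TRUE)
}

# Rank order used package-wide: larger score first, ties broken by
# lexicographic CpG identifier.
scoreOrder <- function(scores, ids) {
    order(-scores, ids, method = "radix")
}

# R squared as 1 - SS_res/SS_tot; NA when the reference has zero variance.
rSquared <- function(actual, predicted) {
    sst <- sum((actual - mean(actual))^2)
    if (sst == 0)
        return(NA_real_)
    1 - sum((actual - predicted)^2) / sst
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
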