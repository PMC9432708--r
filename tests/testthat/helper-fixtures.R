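# Fixtures and independent oracles used across the suite.

# Tiny hand-controllable matrix: explicit betas, explicit ages.
toyExperiment <- function(betas, ages) {
    if (is.null(rownames(betas)))
        rownames(betas) <- paste0("s", seq_len(nrow(betas)))
    MethylationExperiment(betas, ages = ages)
}

# The documented bench conditions: 200 samples x 1000 CpGs, 5 planted
# CpGs at +/-0.004 beta/year, noise SD 0.03, ages 20-90.
benchSpec <- function(seed) syntheticSpec(seed = seed)

# A noiseless toy with one exactly-linear planted CpG and varying
# age-independent nulls (drawn once per seed).
noiselessToy <- function(seed, n = 80, nNull = 6, slope = 0.008) {
    set.seed(seed)
    age <- runif(n, 20, 90)
    planted <- 0.5 + slope * (age - 55)
    nulls <- matrix(runif(n * nNull, 0.1, 0.9), n, nNull)
    b <- cbind(planted, nulls)
    colnames(b) <- c("cgPLANT", sprintf("cgNULL%02d", seq_len(nNull)))
    rownames(b) <- paste0("s", seq_len(n))
    list(m = MethylationExperiment(b, ages = age), planted = "cgPLANT")
}

# Independent one-feature-at-a-time RFE oracle: refits the same
# importance backend, drops the single worst feature (importance
# ascending, ties by reverse-lexicographic id, i.e. the bottom of the
# "importance desc, id asc" ranking) until `target` remain.
stepOneRfeOracle <- function(m, target,
                             estimator = "penalized-linear") {
    surviving <- sort(cpgIds(m))
    x <- betas(m)
    a <- unname(ages(m))
    while (length(surviving) > target) {
        imp <- cpgSieve:::.fitImportance(x[, surviving, drop = FALSE],
                                         a, estimator)
        ranking <- order(-imp, surviving, method = "radix")
        worst <- ranking[length(surviving)]
        surviving <- surviving[-worst]
    }
    surviving
}

# Spy selector: records a hash of the sample ids it was shown, then
# behaves like a fixed selector.
spySelector <- function(logEnv, inner = kBestSelector(2)) {
    functionSelector(function(m) {
        logEnv$seen <- c(logEnv$seen,
                         list(sort(sampleIds(m))))
        selectFeatures(inner, m)
    }, label = "spy")
}

# Hand-built selection records for the set-operation oracles.
handRecords <- function(sets) {
    recs <- list()
    for (method in names(sets))
        for (f in seq_along(sets[[method]]))
            recs[[length(recs) + 1L]] <-
                selectionRecord(method, f, sets[[method]][[f]])
    recs
}
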