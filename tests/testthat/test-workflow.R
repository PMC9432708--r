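test_that("chains restrict stage by stage and compose correctly", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 60, nCpgs = 60,
                                             nInformative = 3, seed = 41))
    m <- ds$matrix
    # single-stage chain is that selector
    single <- chainSelectors(kbest = kBestSelector(10))
    expect_identical(featureIds(selectFeatures(single, m)),
                     featureIds(selectKBest(m, 10)))
    # composite output is a subset of every stage's output
    chain <- chainSelectors(kbest = kBestSelector(20),
                            var = varianceSelector(0))
    out <- selectFeatures(chain, m)
    expect_true(all(featureIds(out) %in%
                    featureIds(selectKBest(m, 20))))
    # an empty stage aborts with the stage named
    alwaysEmpty <- functionSelector(function(m) featureSet(character()),
                                    label = "empty")
    bad <- chainSelectors(kbest = kBestSelector(5), nil = alwaysEmpty)
    expect_error(selectFeatures(bad, m), "stage 2.*'nil'.*empty")
    expect_error(chainSelectors(), "at least one stage")
})

test_that("cross-validated selection yields one record per method and fold
           and never shows a selector held-out samples", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 50, nCpgs = 30,
                                             nInformative = 2, seed = 43))
    m <- ds$matrix
    log <- new.env()
    log$seen <- list()
    methods <- list(spy = spySelector(log), kbest = kBestSelector(5))
    records <- runCvSelection(m, methods, folds = 5, seed = 17)
    expect_length(records, 10L)
    expect_setequal(vapply(records, recordMethod, character(1)),
                    c("spy", "kbest"))
    # leakage guard: reconstruct each fold's held-out samples and check
    # the spy never saw any of them
    foldId <- attr(records, "foldId")
    expect_length(log$seen, 5L)
    allIds <- sampleIds(m)
    for (f in 1:5) {
        train <- sort(allIds[foldId != f])
        expect_identical(log$seen[[f]], train)
    }
    # deterministic fold assignment
    records2 <- runCvSelection(m, list(kbest = kBestSelector(5)),
                               folds = 5, seed = 17)
    expect_identical(attr(records2, "foldId"), foldId)
    # a failing method is recorded, not fatal
    boom <- functionSelector(function(m) stop("boom"), label = "boom")
    expect_warning(
        rec3 <- runCvSelection(m, list(kbest = kBestSelector(5),
                                       boom = boom),
                               folds = 5, seed = 17),
        "boom")
    expect_length(rec3, 5L)
})

test_that("aggregation, intersections and frequency match brute-force oracles", {
    recs <- handRecords(list(
        A = list(c("a", "b"), c("b", "c"), c("a", "d")),
        B = list(c("b", "a"), c("b", "c", "e"), c("a", "b"))))
    agg <- aggregateUnique(recs)
    expect_setequal(names(agg), c("A", "B"))
    expect_identical(featureIds(agg$A), c("a", "b", "c", "d"))
    expect_identical(featureIds(agg$B), c("b", "a", "c", "e"))

    # post-selection intersection == brute-force set intersection
    psi <- postSelectionIntersection(agg)
    expect_identical(featureIds(psi),
                     sort(intersect(c("a", "b", "c", "d"),
                                    c("b", "a", "c", "e"))))
    expect_error(postSelectionIntersection(agg["A"]), "at least two")
    # empty intersection is allowed and returned
    disjoint <- list(A = featureSet("x"), B = featureSet("y"))
    expect_length(postSelectionIntersection(disjoint), 0L)

    # frequency: brute-force tally over the 6 records
    tally <- table(unlist(list(c("a", "b"), c("b", "c"), c("a", "d"),
                               c("b", "a"), c("b", "c", "e"),
                               c("a", "b"))))
    top2 <- topFrequent(recs, 2)
    expect_identical(featureIds(top2), c("b", "a"))
    expect_equal(unname(featureScores(top2)),
                 as.numeric(tally[c("b", "a")]))
    # tie-break: "a" (4) vs "b" (5); next are c (2) then d/e (1 each,
    # lexicographic)
    top5 <- topFrequent(recs, 5)
    expect_identical(featureIds(top5), c("b", "a", "c", "d", "e"))
    expect_error(topFrequent(recs, 6), "distinct")
    # per-method counting collapses within-method repeats
    pm <- topFrequent(recs, 5, perMethod = TRUE)
    expect_equal(unname(featureScores(pm)[featureIds(pm) == "b"]), 2)

    # record ordering does not matter
    expect_identical(featureIds(topFrequent(rev(recs), 2)),
                     featureIds(top2))
})

test_that("per-fold intersection + shadow refinement follows the contract", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 80, nCpgs = 40,
                                             nInformative = 3, seed = 47))
    m <- ds$matrix
    gt <- featureIds(ds$groundTruth)
    # two identical methods: per-fold intersection equals the common set
    recs <- handRecords(list(
        A = list(c(gt, "cg0000001"), gt),
        B = list(gt, c(gt, "cg0000002"))))
    refined <- intersectPerFoldThenRefine(recs, m, nIterations = 30,
                                          seed = 3)
    expect_true(all(featureIds(refined) %in% gt))
    # disjoint methods in every fold: explicit error
    recsDisjoint <- handRecords(list(A = list("cg0000001"),
                                     B = list("cg0000002")))
    expect_error(intersectPerFoldThenRefine(recsDisjoint, m),
                 "empty")
    # a method missing from one fold is an error
    recsMissing <- handRecords(list(A = list(gt, gt), B = list(gt)))
    expect_error(intersectPerFoldThenRefine(recsMissing, m),
                 "every method")
})

test_that("evaluateFeatureSet separates signal panels from noise panels", {
    # noiseless planted data, ground-truth panel: near-perfect fit
    ds <- generateClockDataset(syntheticSpec(nSamples = 80, nCpgs = 30,
                                             nInformative = 3,
                                             noiseSd = 0, seed = 53))
    rep <- evaluateFeatureSet(ds$matrix, ds$groundTruth, seed = 5)
    expect_gte(reportMetrics(rep)[["meanR2"]], 0.999)
    # pure-noise panels on no-signal data: low R2
    fits <- vapply(1:3, function(s) {
        d0 <- generateClockDataset(syntheticSpec(nSamples = 200,
                                                 nCpgs = 50,
                                                 nInformative = 0,
                                                 seed = 900 + s))
        reportMetrics(evaluateFeatureSet(
            d0$matrix, featureSet(cpgIds(d0$matrix)[1:10]),
            repeats = 5, seed = s))[["meanR2"]]
    }, numeric(1))
    expect_lte(mean(fits), 0.2)
    # report surface mirrors the mean/SD/MAE/median-AE columns
    mm <- reportMetrics(rep)
    expect_named(mm, c("meanR2", "r2Sd", "maeYears", "medianAeYears"))
    expect_gte(mm[["maeYears"]], 0)
    expect_identical(nrow(perSplitMetrics(rep)), 10L)
    # validation
    expect_error(evaluateFeatureSet(ds$matrix, featureSet(character())),
                 "empty")
    expect_error(evaluateFeatureSet(ds$matrix, featureSet("cgNOPE")),
                 "absent")
})

test_that("kfold evaluation mode partitions samples", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 50, nCpgs = 20,
                                             nInformative = 2, seed = 59))
    rep <- evaluateFeatureSet(ds$matrix, ds$groundTruth, repeats = 10,
                              seed = 7, mode = "kfold")
    expect_identical(nrow(perSplitMetrics(rep)), 10L)
    expect_false(anyNA(perSplitMetrics(rep)$r2))
})

test_that("runWorkflow produces evaluated panels end to end", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 80, nCpgs = 100,
                                             nInformative = 4, seed = 61))
    methods <- list(
        kbest = kBestSelector(15),
        chain = chainSelectors(k = kBestSelector(30),
                               b = borutaSelector(nIterations = 25,
                                                  seed = 61)))
    res <- runWorkflow(ds$matrix, methods, folds = 4, repeats = 4,
                       topCounts = 5L, seed = 61)
    expect_length(res$records, 8L)
    expect_true(all(c("kbest", "chain", "top5_frequent") %in%
                    names(res$panels)))
    expect_identical(names(res$reports), names(res$panels))
    gt <- featureIds(ds$groundTruth)
    expect_gte(sum(gt %in% featureIds(res$panels$top5_frequent)), 3L)
    best <- reportMetrics(res$reports$top5_frequent)[["meanR2"]]
    expect_gt(best, 0.8)
})
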