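test_that("unpenalized fit recovers generating coefficients exactly", {
    set.seed(71)
    n <- 40
    x <- matrix(runif(n * 3, 0.1, 0.9), n, 3,
                dimnames = list(paste0("s", 1:n), c("cgA", "cgB", "cgC")))
    trueBeta <- c(40, -25, 10)
    y <- as.numeric(30 + x %*% trueBeta)
    y <- pmax(y, 0)
    m <- MethylationExperiment(x, ages = y)
    clock <- fitClock(m, lambda1 = 0, lambda2 = 0)
    # independent closed-form oracle: ordinary least squares via lm()
    ols <- lm(y ~ x)
    expect_equal(clock@beta, unname(coef(ols)[-1]), tolerance = 1e-6)
    expect_equal(clock@intercept, unname(coef(ols)[1]),
                 tolerance = 1e-6)
    expect_equal(unname(predictAge(clock, m)), y, tolerance = 1e-6)
})

test_that("a huge L1 penalty shrinks every coefficient to zero", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 50, nCpgs = 20,
                                             nInformative = 3, seed = 73))
    clock <- fitClock(ds$matrix, lambda1 = 1e7, lambda2 = 0)
    expect_true(all(clock@beta == 0))
    expect_length(nonzeroFeatures(clock), 0L)
    # intercept-only model predicts the mean age
    expect_equal(unname(predictAge(clock, ds$matrix)),
                 rep(mean(ages(ds$matrix)), 50), tolerance = 1e-8)
})

test_that("predictions are exactly linear in the inputs", {
    clock <- new("ClockModel", cpgIds = c("cgA", "cgB"),
                 beta = c(50, -20), intercept = 30,
                 lambdaL1 = 0, lambdaL2 = 0, provenance = list())
    x1 <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2,
                 dimnames = list(c("s1", "s2"), c("cgA", "cgB")))
    m1 <- MethylationExperiment(x1, ages = c(NA, NA))
    # hand arithmetic: 30 + 50*0.2 - 20*0.6 = 28; 30 + 50*0.4 - 20*0.8 = 34
    expect_equal(unname(predictAge(clock, m1)), c(28, 34))
    # convexity/linearity: predict(alpha x1 + (1-alpha) x2)
    x2 <- matrix(c(0.5, 0.1, 0.3, 0.9), 2, 2, dimnames = dimnames(x1))
    al <- 0.3
    mMix <- MethylationExperiment(al * x1 + (1 - al) * x2,
                                  ages = c(NA, NA))
    m2 <- MethylationExperiment(x2, ages = c(NA, NA))
    expect_equal(unname(predictAge(clock, mMix)),
                 al * unname(predictAge(clock, m1)) +
                     (1 - al) * unname(predictAge(clock, m2)),
                 tolerance = 1e-12)
    # missing clock CpGs are an error listing them
    mBad <- MethylationExperiment(
        matrix(0.5, 1, 1, dimnames = list("s1", "cgA")), ages = NA)
    expect_error(predictAge(clock, mBad), "cgB")
})

test_that("nonzeroFeatures isolates the informative coefficient", {
    set.seed(79)
    n <- 60
    a <- runif(n, 20, 90)
    x <- cbind(0.5 + 0.006 * (a - 55),
               matrix(runif(n * 4, 0.3, 0.7), n, 4))
    colnames(x) <- c("cgSIG", paste0("cgN", 1:4))
    rownames(x) <- paste0("s", 1:n)
    m <- MethylationExperiment(x, ages = a)
    clock <- fitClock(m, lambda1 = 50, lambda2 = 0.01)
    nz <- nonzeroFeatures(clock)
    expect_identical(featureIds(nz)[1], "cgSIG")
    expect_true(all(featureIds(nz) %in% clock@cpgIds))
})

test_that("objective value beats the intercept-only bound and L1 is monotone", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 60, nCpgs = 25,
                                             nInformative = 3, seed = 83))
    x <- betas(ds$matrix); y <- unname(ages(ds$matrix))
    objective <- function(clock) {
        yp <- clock@intercept + drop(x[, clock@cpgIds] %*% clock@beta)
        sum((y - yp)^2) + clock@lambdaL1 * sum(abs(clock@beta)) +
            clock@lambdaL2 * sum(clock@beta^2)
    }
    nzCounts <- integer()
    for (l1 in c(0.1, 1, 10, 100, 1000)) {
        clock <- fitClock(ds$matrix, lambda1 = l1, lambda2 = 0.1)
        expect_lte(objective(clock), sum((y - mean(y))^2) + 1e-6)
        nzCounts <- c(nzCounts, length(nonzeroFeatures(clock)))
    }
    expect_true(all(diff(nzCounts) <= 0))
    # CV-tuned fit on training data keeps non-negative R2
    tuned <- fitClock(ds$matrix, seed = 5)
    expect_gte(cpgSieve:::rSquared(y,
                   unname(predictAge(tuned, ds$matrix))), 0)
})

test_that("external validation is self-consistent and handles constant ages", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 60, nCpgs = 30,
                                             nInformative = 3, seed = 89))
    clock <- fitClock(ds$matrix, ds$groundTruth, seed = 3)
    self <- externalValidate(clock, ds$matrix)
    yp <- predictAge(clock, ds$matrix)
    ya <- unname(ages(ds$matrix))
    expect_equal(reportMetrics(self)[["meanR2"]],
                 cpgSieve:::rSquared(ya, unname(yp)))
    expect_equal(reportMetrics(self)[["maeYears"]],
                 mean(abs(ya - unname(yp))))
    # independent draw from the same generative population (same spec,
    # fresh sampling randomness): external R2 close to in-sample
    ds2 <- generateClockDataset(syntheticSpec(nSamples = 60, nCpgs = 30,
                                              nInformative = 3,
                                              seed = 89), draw = 1L)
    expect_identical(featureIds(ds2$groundTruth),
                     featureIds(ds$groundTruth))
    ext <- externalValidate(clock, ds2$matrix)
    expect_lt(abs(reportMetrics(ext)[["meanR2"]] -
                  reportMetrics(self)[["meanR2"]]), 0.1)
    # constant external ages: R2 undefined (NA), MAE still computed
    bConst <- betas(ds$matrix)
    mConst <- MethylationExperiment(bConst,
                                    ages = rep(50, nrow(bConst)))
    rep <- externalValidate(clock, mConst)
    expect_true(is.na(reportMetrics(rep)[["meanR2"]]))
    expect_false(is.na(reportMetrics(rep)[["maeYears"]]))
})

test_that("clock serialisation round-trips bit-exactly", {
    ds <- generateClockDataset(syntheticSpec(nSamples = 40, nCpgs = 15,
                                             nInformative = 2, seed = 97))
    clock <- fitClock(ds$matrix, seed = 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    saveClock(clock, path)
    back <- loadClock(path)
    expect_identical(back@cpgIds, clock@cpgIds)
    expect_identical(back@beta, clock@beta)
    expect_identical(back@intercept, clock@intercept)
    expect_identical(back@lambdaL1, clock@lambdaL1)
    expect_identical(back@lambdaL2, clock@lambdaL2)
})

test_that("transfer between independent draws of one spec succeeds", {
    r2s <- vapply(1:3, function(s) {
        specA <- syntheticSpec(seed = 1100 + s)
        dsA <- generateClockDataset(specA, draw = 0L)
        dsB <- generateClockDataset(specA, draw = 1L)  # independent samples
        expect_false(identical(betas(dsA$matrix), betas(dsB$matrix)))
        rep <- transferFit(dsA$groundTruth, dsB$matrix, repeats = 5,
                           seed = s)
        reportMetrics(rep)[["meanR2"]]
    }, numeric(1))
    expect_gte(mean(r2s), 0.85)
    # transfer on the original matrix is definitionally
    # evaluateFeatureSet
    ds <- generateClockDataset(syntheticSpec(seed = 1201, nSamples = 60,
                                             nCpgs = 40))
    a <- transferFit(ds$groundTruth, ds$matrix, repeats = 4, seed = 9)
    b <- evaluateFeatureSet(ds$matrix, ds$groundTruth, repeats = 4,
                            seed = 9)
    expect_identical(perSplitMetrics(a), perSplitMetrics(b))
    # a panel disjoint from the informative set transfers poorly
    nullPanel <- setdiff(cpgIds(ds$matrix),
                         featureIds(ds$groundTruth))[1:5]
    poor <- transferFit(featureSet(nullPanel), ds$matrix, repeats = 4,
                        seed = 9)
    expect_lte(reportMetrics(poor)[["meanR2"]], 0.2)
})
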