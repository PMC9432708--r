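#' Genetic-algorithm feature subset search
#'
#' Evolutionary search over fixed-size CpG subsets ("creatures"). A
#' population of creatures, each holding \code{subsetSize} distinct CpGs
#' drawn uniformly at random, is scored by the held-out accuracy of an
#' elastic-net clock trained on its features; the lowest-scoring
#' fraction is culled each generation and the population is refilled by
#' breeding (children sample their features from the union of two random
#' surviving parents' features) with random mutation. Survivors carry
#' over unmodified, so the best fitness is non-decreasing across
#' generations.
#'
#' The defaults mirror the reference configuration for array-scale runs:
#' 3000 creatures of 50 features, 50\% culling, and mutation replacing
#' 30\% of a child's features with probability 0.5 per child. At bench
#' scale a reduced population (e.g. 200 creatures, 15 generations)
#' recovers planted signal reliably.
#'
#' @param m a complete \linkS4class{MethylationExperiment}.
#' @param populationSize number of creatures, default 3000.
#' @param subsetSize features per creature, default 50.
#' @param cullFraction fraction culled per generation, default 0.5.
#' @param mutationFeatureFraction fraction of a mutated child's features
#'   replaced, default 0.3.
#' @param mutationProbability per-child probability of mutation, default
#'   0.5.
#' @param generations number of generations, default 20.
#' @param validationFraction fraction of samples held out for fitness
#'   scoring, default 0.2 (the split is drawn once per run and reused).
#' @param fitnessThreshold optional early-stop: halt once the best
#'   fitness reaches this value.
#' @param polygamy when \code{TRUE}, parents are drawn with
#'   fitness-rank-proportional probability instead of uniformly.
#' @param litterScaling when \code{TRUE}, breeding pairs are re-drawn
#'   per child with fitness-proportional weights, so fitter parents
#'   leave more offspring.
#' @param seed integer seed; the whole run is seed-deterministic.
#' @return a \linkS4class{FeatureSet} holding the best creature's
#'   features (lexicographic order, no scores); the best fitness and
#'   generation count are recorded in the provenance.
#' @seealso [initPopulation()], [evaluateFitness()] for the building
#'   blocks.
#' @export
gaSelect <- function(m, populationSize = 3000L, subsetSize = 50L,
                     cullFraction = 0.5, mutationFeatureFraction = 0.3,
                     mutationProbability = 0.5, generations = 20L,
                     validationFraction = 0.2, fitnessThreshold = NULL,
                     polygamy = FALSE, litterScaling = FALSE,
                     seed = 1L) {
    stopIfMissingBetas(m, "gaSelect")
    populationSize <- as.integer(populationSize)
    subsetSize <- as.integer(subsetSize)
    generations <- as.integer(generations)
    if (populationSize < 2L)
        stop("populationSize must be at least 2", call. = FALSE)
    for (f in c(cullFraction, mutationFeatureFraction,
                mutationProbability, validationFraction))
        if (f <= 0 || f >= 1)
            stop("all fractions must lie in (0, 1)", call. = FALSE)
    pool <- cpgIds(m)
    if (subsetSize > length(pool))
        stop("subsetSize exceeds the number of CpGs", call. = FALSE)
    x <- betas(m)
    a <- unname(ages(m))
    n <- nrow(x)

    withSeed(seed, {
        nVal <- max(1L, as.integer(floor(validationFraction * n)))
        if (nVal < 3L)
            stop("validation split has fewer than 3 samples",
                 call. = FALSE)
        valIdx <- sort(sample.int(n, nVal))
        trainIdx <- setdiff(seq_len(n), valIdx)

        scoreCreature <- function(features)
            .quickEnetR2(x[trainIdx, features, drop = FALSE], a[trainIdx],
                         x[valIdx, features, drop = FALSE], a[valIdx])

        pop <- .initPopulationImpl(pool, populationSize, subsetSize)
        fitness <- rep(NA_real_, populationSize)
        nCull <- as.integer(floor(cullFraction * populationSize))
        nMut <- max(1L, as.integer(round(mutationFeatureFraction *
                                         subsetSize)))
        gen <- 0L
        bestTrace <- numeric()
        repeat {
            todo <- which(is.na(fitness))
            for (i in todo)
                fitness[i] <- scoreCreature(pop[[i]])
            gen <- gen + 1L
            best <- max(fitness)
            bestTrace <- c(bestTrace, best)
            if (!is.null(fitnessThreshold) && best >= fitnessThreshold)
                break
            if (gen >= generations)
                break
            ord <- order(fitness, decreasing = TRUE)
            keep <- ord[seq_len(populationSize - nCull)]
            survivors <- pop[keep]
            survFit <- fitness[keep]
            nChildren <- populationSize - length(survivors)
            weights <- if (polygamy || litterScaling) {
                r <- rank(survFit, ties.method = "first")
                r / sum(r)
            } else NULL
            children <- vector("list", nChildren)
            for (cidx in seq_len(nChildren)) {
                pair <- if (is.null(weights))
                    sample.int(length(survivors), 2L)
                else sample.int(length(survivors), 2L, prob = weights)
                u <- union(survivors[[pair[1]]], survivors[[pair[2]]])
                feat <- if (length(u) >= subsetSize)
                    sample(u, subsetSize)
                else c(u, sample(setdiff(pool, u), subsetSize - length(u)))
                if (stats::runif(1) < mutationProbability) {
                    posn <- sample.int(subsetSize, nMut)
                    repl <- sample(setdiff(pool, feat), nMut)
                    feat[posn] <- repl
                }
                children[[cidx]] <- feat
            }
            pop <- c(survivors, children)
            fitness <- c(survFit, rep(NA_real_, nChildren))
        }
        bestIdx <- which.max(fitness)
        featureSet(sort(pop[[bestIdx]]),
                   provenance = sprintf(
                       "ga(pop=%d, subset=%d, generations=%d, fitness=%.4f, trace=%s)",
                       populationSize, subsetSize, gen, fitness[bestIdx],
                       paste(sprintf("%.6f", bestTrace), collapse = "|")))
    })
}

.initPopulationImpl <- function(pool, populationSize, subsetSize)
    lapply(seq_len(populationSize),
           function(i) sample(pool, subsetSize))

#' Initialise a GA population
#'
#' Draws \code{populationSize} creatures of \code{subsetSize} distinct
#' CpGs each, uniformly without replacement from the matrix's CpG set.
#'
#' @inheritParams gaSelect
#' @return list of character vectors (one feature set per creature).
#' @export
initPopulation <- function(m, populationSize = 3000L, subsetSize = 50L,
                           seed = 1L) {
    pool <- cpgIds(m)
    if (as.integer(subsetSize) > length(pool))
        stop("subsetSize exceeds the number of CpGs", call. = FALSE)
    withSeed(seed, .initPopulationImpl(pool, as.integer(populationSize),
                                       as.integer(subsetSize)))
}

#' Score a GA population
#'
#' Computes each creature's fitness: the coefficient of determination of
#' a fixed-penalty elastic-net clock trained on the creature's features
#' on the training part of a seeded split and scored on the validation
#' part. The same split is used for every creature.
#'
#' @param population list of character feature vectors (see
#'   [initPopulation()]).
#' @inheritParams gaSelect
#' @return numeric vector of fitness values, one per creature.
#' @export
evaluateFitness <- function(population, m, validationFraction = 0.2,
                            seed = 1L) {
    stopIfMissingBetas(m, "evaluateFitness")
    x <- betas(m)
    a <- unname(ages(m))
    n <- nrow(x)
    withSeed(seed, {
        nVal <- max(1L, as.integer(floor(validationFraction * n)))
        if (nVal < 3L)
            stop("validation split has fewer than 3 samples",
                 call. = FALSE)
        valIdx <- sort(sample.int(n, nVal))
        trainIdx <- setdiff(seq_len(n), valIdx)
        vapply(population, function(features)
            .quickEnetR2(x[trainIdx, features, drop = FALSE], a[trainIdx],
                         x[valIdx, features, drop = FALSE], a[valIdx]),
            numeric(1))
    })
}

#' @rdname selectorConstructors
#' @param populationSize,subsetSize,cullFraction,mutationFeatureFraction
#'   parameters of [gaSelect()].
#' @param mutationProbability,generations,validationFraction,fitnessThreshold
#'   parameters of [gaSelect()].
#' @param polygamy,litterScaling parameters of [gaSelect()].
#' @export
gaSelector <- function(populationSize = 3000L, subsetSize = 50L,
                       cullFraction = 0.5,
                       mutationFeatureFraction = 0.3,
                       mutationProbability = 0.5, generations = 20L,
                       validationFraction = 0.2,
                       fitnessThreshold = NULL, polygamy = FALSE,
                       litterScaling = FALSE, seed = 1L)
    new("GaSelector", populationSize = as.integer(populationSize),
        subsetSize = as.integer(subsetSize),
        cullFraction = as.numeric(cullFraction),
        mutationFeatureFraction = as.numeric(mutationFeatureFraction),
        mutationProbability = as.numeric(mutationProbability),
        generations = as.integer(generations),
        validationFraction = as.numeric(validationFraction),
        polygamy = polygamy, litterScaling = litterScaling,
        fitnessThreshold = fitnessThreshold, seed = as.integer(seed))

#' @rdname selectFeatures
#' @export
setMethod("selectFeatures", "GaSelector",
    function(selector, m, ...)
        gaSelect(m, selector@populationSize, selector@subsetSize,
                 selector@cullFraction,
                 selector@mutationFeatureFraction,
                 selector@mutationProbability, selector@generations,
                 selector@validationFraction,
                 selector@fitnessThreshold, selector@polygamy,
                 selector@litterScaling, selector@seed))
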