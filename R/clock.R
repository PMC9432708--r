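#' Fit an elastic-net epigenetic clock
#'
#' Fits the linear age predictor minimising
#' \deqn{\sum_i (y_i - b - \sum_j \beta_j x_{ij})^2
#'       + \lambda_1 \sum_j |\beta_j| + \lambda_2 \sum_j \beta_j^2}
#' over the CpGs of \code{fs}. When \code{lambda1}/\code{lambda2} are
#' supplied the model is fitted at exactly that penalty; when omitted,
#' the penalty pair is tuned by seeded internal cross-validation
#' (default 5-fold) over a logarithmic overall-strength path crossed
#' with L1-shares \code{l1Share} (default 0.1/0.5/0.9).
#'
#' Fitting goes through coordinate descent (glmnet) with the exact
#' penalty mapping \eqn{\lambda_1 = 2 n \lambda \alpha},
#' \eqn{\lambda_2 = n \lambda (1 - \alpha)} between the unscaled
#' objective above and glmnet's per-observation parameterisation. The
#' pure ridge/ordinary-least-squares case (\code{lambda1 = 0}) is solved
#' in closed form, \eqn{\beta = (X_c'X_c + \lambda_2 I)^{-1} X_c' y}
#' on centred data, so the unpenalised fit is exact. Features are not
#' standardized before fitting (betas already share the [0, 1] scale);
#' set \code{standardize = TRUE} to override.
#'
#' @param m a complete \linkS4class{MethylationExperiment} with known
#'   ages.
#' @param fs features to use: a \linkS4class{FeatureSet}, character
#'   vector, or \code{NULL} for all CpGs.
#' @param lambda1,lambda2 optional exact penalties (both \code{>= 0}).
#'   Supply both or neither.
#' @param l1Share candidate L1 shares for tuning.
#' @param nfolds internal CV folds, default 5.
#' @param standardize standardize features before fitting; default
#'   \code{FALSE}.
#' @param seed integer seed pinning the CV fold assignment.
#' @return a \linkS4class{ClockModel}.
#' @examples
#' ds <- generateClockDataset(syntheticSpec(nSamples = 80, nCpgs = 30,
#'                                          nInformative = 3, seed = 2))
#' clock <- fitClock(ds$matrix, ds$groundTruth, seed = 11)
#' head(predictAge(clock, ds$matrix))
#' @export
fitClock <- function(m, fs = NULL, lambda1 = NULL, lambda2 = NULL,
                     l1Share = c(0.1, 0.5, 0.9), nfolds = 5L,
                     standardize = FALSE, seed = 1L) {
    ids <- if (is.null(fs)) cpgIds(m)
           else if (is(fs, "FeatureSet")) featureIds(fs)
           else as.character(fs)
    if (!length(ids))
        stop("feature set is empty", call. = FALSE)
    mR <- restrictFeatures(m, ids)
    stopIfMissingBetas(mR, "fitClock")
    x <- betas(mR)
    y <- unname(ages(mR))
    n <- nrow(x)
    if (n < 2L)
        stop("at least 2 samples are required to fit a clock",
             call. = FALSE)
    if (xor(is.null(lambda1), is.null(lambda2)))
        stop("supply both lambda1 and lambda2, or neither",
             call. = FALSE)

    if (!is.null(lambda1)) {
        if (lambda1 < 0 || lambda2 < 0)
            stop("penalties must be non-negative", call. = FALSE)
        if (lambda1 == 0) {
            ## closed-form ridge / OLS on centred data
            xc <- scale(x, center = TRUE, scale = FALSE)
            yc <- y - mean(y)
            xtx <- crossprod(xc) + diag(lambda2, ncol(x))
            beta <- as.numeric(solve(xtx, crossprod(xc, yc)))
            b0 <- mean(y) - sum(colMeans(x) * beta)
        } else {
            ## glmnet parameterisation: (1/2n)RSS + lam*(al*L1 + (1-al)/2*L2)
            A <- lambda1 / (2 * n)
            B <- lambda2 / n
            lam <- A + B
            al <- A / (A + B)
            fit <- glmnet::glmnet(x, y, alpha = al, lambda = lam,
                                  standardize = standardize,
                                  thresh = 1e-12)
            beta <- as.numeric(fit$beta[, 1])
            b0 <- as.numeric(fit$a0[1])
        }
        prov <- list(seed = seed, tuned = FALSE)
    } else {
        bestCvm <- Inf; bestAlpha <- NA_real_; bestLam <- NA_real_
        foldid <- withSeed(seed,
            sample(rep(seq_len(nfolds), length.out = n)))
        for (al in l1Share) {
            cv <- glmnet::cv.glmnet(x, y, alpha = al, foldid = foldid,
                                    standardize = standardize)
            i <- which.min(cv$cvm)
            if (cv$cvm[i] < bestCvm) {
                bestCvm <- cv$cvm[i]
                bestAlpha <- al
                bestLam <- cv$lambda[i]
            }
        }
        fit <- glmnet::glmnet(x, y, alpha = bestAlpha, lambda = bestLam,
                              standardize = standardize, thresh = 1e-10)
        beta <- as.numeric(fit$beta[, 1])
        b0 <- as.numeric(fit$a0[1])
        lambda1 <- 2 * n * bestLam * bestAlpha
        lambda2 <- n * bestLam * (1 - bestAlpha)
        prov <- list(seed = seed, tuned = TRUE, nfolds = nfolds,
                     l1Share = l1Share, alpha = bestAlpha,
                     glmnetLambda = bestLam, cvm = bestCvm)
    }
    new("ClockModel", cpgIds = colnames(x), beta = beta,
        intercept = b0, lambdaL1 = as.numeric(lambda1),
        lambdaL2 = as.numeric(lambda2), provenance = prov)
}

setMethod("show", "ClockModel", function(object) {
    cat(sprintf(paste0("ClockModel: %d CpGs (%d nonzero), ",
                       "intercept %.2f years, lambda1=%.4g, ",
                       "lambda2=%.4g\n"),
                length(object@cpgIds), sum(object@beta != 0),
                object@intercept, object@lambdaL1, object@lambdaL2))
})

#' Predict age from methylation
#'
#' Evaluates \eqn{\hat y = b + \sum_j \beta_j x_j} for every sample of
#' \code{m}. All clock CpGs must be present; missing ones are an error
#' listing them.
#'
#' @param clock a \linkS4class{ClockModel}.
#' @param m a \linkS4class{MethylationExperiment} (ages may be
#'   \code{NA}).
#' @return named numeric vector of predicted ages (years).
#' @export
setMethod("predictAge", signature("ClockModel", "MethylationExperiment"),
    function(clock, m) {
        mR <- restrictFeatures(m, clock@cpgIds)
        x <- betas(mR)
        if (anyNA(x[, clock@cpgIds, drop = FALSE]))
            stop("missing betas among clock CpGs", call. = FALSE)
        drop(x[, clock@cpgIds, drop = FALSE] %*% clock@beta) +
            clock@intercept
    })

#' Extract the nonzero-coefficient features of a clock
#'
#' The CpGs a fitted clock actually uses: those with \eqn{\beta \ne 0},
#' scored by \eqn{|\beta|}. For an unselected ("no feature selection")
#' elastic-net clock this is the model's effective panel.
#'
#' @param clock a \linkS4class{ClockModel}.
#' @return a \linkS4class{FeatureSet} (possibly empty), sorted by
#'   \eqn{|\beta|} descending.
#' @export
setMethod("nonzeroFeatures", "ClockModel", function(clock) {
    keep <- which(clock@beta != 0)
    s <- abs(clock@beta[keep])
    ord <- scoreOrder(s, clock@cpgIds[keep])
    featureSet(clock@cpgIds[keep][ord], scores = unname(s[ord]),
               provenance = "nonzero_coefficients")
})

#' Validate a fitted clock on an external dataset
#'
#' Single-pass prediction on an independent matrix with no refitting:
#' reports the coefficient of determination, mean and median absolute
#' error against the external ages. If the external ages are constant,
#' R squared is undefined and reported as \code{NA} while the absolute
#' errors are still computed.
#'
#' @param clock a \linkS4class{ClockModel}.
#' @param mExternal a \linkS4class{MethylationExperiment} with known
#'   ages containing every clock CpG (apply [dropIncompleteCpgs()]
#'   first if needed).
#' @return an \linkS4class{EvaluationReport} with a single split row.
#' @export
setMethod("externalValidate",
    signature("ClockModel", "MethylationExperiment"),
    function(clock, mExternal) {
        yp <- predictAge(clock, mExternal)
        ya <- unname(ages(mExternal))
        if (anyNA(ya))
            stop("external matrix has missing ages", call. = FALSE)
        ae <- abs(ya - yp)
        r2 <- rSquared(ya, unname(yp))
        new("EvaluationReport", meanR2 = r2, r2Sd = 0,
            maeYears = mean(ae), medianAeYears = stats::median(ae),
            perSplit = data.frame(split = 1L, r2 = r2, mae = mean(ae),
                                  medianAe = stats::median(ae)))
    })

#' Serialise / restore a clock as delimited text
#'
#' Writes a clock as a human-diffable TSV: header lines (prefixed
#' \code{#}) carrying intercept, penalties and provenance, followed by
#' (cpg_id, coefficient) rows at full precision. \code{loadClock()}
#' restores it bit-exactly.
#'
#' @param clock a \linkS4class{ClockModel}.
#' @param path output (input) file path.
#' @return \code{saveClock()} returns \code{path} invisibly;
#'   \code{loadClock()} returns a \linkS4class{ClockModel}.
#' @export
saveClock <- function(clock, path) {
    hdr <- c(sprintf("# intercept\t%s",
                     format(clock@intercept, digits = 17)),
             sprintf("# lambda1\t%s", format(clock@lambdaL1, digits = 17)),
             sprintf("# lambda2\t%s", format(clock@lambdaL2, digits = 17)),
             sprintf("# seed\t%s",
                     format(clock@provenance$seed %||% NA)))
    body <- sprintf("%s\t%s", clock@cpgIds,
                    vapply(clock@beta, format, character(1), digits = 17))
    writeLines(c(hdr, "cpg_id\tcoefficient", body), path)
    invisible(path)
}

#' @rdname saveClock
#' @export
loadClock <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "# ")]
    kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
    getv <- function(key) as.numeric(kv[kv[, 1] == key, 2][1])
    body <- lines[!startsWith(lines, "#")]
    body <- body[-1]  # column header
    parts <- do.call(rbind, strsplit(body, "\t"))
    seedv <- suppressWarnings(getv("seed"))
    new("ClockModel", cpgIds = parts[, 1],
        beta = as.numeric(parts[, 2]), intercept = getv("intercept"),
        lambdaL1 = getv("lambda1"), lambdaL2 = getv("lambda2"),
        provenance = list(seed = if (is.na(seedv)) NULL
                          else as.integer(seedv)))
}

#' Transfer a CpG panel to a new dataset
#'
#' Cross-dataset feature transfer: restricts \code{mNew} to the panel
#' \code{fs} and evaluates fresh clocks on it with the standard repeated
#' train/test protocol of [evaluateFeatureSet()] (a new clock is fitted
#' per split; no coefficients are carried over).
#'
#' @param fs the CpG panel selected on the source dataset.
#' @param mNew the target \linkS4class{MethylationExperiment}.
#' @param repeats,testFraction,seed,mode as in [evaluateFeatureSet()].
#' @return an \linkS4class{EvaluationReport}.
#' @export
transferFit <- function(fs, mNew, repeats = 10L, testFraction = 0.2,
                        seed = 1L, mode = c("split", "kfold")) {
    evaluateFeatureSet(mNew, fs, repeats = repeats,
                       testFraction = testFraction, seed = seed,
                       mode = mode)
}
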