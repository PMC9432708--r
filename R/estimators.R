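## Importance backends shared by SFM and %-RFE.
##
## "penalized-linear" fits a single fixed-penalty elastic net (glmnet,
## unstandardized — betas already share the [0,1] scale) and takes
## absolute coefficients as importance. "tree-ensemble" fits an
## extremely-randomized-trees regressor (ranger, splitrule "extratrees",
## whole-sample training without bootstrap, single random split per
## candidate) and takes mean impurity importance.

.fitImportance <- function(x, y,
                           estimator = c("penalized-linear",
                                         "tree-ensemble"),
                           nTrees = 100L, seed = NULL,
                           lambda = 0.01, alpha = 0.5,
                           splitrule = "extratrees") {
    estimator <- match.arg(estimator)
    if (estimator == "penalized-linear") {
        fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                              standardize = FALSE)
        imp <- abs(as.numeric(fit$beta[, 1]))
        names(imp) <- rownames(fit$beta)
    } else {
        args <- list(x = x, y = y, num.trees = nTrees,
                     importance = "impurity", splitrule = splitrule,
                     seed = seed %||% 1L, num.threads = 1L)
        if (splitrule == "extratrees") {
            args$num.random.splits <- 1L
            args$replace <- FALSE
            args$sample.fraction <- 1
        }
        fit <- do.call(ranger::ranger, args)
        imp <- fit$variable.importance[colnames(x)]
        imp <- pmax(imp, 0)
    }
    if (any(!is.finite(imp)))
        stop("estimator produced non-finite importances", call. = FALSE)
    imp
}

# Single fixed-penalty elastic-net fit + R^2 on a validation block.
# Used as the cheap inner scorer of the genetic algorithm.
.quickEnetR2 <- function(xTrain, yTrain, xVal, yVal,
                         alpha = 0.5, lambda = 0.01) {
    fit <- glmnet::glmnet(xTrain, yTrain, alpha = alpha, lambda = lambda,
                          standardize = FALSE)
    pred <- as.numeric(stats::predict(fit, xVal, s = lambda))
    rSquared(yVal, pred)
}
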