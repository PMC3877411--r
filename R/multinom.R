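#' Ridge-penalized multinomial logit fit
#'
#' Fits the multinomial (polytomous) logistic model
#' `log(P(y = j) / P(y = ref)) = alpha_j + x' beta_j` for each non-reference
#' category j, maximizing the log-likelihood minus `ridge * ||w||^2 / 2`.
#' The most frequent category is taken as the reference.  The small,
#' always-on ridge penalty keeps the fit finite under perfect separation —
#' a frequent and benign situation when intensities or tightly linked
#' markers predict the genotype without error.  With two observed
#' categories the model reduces to binary logistic regression.  Aliased
#' (collinear) predictor columns are dropped with a warning.
#'
#' Fitting is delegated to [nnet::multinom()] with `decay = ridge`; the
#' coefficient covariance comes from the penalized Hessian, which is what
#' the proper-imputation coefficient draws ([drawCoefficients()]) use.
#'
#' @param y response: factor or vector of observed genotype categories.
#' @param X predictor `data.frame`/matrix (or `NULL` for an intercept-only
#'   model, whose fitted probabilities are the category frequencies).
#' @param ridge L2 penalty scale (default `1e-4`).
#' @param maxit maximum optimizer iterations (default 2000; penalized fits near separation have long, shallow plateaus).
#' @return an object of class `"LogitFit"`: list with elements
#'   `categories`, `reference`, `coef` (matrix, one row per non-reference
#'   category), `vcov`, `fit` (the underlying multinom object) and
#'   `predictors`.
#' @export
fitMultinomialLogit <- function(y, X = NULL, ridge = 1e-4, maxit = 2000L) {
    y <- factor(y)
    y <- droplevels(y)
    if (nlevels(y) < 2L)
        stop("only one observed category; fit a marginal draw instead")
    ref <- names(sort(table(y), decreasing = TRUE))[1L]
    y <- stats::relevel(y, ref = ref)
    if (is.null(X) || NCOL(X) == 0L) {
        dat <- data.frame(.y = y)
        form <- .y ~ 1
    } else {
        X <- as.data.frame(X)
        if (anyNA(X)) stop("predictors must be complete for the fitted rows")
        mm <- model.matrix(~ ., data = X)
        qr_ <- qr(mm)
        if (qr_$rank < ncol(mm)) {
            aliased <- colnames(mm)[qr_$pivot[-seq_len(qr_$rank)]]
            aliased <- setdiff(aliased, "(Intercept)")
            dropCols <- names(X)[vapply(names(X), function(nm)
                any(startsWith(aliased, nm)), logical(1))]
            if (length(dropCols)) {
                warning("dropping collinear predictor(s): ",
                        paste(dropCols, collapse = ", "))
                X <- X[, setdiff(names(X), dropCols), drop = FALSE]
            }
        }
        if (NCOL(X) == 0L) {
            dat <- data.frame(.y = y)
            form <- .y ~ 1
        } else {
            dat <- data.frame(.y = y, X, check.names = TRUE)
            form <- .y ~ .
        }
    }
    fit <- nnet::multinom(form, data = dat, decay = ridge, Hess = TRUE,
                          trace = FALSE, maxit = maxit)
    if (fit$convergence != 0)
        stop("multinomial logit did not converge (value ", fit$value,
             ", ", maxit, " iterations)")
    cf <- coef(fit)
    if (is.null(dim(cf)))
        cf <- matrix(cf, nrow = 1L,
                     dimnames = list(levels(y)[2L], names(cf)))
    vc <- tryCatch(vcov(fit), error = function(e) NULL)
    if (is.null(vc)) {
        # penalized Hessian numerically singular: inflate a diagonal proxy
        vc <- diag(1 / max(ridge, 1e-8), length(cf))
    }
    structure(list(categories = levels(y), reference = ref, coef = cf,
                   vcov = vc, fit = fit,
                   predictors = if (is.null(X)) character(0) else names(as.data.frame(X))),
              class = "LogitFit")
}

#' @export
print.LogitFit <- function(x, ...) {
    cat("Multinomial logit fit (", length(x$categories), " categories, ref = ",
        x$reference, ")\n", sep = "")
    print(x$coef)
    invisible(x)
}

#' Predicted category probabilities from a LogitFit
#'
#' Computes the softmax category probabilities at new predictor values,
#' optionally under a supplied coefficient vector (as drawn by
#' [drawCoefficients()]) rather than the point estimates.
#'
#' @param object a `"LogitFit"`.
#' @param newdata `data.frame` of predictors (ignored for intercept-only
#'   fits, where `n` rows of marginal probabilities are returned).
#' @param coefVec optional replacement coefficient vector, in the layout of
#'   `as.vector(t(object$coef))`.
#' @param n number of rows when `newdata` is `NULL`.
#' @return matrix of probabilities, one column per category (reference
#'   first), rows summing to one.
#' @export
predictCategoryProbs <- function(object, newdata = NULL, coefVec = NULL,
                                 n = NULL) {
    stopifnot(inherits(object, "LogitFit"))
    cf <- object$coef
    if (!is.null(coefVec))
        cf <- matrix(coefVec, nrow = nrow(cf), byrow = TRUE,
                     dimnames = dimnames(cf))
    if (length(object$predictors) == 0L) {
        if (is.null(n)) n <- if (is.null(newdata)) 1L else NROW(newdata)
        mm <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    } else {
        newdata <- as.data.frame(newdata)[, object$predictors, drop = FALSE]
        mm <- model.matrix(~ ., data = newdata)
    }
    eta <- cbind(0, mm %*% t(cf[, colnames(mm), drop = FALSE]))
    eta <- eta - apply(eta, 1L, max)
    pr <- exp(eta)
    pr <- pr / rowSums(pr)
    colnames(pr) <- object$categories
    pr
}

#' Draw coefficients from their asymptotic distribution
#'
#' Proper-imputation step: samples one coefficient vector from the normal
#' approximation `N(theta_hat, Vcov)` of the penalized multinomial logit
#' posterior, so that imputation draws propagate estimation uncertainty
#' into Rubin's between-imputation variance.
#'
#' @param object a `"LogitFit"`.
#' @return numeric coefficient vector (layout `as.vector(t(coef))`).
#' @export
drawCoefficients <- function(object) {
    stopifnot(inherits(object, "LogitFit"))
    mu <- as.vector(t(object$coef))
    vc <- (object$vcov + t(object$vcov)) / 2
    ev <- eigen(vc, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    L <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
    as.vector(mu + L %*% rnorm(length(mu)))
}
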