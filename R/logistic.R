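#' @importFrom stats pnorm plogis qlogis var
NULL

# Core logistic fit: iteratively reweighted least squares to a relative
# log-likelihood (deviance) change below 1e-10, at most 50 iterations, with
# step-halving when an update overshoots. Returns coefficients, standard
# errors from the observed information, the maximized Bernoulli
# log-likelihood, and convergence/boundary flags. The first column of X is
# assumed to be the intercept.
.logisticCore <- function(X, y, eps = 1e-10, maxit = 50L, start = NULL) {
    p <- ncol(X); n <- length(y)
    # Bernoulli log-likelihood sum(y*eta - log(1 + exp(eta))), stably
    bern_ll <- function(eta) sum(y * eta) -
        sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
    if (is.null(start)) {
        beta <- numeric(p)
        beta[1L] <- qlogis((sum(y) + 0.5) / (n + 1))
        eta <- rep(beta[1L], n)
    } else {
        beta <- start
        eta <- as.vector(X %*% beta)
    }
    mu <- 1 / (1 + exp(-eta))
    ll <- bern_ll(eta)
    converged <- FALSE
    for (it in seq_len(maxit)) {
        w <- pmax(mu * (1 - mu), 1e-12)
        wz <- w * eta + (y - mu)
        XtWX <- crossprod(X, X * w)
        XtWz <- crossprod(X, wz)
        beta_new <- tryCatch(drop(solve(XtWX, XtWz)), error = function(e) NULL)
        if (is.null(beta_new) || any(!is.finite(beta_new)))
            return(list(beta = beta, se = rep(NA_real_, p), loglik = ll,
                        converged = FALSE, boundary = TRUE))
        for (half in 0:20) {  # step-halve if the likelihood got worse
            eta_new <- as.vector(X %*% beta_new)
            ll_new <- bern_ll(eta_new)
            if (is.finite(ll_new) && ll_new >= ll - 1e-8) break
            beta_new <- (beta + beta_new) / 2
        }
        delta <- abs(ll_new - ll) / (abs(ll_new) + 0.1)
        beta <- beta_new; eta <- eta_new; ll <- ll_new
        mu <- 1 / (1 + exp(-eta))
        if (delta < eps) { converged <- TRUE; break }
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * W, X)
    se <- rep(NA_real_, p)
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
    list(beta = unname(beta), se = se, loglik = ll, converged = converged,
         boundary = any(mu < 1e-10) || any(mu > 1 - 1e-10))
}

.assocRow <- function(variant, population, beta = NA_real_, se = NA_real_,
                      loglik = NA_real_, null_loglik = NA_real_,
                      n = NA_integer_, maf = NA_real_, evaluable = FALSE) {
    z <- if (evaluable) beta / se else NA_real_
    data.frame(variant = variant, population = population,
               beta = if (evaluable) beta else NA_real_,
               se = if (evaluable) se else NA_real_,
               z = z,
               p = if (evaluable) 2 * pnorm(-abs(z)) else NA_real_,
               loglik = loglik, null_loglik = null_loglik,
               n = n, maf = maf, evaluable = evaluable,
               stringsAsFactors = FALSE)
}

#' Single-SNV logistic regression
#'
#' Fits \code{phenotype ~ dosage + covariates} by logistic regression (IRLS
#' to a relative log-likelihood change below 1e-10, at most 50 iterations)
#' and reports the per-allele log odds ratio with its Wald standard error, z
#' and two-sided p-value, plus the maximized log-likelihood and the
#' covariates-only (null) log-likelihood evaluated on the identical sample
#' subset -- samples with missing dosage are dropped for that variant.
#' Monomorphic dosages, quasi-complete separation and non-convergence yield a
#' not-evaluable result (the null log-likelihood is still recorded when
#' computable, so downstream posterior sums stay on a common scale).
#'
#' @param dosage numeric vector of 0/1/2 alt-allele counts (NA = missing)
#' @param phenotype 0/1 vector (NA entries are excluded)
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is added internally)
#' @param variant,population labels carried into the result row
#' @param null_fit precomputed covariates-only fit for this exact sample
#'   subset (internal use by \code{\link{scanRegion}}: avoids refitting the
#'   null model when many variants share a missingness pattern)
#' @return one-row data.frame (an association-result record)
#' @examples
#' # carrier-coded 2x2 table: cases 30/70 exposed, controls 10/90
#' g <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' y <- c(rep(1, 100), rep(0, 100))
#' fitLogistic(g, y)$beta  # log((30*90)/(70*10))
#' @export
fitLogistic <- function(dosage, phenotype, covariates = NULL,
                        variant = "", population = "", null_fit = NULL) {
    keep <- !is.na(dosage) & !is.na(phenotype)
    g <- dosage[keep]; y <- phenotype[keep]
    if (!all(y %in% 0:1)) stop("phenotype must be binary 0/1")
    n <- length(y)
    maf <- if (n > 0) min(mean(g) / 2, 1 - mean(g) / 2) else NA_real_
    if (n == 0L || sum(y) == 0L || sum(1 - y) == 0L)
        return(.assocRow(variant, population, n = n, maf = maf))
    Xnull <- cbind(intercept = rep(1, n),
                   if (!is.null(covariates))
                       covariates[keep, , drop = FALSE] else NULL)
    nullfit <- if (is.null(null_fit)) .logisticCore(Xnull, y) else null_fit
    null_loglik <- if (nullfit$converged) nullfit$loglik else NA_real_
    if (var(g) == 0)
        return(.assocRow(variant, population, null_loglik = null_loglik,
                         n = n, maf = maf))
    X <- cbind(Xnull, dosage = g)
    fit <- .logisticCore(X, y, start = if (nullfit$converged)
        c(nullfit$beta, 0) else NULL)
    j <- ncol(X)
    bad <- !fit$converged || is.na(fit$se[j]) ||
        abs(fit$beta[j]) > 15 || fit$se[j] > 100 || fit$boundary
    if (bad)
        return(.assocRow(variant, population, null_loglik = null_loglik,
                         n = n, maf = maf))
    .assocRow(variant, population, beta = fit$beta[j], se = fit$se[j],
              loglik = fit$loglik, null_loglik = null_loglik,
              n = n, maf = maf, evaluable = TRUE)
}
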