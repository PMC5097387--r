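#' @importFrom stats integrate pchisq
NULL

# Tail probability P(sum_l lambda_l * chisq_1 > q) for a positive weighted
# sum of independent 1-df chi-squares.
#
# Primary route: numerical inversion of the characteristic function
# (Imhof's integral),
#   p = 1/2 + (1/pi) * int_0^inf sin(theta(u)) / (u * rho(u)) du,
#   theta(u) = (1/2) sum atan(lambda_l u) - q u / 2,
#   rho(u)   = prod (1 + lambda_l^2 u^2)^(1/4).
# Fallback: Liu-Tang-Zhang moment matching to a noncentral chi-square, used
# when the inversion fails to converge or returns an out-of-range value.
.liuPvalue <- function(q, lambda) {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
        a <- 1 / (s1 - sqrt(s1^2 - s2))
        delta <- s1 * a^3 - a^2
        l <- a^2 - 2 * delta
    } else {
        delta <- 0
        l <- 1 / s2
    }
    mu_x <- l + delta; sigma_x <- sqrt(2) * sqrt(l + 2 * delta)
    t_star <- (q - c1) / sqrt(2 * c2)
    pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

.imhofPvalue <- function(q, lambda) {
    integrand <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
        logrho <- 0.25 * colSums(log1p(outer(lambda, u)^2))
        sin(theta) / (u * exp(logrho))
    }
    res <- tryCatch(
        integrate(integrand, lower = 0, upper = Inf,
                  subdivisions = 5000L, rel.tol = 1e-10, abs.tol = 1e-12,
                  stop.on.error = FALSE),
        error = function(e) NULL)
    if (is.null(res) || res$message != "OK") return(NA_real_)
    0.5 + res$value / pi
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Davies-type numerical inversion of the characteristic function (Imhof's
#' integral) with a Liu moment-matching fallback when the inversion does not
#' converge. Eigenvalues below \code{1e-10 * max(lambda)} are truncated.
#'
#' @param q observed statistic
#' @param lambda nonnegative weights (eigenvalues of the null kernel)
#' @return upper-tail probability, clamped to (1e-300, 1]
#' @export
quadFormPvalue <- function(q, lambda) {
    lambda <- lambda[lambda > 1e-10 * max(lambda, 0)]
    if (!length(lambda)) stop("no positive eigenvalues")
    if (q <= 0) return(1)
    p <- .imhofPvalue(q, lambda)
    if (is.na(p) || p < -1e-8 || p > 1 + 1e-8 ||
        (p < 1e-12))  # inversion noise floor: switch to moment matching
        p <- .liuPvalue(q, lambda)
    min(1, max(p, 1e-300))
}
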