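#' Single-causal posterior probabilities from per-SNV log-likelihoods
#'
#' Under a uniform prior over "which single SNV is causal" and equal model
#' dimension (each model = intercept + covariates + one SNV), the posterior
#' probability of SNV i is its maximized likelihood divided by the region sum:
#' \code{pi_i = exp(l_i - m) / sum_j exp(l_j - m)} with \code{m = max(l)}
#' (log-sum-exp stabilized). Not-evaluable variants (NA log-likelihood)
#' receive posterior 0 and are excluded from the sum.
#'
#' @param loglik named numeric vector of maximized log-likelihoods (NA for
#'   not-evaluable variants)
#' @param penalty optional per-variant complexity penalty subtracted from the
#'   log-likelihoods before normalization (e.g. \code{0.5 * k * log(n)} for a
#'   BIC-style weighting). Under the default construction every per-SNV model
#'   has the same dimension, so an equal penalty cancels exactly and the
#'   default \code{NULL} applies none.
#' @return named numeric vector of posterior probabilities summing to 1 over
#'   the evaluable variants
#' @examples
#' posteriorsFromLogliks(c(a = -100, b = -101, c = -103))
#' @export
posteriorsFromLogliks <- function(loglik, penalty = NULL) {
    if (!is.null(penalty)) loglik <- loglik - penalty
    ok <- !is.na(loglik)
    if (!any(ok)) stop("no evaluable variants in region")
    m <- max(loglik[ok])
    w <- exp(loglik[ok] - m)
    pi <- numeric(length(loglik))
    names(pi) <- names(loglik)
    pi[ok] <- w / sum(w)
    pi
}

#' Credible (posterior probability) set
#'
#' Sorts posteriors in descending order (ties broken by variant id for
#' determinism) and includes the shortest prefix whose cumulative mass
#' strictly exceeds the target (the ">90\%" rule; a 1e-12 tolerance guards
#' float equality at the boundary, so ten equal posteriors of 0.1 at mass
#' 0.9 give a set of size 10, not 9).
#'
#' @param pi named numeric vector of normalized posterior probabilities
#' @param mass target mass in (0, 1); default 0.90
#' @param region region label carried into the result
#' @return a \linkS4class{PosteriorSet}
#' @export
credibleSet <- function(pi, mass = 0.90, region = "region") {
    if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
    if (abs(sum(pi) - 1) > 1e-6)
        stop("posteriors must be normalized (sum to 1)")
    if (is.null(names(pi))) names(pi) <- seq_along(pi)
    o <- order(-pi, names(pi))
    cums <- cumsum(pi[o])
    k <- which(cums > mass + 1e-12)[1]
    if (is.na(k)) k <- length(pi)
    member <- logical(length(pi))
    member[o[seq_len(k)]] <- TRUE
    rank <- integer(length(pi))
    rank[o] <- seq_along(pi)
    tb <- DataFrame(variant = names(pi), pi = unname(pi), rank = rank,
                    member = member)
    new("PosteriorSet", region = region, table = tb, mass = mass,
        cum_mass = unname(cums[k]))
}

#' @describeIn credibleSet Member variant ids, in descending posterior order.
#' @param x a \linkS4class{PosteriorSet}
#' @export
credibleSetVariants <- function(x) {
    tb <- x@table
    tb$variant[order(tb$rank)][seq_len(sum(tb$member))]
}

#' @describeIn credibleSet Set size and size/region proportion summary row.
#' @export
credibleSetSummary <- function(x) {
    k <- sum(x@table$member)
    data.frame(region = x@region, n_variants = nrow(x@table), set_size = k,
               proportion = k / nrow(x@table), mass = x@mass,
               cum_mass = x@cum_mass, stringsAsFactors = FALSE)
}

#' Combine per-population log-likelihoods onto a common scale
#'
#' For a cross-population single-causal analysis the per-SNV log-likelihood
#' is the sum of the stratified population log-likelihoods. Where a variant
#' is not evaluable in some population (e.g. monomorphic there), that
#' population contributes its covariates-only (null) log-likelihood instead,
#' keeping all variants on the same likelihood scale. Variants evaluable in
#' no population are excluded.
#'
#' @param scans list of per-population association-result data.frames (from
#'   \code{\link{scanRegion}}) sharing variant keys
#' @return data.frame with columns \code{variant}, \code{loglik},
#'   \code{k_evaluable}
#' @export
crossPopulationLogliks <- function(scans) {
    if (is.data.frame(scans)) scans <- list(scans)
    variants <- unique(unlist(lapply(scans, `[[`, "variant")))
    loglik <- setNames(rep(0, length(variants)), variants)
    k_eval <- setNames(rep(0L, length(variants)), variants)
    drop <- setNames(rep(FALSE, length(variants)), variants)
    for (sc in scans) {
        if (nrow(sc) == 0L) next
        idx <- match(variants, sc$variant)
        has <- !is.na(idx)
        ll <- rep(NA_real_, length(variants))
        ll[has] <- ifelse(sc$evaluable[idx[has]], sc$loglik[idx[has]],
                          sc$null_loglik[idx[has]])
        # variants this population never tested contribute its covariates-only
        # log-likelihood, keeping every variant on the same scale
        pop_null <- sc$null_loglik[which(!is.na(sc$null_loglik))[1]]
        ll[is.na(ll)] <- pop_null
        loglik <- loglik + ll
        eval_here <- logical(length(variants))
        eval_here[has] <- sc$evaluable[idx[has]]
        k_eval <- k_eval + as.integer(eval_here)
        drop <- drop | is.na(ll)
    }
    keep <- k_eval > 0L & !drop
    data.frame(variant = variants[keep], loglik = unname(loglik[keep]),
               k_evaluable = unname(k_eval[keep]), stringsAsFactors = FALSE)
}

#' Frequentist coverage study of the credible-set construction
#'
#' Simulates independent single-causal regions
#' (\code{\link{simulateCausalRegion}}), runs the single-SNV logistic scan on
#' each, forms single-causal posteriors from the maximized likelihoods and
#' builds the credible set, then reports how often the set contains the true
#' causal SNV. Per-replicate seeds are derived deterministically from the
#' master seed.
#'
#' @param n_regions number of simulated regions
#' @param seed master seed
#' @param mass credible mass target
#' @param ... further arguments passed to \code{\link{simulateCausalRegion}}
#'   (region size, founder pool, cohort sizes, causal effect)
#' @return list with \code{coverage} (percentage), \code{hits},
#'   \code{n_regions} and the per-region credible-set sizes
#' @export
ppsCoverageStudy <- function(n_regions = 500L, seed, mass = 0.90, ...) {
    if (missing(seed)) stop("a master seed must be supplied")
    hits <- 0L
    sizes <- integer(n_regions)
    for (i in seq_len(n_regions)) {
        rep_i <- simulateCausalRegion(seed = childSeed(seed, "pps", i), ...)
        sc <- scanRegion(rep_i$ge, maf_min = 0.005)
        ps <- finemapRegion(sc, mass = mass, region = "sim")
        hits <- hits + (rep_i$causal %in% credibleSetVariants(ps))
        sizes[i] <- sum(ps@table$member)
    }
    list(coverage = 100 * hits / n_regions, hits = hits,
         n_regions = n_regions, set_sizes = sizes)
}

#' Fine-map a region from association scans
#'
#' Convenience wrapper: combines per-population log-likelihoods
#' (\code{\link{crossPopulationLogliks}}), forms single-causal posteriors and
#' builds the credible set.
#'
#' @param scans a single association-result data.frame or a list of them
#'   (one per population)
#' @param mass credible mass target
#' @param region region label
#' @return a \linkS4class{PosteriorSet}
#' @export
finemapRegion <- function(scans, mass = 0.90, region = "region") {
    comb <- crossPopulationLogliks(scans)
    ll <- setNames(comb$loglik, comb$variant)
    credibleSet(posteriorsFromLogliks(ll), mass = mass, region = region)
}
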