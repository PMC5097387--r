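#' @importFrom stats var cor
NULL

#' Per-SNV association scan over a region (optionally conditional)
#'
#' Runs \code{\link{fitLogistic}} for every variant with MAF above
#' \code{maf_min} (computed in the analyzed samples), adjusting for the
#' supplied covariate columns and, for a conditional scan, for the dosages of
#' the \code{condition_on} variants (mean-imputed where missing); the
#' conditioned variants themselves are reported not-evaluable. The phenotype
#' is either overall case/control status or ER-negative disease (ER+ and
#' ER-unknown cases excluded). Covariates-only fits are cached per
#' missingness pattern, since the null log-likelihood must be evaluated on
#' each variant's exact sample subset.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param population optional population label restricting the samples
#' @param phenotype \code{"overall"} or \code{"er_neg"}
#' @param covariate_cols names of numeric colData columns to adjust for
#'   (default: every column matching \code{^PC})
#' @param condition_on character vector of variant ids whose dosages are
#'   added as covariates
#' @param maf_min minimum MAF for a variant to be tested (exclusive; default
#'   0.005, the common-variant threshold of the analysis)
#' @param region optional region id (rowData \code{region} column) to scan
#' @return data.frame of association-result rows (one per tested variant)
#' @export
scanRegion <- function(ge, population = NULL,
                       phenotype = c("overall", "er_neg", "er_pos"),
                       covariate_cols = NULL, condition_on = character(0),
                       maf_min = 0.005, region = NULL) {
    phenotype <- match.arg(phenotype)
    if (!is.null(region)) {
        rg <- rowData(ge)$region
        if (is.null(rg)) stop("rowData has no 'region' column")
        ge <- ge[rg == region, ]
    }
    if (!is.null(population)) {
        pops <- colData(ge)$population
        if (is.null(pops)) stop("sample sheet has no 'population' column")
        if (!population %in% pops)
            stop("unknown population label: ", population)
        ge <- ge[, pops == population]
    }
    y_all <- phenotypeVector(ge, phenotype)
    keep_s <- !is.na(y_all)
    ge <- ge[, keep_s]
    y <- y_all[keep_s]
    pop_label <- if (is.null(population)) "all" else population

    if (is.null(covariate_cols))
        covariate_cols <- grep("^PC", colnames(colData(ge)), value = TRUE)
    covs <- if (length(covariate_cols))
        as.matrix(as.data.frame(colData(ge)[, covariate_cols, drop = FALSE]))
    else NULL

    if (length(condition_on)) {
        missing_ids <- setdiff(condition_on, rownames(ge))
        if (length(missing_ids))
            stop("condition_on variants not present: ",
                 paste(missing_ids, collapse = ", "))
        cg <- dosage(ge)[condition_on, , drop = FALSE]
        cg <- t(apply(cg, 1L, function(x) {
            x[is.na(x)] <- mean(x, na.rm = TRUE); x
        }))
        if (length(condition_on) == 1L) cg <- matrix(cg, nrow = 1L)
        cond_mat <- t(cg)
        colnames(cond_mat) <- paste0("cond_", condition_on)
        Xchk <- cbind(1, covs, cond_mat)
        qrx <- qr(Xchk)
        if (qrx$rank < ncol(Xchk)) {
            drop_col <- colnames(Xchk)[qrx$pivot[(qrx$rank + 1):ncol(Xchk)]]
            stop("conditioning variant collinear with covariates: ",
                 paste(sub("^cond_", "", drop_col), collapse = ", "))
        }
        covs <- cbind(covs, cond_mat)
    }

    if (nrow(ge) == 0L)
        return(.assocRow("", "")[0, ])

    maf <- alleleFrequency(ge)
    d <- dosage(ge)
    null_cache <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
        vid <- rownames(d)[i]
        if (vid %in% condition_on) {
            rows[[i]] <- .assocRow(vid, pop_label, n = ncol(d),
                                   maf = maf[i])
            next
        }
        if (is.na(maf[i]) || maf[i] <= maf_min) next
        g <- d[i, ]
        miss <- is.na(g)
        key <- if (any(miss)) paste(which(miss), collapse = ",") else "full"
        if (is.null(null_cache[[key]])) {
            keep <- !miss
            Xn <- cbind(rep(1, sum(keep)),
                        if (!is.null(covs)) covs[keep, , drop = FALSE]
                        else NULL)
            null_cache[[key]] <- .logisticCore(Xn, y[keep])
        }
        rows[[i]] <- fitLogistic(g, y, covs, variant = vid,
                                 population = pop_label,
                                 null_fit = null_cache[[key]])
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out)) .assocRow("", "")[0, ] else out
}

#' Fixed-effect (inverse-variance) meta-analysis of per-population results
#'
#' For each variant, combines the evaluable population results with weights
#' \code{1/se^2}: the combined estimate is the weighted mean of the
#' per-population log odds ratios, its standard error
#' \code{1/sqrt(sum(w))}, with a two-sided normal p-value. Populations where
#' a variant is not evaluable (e.g. monomorphic) are skipped; a variant
#' evaluable nowhere is dropped.
#'
#' @param results data.frame of association-result rows from
#'   \code{\link{scanRegion}} / \code{\link{fitLogistic}}, stacked over
#'   populations
#' @return data.frame of meta-analysis rows (one per variant with at least
#'   one evaluable population)
#' @examples
#' r <- rbind(
#'     fitLogistic(c(0,1,2,0,1,0), c(1,1,1,0,0,0), variant = "v", population = "A"),
#'     fitLogistic(c(0,1,2,0,1,0), c(1,1,0,1,0,0), variant = "v", population = "B"))
#' metaFixed(r)
#' @export
metaFixed <- function(results) {
    ok <- results[results$evaluable, , drop = FALSE]
    if (nrow(ok) == 0L)
        stop("no evaluable population results to combine")
    out <- lapply(split(ok, ok$variant), function(df) {
        w <- 1 / df$se^2
        beta <- sum(w * df$beta) / sum(w)
        se <- 1 / sqrt(sum(w))
        z <- beta / se
        data.frame(variant = df$variant[1], population = "meta",
                   beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                   n = sum(df$n), k_pops = nrow(df),
                   populations = paste(df$population, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[match(unique(ok$variant), res$variant), , drop = FALSE]
}

#' Effective number of tests from a correlation matrix
#'
#' The simpleM construction: the effective number of tests is the smallest k
#' such that the top-k eigenvalues of the genotype correlation matrix account
#' for at least a fraction C (default 0.995) of the total variance.
#'
#' @param R correlation matrix of the region's variant dosages
#' @param C variance-explained constant (simpleM's published default 0.995)
#' @return integer Meff, between 1 and \code{ncol(R)}
#' @export
meffFromCorrelation <- function(R, C = 0.995) {
    if (is.null(dim(R)) || nrow(R) == 0L) stop("empty correlation matrix")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    as.integer(which(cumsum(ev) >= C * sum(ev))[1])
}

#' Region-specific effective numbers of tests and adjusted threshold
#'
#' For each region, computes the correlation matrix of the evaluable common
#' variants (dosages mean-imputed at missing genotypes; constant columns
#' dropped) and the simpleM effective number of tests; the multiplicity-
#' adjusted significance threshold is \code{alpha / sum(Meff)}.
#'
#' @param ge a \linkS4class{GenotypeExperiment} with a rowData \code{region}
#'   column
#' @param maf_min variants with MAF at or below this are excluded (default
#'   0.005)
#' @param C simpleM variance-explained constant
#' @param alpha nominal family-wise significance level
#' @param population optional population restriction
#' @return list with \code{regions} (data.frame region/n_variants/meff),
#'   \code{total_meff} and \code{threshold}
#' @export
effectiveTests <- function(ge, maf_min = 0.005, C = 0.995, alpha = 0.05,
                           population = NULL) {
    rg <- rowData(ge)$region
    if (is.null(rg)) stop("rowData has no 'region' column")
    if (!is.null(population)) {
        pops <- colData(ge)$population
        ge <- ge[, pops == population]
        rg <- rowData(ge)$region
    }
    maf <- alleleFrequency(ge)
    rows <- list()
    for (r in unique(rg)) {
        idx <- which(rg == r & !is.na(maf) & maf > maf_min)
        if (!length(idx))
            stop("region '", r, "' has no evaluable common variants")
        d <- dosage(ge)[idx, , drop = FALSE]
        d <- apply(d, 1L, function(x) {
            x[is.na(x)] <- mean(x, na.rm = TRUE); x
        })  # samples x variants after apply
        keep <- apply(d, 2L, var) > 0
        d <- d[, keep, drop = FALSE]
        meff <- if (ncol(d) == 0L) 1L else meffFromCorrelation(cor(d), C)
        rows[[r]] <- data.frame(region = r, n_variants = length(idx),
                                meff = meff, stringsAsFactors = FALSE)
    }
    regions <- do.call(rbind, rows)
    rownames(regions) <- NULL
    total <- sum(regions$meff)
    list(regions = regions, total_meff = total, threshold = alpha / total)
}

#' Principal components of genotype dosages
#'
#' Restricts to variants with MAF above \code{maf_min} within the analyzed
#' samples, mean-imputes missing dosages, centers each variant and scales by
#' \code{sqrt(2 f (1 - f))} (the binomial standard deviation at the variant's
#' allele frequency), and returns the top-k eigenvectors of the sample
#' covariance. Each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param k number of components (the analysis default is 3)
#' @param population optional population label; components are then computed
#'   within that population
#' @param maf_min MAF restriction for the variants used (default 0.05)
#' @return numeric matrix (samples x k) with columns \code{PC1..PCk}
#' @export
computePCs <- function(ge, k = 3L, population = NULL, maf_min = 0.05) {
    if (!is.null(population)) {
        pops <- colData(ge)$population
        if (is.null(pops)) stop("sample sheet has no 'population' column")
        ge <- ge[, pops == population]
    }
    if (ncol(ge) < k + 1L) stop("need at least k + 1 samples")
    f <- alleleFrequency(ge, alt_freq = TRUE)
    maf <- pmin(f, 1 - f)
    use <- which(!is.na(maf) & maf > maf_min)
    if (!length(use)) stop("no variants above the MAF threshold")
    d <- dosage(ge)[use, , drop = FALSE]
    f <- f[use]
    X <- d - 2 * f  # center by 2f
    X[is.na(X)] <- 0  # mean imputation after centering
    X <- X / sqrt(2 * f * (1 - f))
    G <- crossprod(X) / nrow(X)  # samples x samples
    eg <- eigen(G, symmetric = TRUE)
    if (sum(eg$values > 1e-12) < k)
        stop("k exceeds the rank of the genotype matrix")
    pcs <- eg$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(pcs[, j]))
        if (pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
    }
    dimnames(pcs) <- list(colnames(ge)[seq_len(ncol(ge))],
                          paste0("PC", seq_len(k)))
    pcs
}

#' Attach within-population principal components to the sample sheet
#'
#' Computes \code{\link{computePCs}} separately within each population (the
#' scan adjusts for ancestry-specific structure) and stores the values as
#' \code{PC1..PCk} columns of \code{colData}.
#'
#' @inheritParams computePCs
#' @return the \linkS4class{GenotypeExperiment} with PC columns added
#' @export
addPCs <- function(ge, k = 3L, maf_min = 0.05) {
    pops <- colData(ge)$population
    if (is.null(pops)) pops <- rep("all", ncol(ge))
    pcmat <- matrix(NA_real_, ncol(ge), k,
                    dimnames = list(colnames(ge), paste0("PC", seq_len(k))))
    for (pop in unique(pops)) {
        sel <- pops == pop
        pcs <- computePCs(ge[, sel], k = k, maf_min = maf_min)
        pcmat[sel, ] <- pcs
    }
    for (j in seq_len(k)) colData(ge)[[paste0("PC", j)]] <- pcmat[, j]
    ge
}
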