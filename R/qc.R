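#' @importFrom stats setNames
NULL

#' Minor allele frequency per variant
#'
#' The alt-allele frequency is computed as the alt dosage sum over twice the
#' number of non-missing genotypes; the MAF is \code{min(f, 1 - f)}. Variants
#' missing in every (selected) sample are not evaluable (\code{NA}).
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param population optional population label; frequencies are then computed
#'   within that population only
#' @param alt_freq return the alt-allele frequency instead of the MAF
#' @return named numeric vector, one entry per variant
#' @export
alleleFrequency <- function(ge, population = NULL, alt_freq = FALSE) {
    d <- dosage(ge)
    if (!is.null(population)) {
        pops <- colData(ge)$population
        if (is.null(pops)) stop("sample sheet has no 'population' column")
        if (!population %in% pops)
            stop("unknown population label: ", population)
        d <- d[, pops == population, drop = FALSE]
    }
    nn <- rowSums(!is.na(d))
    f <- rowSums(d, na.rm = TRUE) / (2 * nn)
    f[nn == 0] <- NA_real_
    out <- if (alt_freq) f else pmin(f, 1 - f)
    setNames(out, rownames(d))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' The exact conditional test: given the observed allele counts, the p-value
#' is the summed probability of all heterozygote counts no more probable than
#' the observed one. Appropriate for the rare variants dominating targeted
#' sequencing, where the chi-square approximation fails.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote)
#' @return the exact p-value; 1 for monomorphic sites
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(50, 0, 50) < 1e-6
#' @export
hweExactTest <- function(n_AA, n_Aa, n_aa) {
    if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be nonnegative")
    n <- n_AA + n_Aa + n_aa
    if (n == 0L) stop("all genotype counts are zero")
    r <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # rare allele count
    if (r == 0L) return(1)
    hets <- seq(r %% 2L, r, by = 2L)
    # unnormalized log-probabilities of each heterozygote count given (n, r)
    lw <- hets * log(2) - lfactorial(hets) - lfactorial((r - hets) / 2) -
        lfactorial(n - (r + hets) / 2)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    obs <- w[match(n_Aa, hets)]
    if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
    min(1, sum(w[w <= obs * (1 + 1e-12)]))
}

#' Mask low-quality genotypes
#'
#' Genotypes with read depth below \code{min_depth} or quality below
#' \code{min_gq} are set to missing (thresholds are exclusive: DP = 5 and
#' GQ = 10 pass at the defaults). A no-op with a warning when the DP/GQ
#' side-channels are absent.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param thresholds a \linkS4class{QcThresholds}
#' @return list with elements \code{ge} (masked) and \code{n_masked}
#' @export
maskLowQualityGenotypes <- function(ge, thresholds = QcThresholds()) {
    dp <- readDepth(ge); gq <- genoQual(ge)
    if (is.null(dp) && is.null(gq)) {
        warning("no DP/GQ side-channels; genotype masking skipped")
        return(list(ge = ge, n_masked = 0L))
    }
    d <- dosage(ge)
    bad <- matrix(FALSE, nrow(d), ncol(d))
    if (!is.null(dp)) bad <- bad | (!is.na(dp) & dp < thresholds@min_depth)
    if (!is.null(gq)) bad <- bad | (!is.na(gq) & gq < thresholds@min_gq)
    n_masked <- sum(bad & !is.na(d))
    d[bad] <- NA_integer_
    SummarizedExperiment::assay(ge, "dosage") <- d
    list(ge = ge, n_masked = as.integer(n_masked))
}

#' Variant-level QC filters
#'
#' Drops variants failing, in this fixed attribution order: (1)
#' \emph{nodata}: more than \code{max_nodata_samples} of samples have no
#' reads (DP of 0 or missing); (2) \emph{total_depth}: summed read depth
#' below \code{min_total_reads}; (3) \emph{missingness}: more than
#' \code{max_missing} missing dosages; (4) \emph{hwe}: exact Hardy-Weinberg
#' p below \code{hwe_p_min} in any population. A variant tripping several
#' rules is counted under the first. Depth-based rules are skipped when the
#' DP assay is absent. Genotype masking
#' (\code{\link{maskLowQualityGenotypes}}) is assumed to have been applied.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param thresholds a \linkS4class{QcThresholds}
#' @param controls_only_hwe compute the HWE test in controls only (default
#'   uses all samples of each ancestry group)
#' @return list with \code{ge} (filtered) and \code{report}
#'   (\linkS4class{QcReport})
#' @export
filterVariants <- function(ge, thresholds = QcThresholds(),
                           controls_only_hwe = FALSE) {
    d <- dosage(ge)
    dp <- readDepth(ge)
    n <- ncol(d)
    fail_rule <- rep(NA_character_, nrow(d))

    if (!is.null(dp)) {
        nodata <- rowMeans(is.na(dp) | dp == 0L)
        fail_rule[is.na(fail_rule) & nodata > thresholds@max_nodata_samples] <-
            "nodata"
        tot <- rowSums(dp, na.rm = TRUE)
        fail_rule[is.na(fail_rule) & tot < thresholds@min_total_reads] <-
            "total_depth"
    }
    miss <- rowMeans(is.na(d))
    fail_rule[is.na(fail_rule) & miss > thresholds@max_missing] <- "missingness"

    pops <- colData(ge)$population
    if (is.null(pops)) pops <- rep("all", n)
    use <- rep(TRUE, n)
    if (controls_only_hwe) {
        st <- colData(ge)$status
        if (is.null(st)) stop("controls_only_hwe needs a 'status' column")
        use <- st == "control"
    }
    todo <- which(is.na(fail_rule))
    for (pop in unique(pops)) {
        sel <- use & pops == pop
        if (!any(sel)) next
        dd <- d[todo, sel, drop = FALSE]
        nAA <- rowSums(dd == 0L, na.rm = TRUE)
        nAa <- rowSums(dd == 1L, na.rm = TRUE)
        naa <- rowSums(dd == 2L, na.rm = TRUE)
        nz <- nAA + nAa + naa > 0
        pvals <- rep(1, length(todo))
        pvals[nz] <- mapply(hweExactTest, nAA[nz], nAa[nz], naa[nz])
        fail_rule[todo[pvals < thresholds@hwe_p_min]] <- "hwe"
        todo <- which(is.na(fail_rule))
    }

    rules <- c("nodata", "total_depth", "missingness", "hwe")
    counts <- setNames(vapply(rules, function(r)
        sum(fail_rule == r, na.rm = TRUE), integer(1)), rules)
    keep <- is.na(fail_rule)
    report <- new("QcReport", genotypes_masked = 0L,
                  variant_rules = counts, sample_rules = integer(0),
                  dim_in = dim(d), dim_out = c(sum(keep), n))
    list(ge = ge[keep, ], report = report)
}

# Pairwise genotype concordance between the columns of two dosage matrices
# (or within one), computed with indicator cross-products.
.concordance <- function(d1, d2) {
    nm1 <- !is.na(d1); nm2 <- !is.na(d2)
    agree <- matrix(0, ncol(d1), ncol(d2))
    for (g in 0:2) {
        i1 <- nm1 & d1 == g; i1[!nm1] <- FALSE
        i2 <- nm2 & d2 == g; i2[!nm2] <- FALSE
        agree <- agree + crossprod(i1 * 1, i2 * 1)
    }
    both <- crossprod(nm1 * 1, nm2 * 1)
    list(agree = agree, both = both)
}

#' Sample-level QC filters
#'
#' Removes, in this attribution order: (1) \emph{call_rate}: samples with a
#' dosage call rate below \code{min_call_rate}; (2) \emph{concordance}:
#' samples whose genotype concordance with an external table (e.g. prior
#' array genotypes) at overlapping variants falls below
#' \code{min_concordance} -- with no overlapping variants the check is logged
#' as not evaluable and nobody is removed; (3) \emph{duplicate}: of each pair
#' with pairwise concordance above \code{duplicate_concordance}, the
#' lexicographically larger sample id is dropped.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param thresholds a \linkS4class{QcThresholds}
#' @param external_genotypes optional dosage matrix (variants x samples) with
#'   dimnames matching the experiment's
#' @return list with \code{ge} (filtered) and \code{report}
#' @export
filterSamples <- function(ge, thresholds = QcThresholds(),
                          external_genotypes = NULL) {
    d <- dosage(ge)
    fail <- rep(NA_character_, ncol(d))
    names(fail) <- colnames(d)

    call_rate <- colMeans(!is.na(d))
    fail[call_rate < thresholds@min_call_rate] <- "call_rate"

    if (!is.null(external_genotypes)) {
        shared_v <- intersect(rownames(d), rownames(external_genotypes))
        shared_s <- intersect(colnames(d), colnames(external_genotypes))
        if (!length(shared_v)) {
            message("no overlapping variants with external genotypes; ",
                    "concordance not evaluable")
        } else {
            for (s in shared_s) {
                if (!is.na(fail[s])) next
                a <- d[shared_v, s]; b <- external_genotypes[shared_v, s]
                ok <- !is.na(a) & !is.na(b)
                if (!any(ok)) next
                if (mean(a[ok] == b[ok]) < thresholds@min_concordance)
                    fail[s] <- "concordance"
            }
        }
    }

    alive <- which(is.na(fail))
    if (length(alive) > 1L) {
        cc <- .concordance(d[, alive, drop = FALSE], d[, alive, drop = FALSE])
        conc <- cc$agree / pmax(cc$both, 1)
        conc[cc$both == 0] <- 0
        ids <- colnames(d)[alive]
        hits <- which(conc > thresholds@duplicate_concordance &
                      upper.tri(conc), arr.ind = TRUE)
        for (h in seq_len(nrow(hits))) {
            drop_id <- max(ids[hits[h, 1L]], ids[hits[h, 2L]])
            if (is.na(fail[drop_id])) fail[drop_id] <- "duplicate"
        }
    }

    rules <- c("call_rate", "concordance", "duplicate")
    counts <- setNames(vapply(rules, function(r)
        sum(fail == r, na.rm = TRUE), integer(1)), rules)
    keep <- is.na(fail)
    report <- new("QcReport", genotypes_masked = 0L,
                  variant_rules = integer(0), sample_rules = counts,
                  dim_in = dim(d), dim_out = c(nrow(d), sum(keep)))
    list(ge = ge[, keep], report = report)
}

#' Run the full QC cascade
#'
#' Masks low-quality genotypes, then applies the variant filters, then the
#' sample filters, returning the surviving experiment and a consolidated
#' \linkS4class{QcReport}.
#'
#' @inheritParams filterVariants
#' @inheritParams filterSamples
#' @return list with \code{ge} and \code{report}
#' @export
runQc <- function(ge, thresholds = QcThresholds(),
                  external_genotypes = NULL, controls_only_hwe = FALSE) {
    dim_in <- dim(ge)
    m <- maskLowQualityGenotypes(ge, thresholds)
    v <- filterVariants(m$ge, thresholds, controls_only_hwe)
    s <- filterSamples(v$ge, thresholds, external_genotypes)
    report <- new("QcReport",
                  genotypes_masked = m$n_masked,
                  variant_rules = v$report@variant_rules,
                  sample_rules = s$report@sample_rules,
                  dim_in = dim_in, dim_out = dim(s$ge))
    list(ge = s$ge, report = report)
}
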