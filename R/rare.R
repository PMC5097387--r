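#' @importFrom stats dbeta
NULL

#' Select a gene's rare-variant set
#'
#' Members are the gene's nonsynonymous (moderate-impact) SNVs whose pooled
#' MAF is strictly below \code{maf_max} (a variant at exactly the threshold
#' is excluded); with \code{damaging_only}, membership additionally requires
#' the damaging prediction flag. An empty set is returned (not an error) and
#' is skipped by the tests with a logged reason. Per-population counts of
#' polymorphic members are recorded.
#'
#' @param ge an annotated \linkS4class{GenotypeExperiment} (rowData columns
#'   \code{gene}, \code{impact}, \code{damaging})
#' @param gene gene name
#' @param maf_max rarity threshold on the pooled MAF (default 0.005)
#' @param damaging_only restrict to predicted-damaging variants
#' @return a \linkS4class{VariantSet}
#' @export
selectVariantSet <- function(ge, gene, maf_max = 0.005,
                             damaging_only = FALSE) {
    rd <- rowData(ge)
    if (is.null(rd$gene) || is.null(rd$impact))
        stop("experiment lacks gene/impact annotations")
    if (!gene %in% rd$gene[!is.na(rd$gene)])
        stop("unknown gene: ", gene)
    sel <- !is.na(rd$gene) & rd$gene == gene & rd$impact == "moderate"
    if (damaging_only)
        sel <- sel & !is.na(rd$damaging) & rd$damaging
    maf <- alleleFrequency(ge)
    sel <- sel & !is.na(maf) & maf < maf_max
    ids <- rownames(ge)[sel]
    pops <- colData(ge)$population
    if (is.null(pops)) pops <- rep("all", ncol(ge))
    pop_counts <- vapply(unique(pops), function(pp) {
        if (!length(ids)) return(0L)
        d <- dosage(ge)[ids, pops == pp, drop = FALSE]
        sum(rowSums(d > 0, na.rm = TRUE) > 0)
    }, integer(1))
    new("VariantSet", gene = gene, variants = ids,
        rule = if (damaging_only) "nonsyn_rare_damaging" else "nonsyn_rare",
        maf_max = maf_max, pop_counts = pop_counts)
}

# Minor-allele dosage matrix (samples x variants) for a set: alt dosages
# flipped at variants where the alt allele is the major one; missing
# genotypes imputed to 0 (reference) per the rare-variant convention.
.minorDosage <- function(ge, variants, impute_zero = TRUE) {
    d <- t(dosage(ge)[variants, , drop = FALSE])
    nn <- colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / (2 * nn)
    f[nn == 0] <- NA_real_
    flip <- !is.na(f) & f > 0.5
    if (any(flip)) d[, flip] <- 2L - d[, flip]
    if (impute_zero) d[is.na(d)] <- 0L
    d
}

#' Carrier proportion of a rare-variant set
#'
#' The fraction of samples carrying at least one (non-missing) minor allele
#' across the set's member variants; samples missing at every member are
#' excluded from the denominator.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param set a \linkS4class{VariantSet}
#' @return proportion in [0, 1]
#' @export
carrierProportion <- function(ge, set) {
    if (!length(set@variants)) stop("empty variant set")
    d <- .minorDosage(ge, set@variants, impute_zero = FALSE)
    informative <- rowSums(!is.na(d)) > 0
    carriers <- rowSums(d > 0, na.rm = TRUE) > 0
    sum(carriers[informative]) / sum(informative)
}

#' Gene-based burden test
#'
#' Collapses the set into a per-subject burden score (the summed minor-allele
#' count over member variants, missing genotypes counted as 0) and tests it
#' in a logistic regression with covariates, giving a per-unit-burden odds
#' ratio with Wald confidence interval and p-value. A zero-variance burden is
#' not evaluable.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param set a \linkS4class{VariantSet}
#' @param phenotype \code{"overall"} or \code{"er_neg"}
#' @param covariates optional covariate matrix (rows = samples of \code{ge})
#' @param carrier_indicator use a 0/1 carrier indicator instead of the allele
#'   count as the burden score
#' @param scope label for the result row (population or "meta")
#' @return one-row gene-test data.frame (burden part)
#' @export
burdenTest <- function(ge, set, phenotype = c("overall", "er_neg", "er_pos"),
                       covariates = NULL, carrier_indicator = FALSE,
                       scope = "all") {
    phenotype <- match.arg(phenotype)
    y <- phenotypeVector(ge, phenotype)
    if (!length(set@variants))
        return(.geneRow(set, scope, "BURDEN", cp = NA_real_))
    b <- rowSums(.minorDosage(ge, set@variants))
    if (carrier_indicator) b <- as.numeric(b > 0)
    cp <- carrierProportion(ge, set)
    fit <- fitLogistic(b, y, covariates, variant = set@gene,
                       population = scope)
    if (!fit$evaluable)
        return(.geneRow(set, scope, "BURDEN", cp = cp))
    .geneRow(set, scope, "BURDEN", cp = cp, beta = fit$beta, se = fit$se,
             p = fit$p, evaluable = TRUE)
}

#' Per-cohort SKAT score components
#'
#' The building blocks of \code{\link{skatTest}} and
#' \code{\link{metaSkatHom}}: the per-variant score vector
#' \code{S = G'(y - mu)} under the covariates-only null fit, the projected
#' information matrix \code{G' P G} that generates the null eigenvalues, and
#' the minor-allele counts used for pooled-MAF weighting in meta-analysis.
#'
#' @inheritParams burdenTest
#' @return list with elements \code{S}, \code{info}, \code{minor_count},
#'   \code{n}
#' @export
skatComponents <- function(ge, set, phenotype = c("overall", "er_neg", "er_pos"),
                           covariates = NULL) {
    phenotype <- match.arg(phenotype)
    y <- phenotypeVector(ge, phenotype)
    keep <- !is.na(y)
    y <- y[keep]
    G <- .minorDosage(ge, set@variants)[keep, , drop = FALSE]
    X <- cbind(rep(1, sum(keep)), if (!is.null(covariates))
        covariates[keep, , drop = FALSE] else NULL)
    if (sum(y) == 0L || sum(1 - y) == 0L)
        stop("both phenotype classes must be present")
    nullfit <- .logisticCore(X, y)
    mu <- 1 / (1 + exp(-as.vector(X %*% nullfit$beta)))
    v <- mu * (1 - mu)
    S <- as.vector(crossprod(G, y - mu))
    # projected information: G' P G with P = V - V X (X'VX)^-1 X'V
    VX <- X * v
    XtVX_inv <- solve(crossprod(X, VX))
    GtVX <- crossprod(G, VX)
    info <- crossprod(G, G * v) - GtVX %*% XtVX_inv %*% t(GtVX)
    minor_count <- colSums(G)
    n_used <- nrow(G)
    list(S = setNames(S, set@variants),
         info = info, minor_count = setNames(minor_count, set@variants),
         n = n_used)
}

.skatWeights <- function(maf, params = c(1, 25)) {
    dbeta(pmin(pmax(maf, 1e-12), 1 - 1e-12), params[1], params[2])
}

.skatFromComponents <- function(S, info, maf, weight_params = c(1, 25)) {
    w <- .skatWeights(maf, weight_params)
    Q <- sum(w^2 * S^2)
    A <- (w %o% w) * info  # W^(1/2) G'PG W^(1/2)
    lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    lambda <- pmax(lambda, 0)
    if (max(lambda) <= 0) return(list(Q = Q, p = NA_real_))
    list(Q = Q, p = quadFormPvalue(Q, lambda))
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test on a gene's rare-variant set: with the null
#' logistic fit's fitted probabilities \code{mu}, the per-variant scores are
#' \code{S = G'(y - mu)} and the statistic is \code{Q = sum_j w_j^2 S_j^2},
#' weighting each variant by the Beta(1, 25) density at its pooled-sample
#' MAF. The null distribution is the weighted chi-square mixture with
#' weights the eigenvalues of \code{W^(1/2) G' P G W^(1/2)} (P the
#' variance-projected hat complement), evaluated by Davies-type numerical
#' inversion with a Liu moment-matching fallback.
#'
#' @inheritParams burdenTest
#' @param weight_params Beta density parameters of the MAF weights (published
#'   SKAT default c(1, 25))
#' @return one-row gene-test data.frame (SKAT part)
#' @export
skatTest <- function(ge, set, phenotype = c("overall", "er_neg", "er_pos"),
                     covariates = NULL, weight_params = c(1, 25),
                     scope = "all") {
    phenotype <- match.arg(phenotype)
    if (!length(set@variants))
        return(.geneRow(set, scope, "SKAT", cp = NA_real_))
    cp <- carrierProportion(ge, set)
    comp <- skatComponents(ge, set, phenotype, covariates)
    maf <- pmin(comp$minor_count / (2 * comp$n),
                1 - comp$minor_count / (2 * comp$n))
    res <- .skatFromComponents(comp$S, comp$info, maf, weight_params)
    if (is.na(res$p))
        return(.geneRow(set, scope, "SKAT", cp = cp))
    .geneRow(set, scope, "SKAT", cp = cp, p = res$p, q_stat = res$Q,
             evaluable = TRUE)
}

#' Inverse-variance meta-analysis of per-population burden tests
#'
#' Combines the evaluable per-population burden log odds ratios with
#' inverse-variance weights, exactly as the fixed-effect SNV meta-analysis.
#'
#' @param results data.frame of per-population burden rows (from
#'   \code{\link{burdenTest}})
#' @return one-row gene-test data.frame with scope "meta"
#' @export
metaBurden <- function(results) {
    ok <- results[results$evaluable & results$test == "BURDEN", ,
                  drop = FALSE]
    if (nrow(ok) == 0L) stop("no evaluable burden results to combine")
    w <- 1 / ok$se^2
    beta <- sum(w * ok$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- beta / se
    data.frame(gene = ok$gene[1], scope = "meta", rule = ok$rule[1],
               n_variants = max(ok$n_variants),
               carrier_prop = NA_real_, test = "BURDEN",
               beta = beta, se = se, or = exp(beta),
               ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
               p = 2 * pnorm(-abs(z)), q_stat = NA_real_, evaluable = TRUE,
               stringsAsFactors = FALSE)
}

#' Homogeneous-effect SKAT meta-analysis (Hom-Meta-SKAT)
#'
#' Assuming each variant's effect is homogeneous across populations, the
#' per-variant scores are summed over cohorts (variants absent from a cohort
#' contribute zero score and zero information), the statistic is
#' \code{Q = sum_j w_j^2 (sum_k S_kj)^2} with weights from the pooled MAF,
#' and the null eigenvalues come from the summed projected information
#' matrices.
#'
#' @param components list of per-population outputs of
#'   \code{\link{skatComponents}}
#' @param set the \linkS4class{VariantSet} (for labels)
#' @param weight_params Beta MAF-weight parameters
#' @return one-row gene-test data.frame with scope "meta"
#' @export
metaSkatHom <- function(components, set, weight_params = c(1, 25)) {
    if (!length(components)) stop("no cohort components supplied")
    variants <- unique(unlist(lapply(components, function(cc) names(cc$S))))
    m <- length(variants)
    S <- setNames(numeric(m), variants)
    info <- matrix(0, m, m, dimnames = list(variants, variants))
    minor <- setNames(numeric(m), variants)
    n2 <- 0
    for (cc in components) {
        idx <- match(names(cc$S), variants)
        S[idx] <- S[idx] + cc$S
        info[idx, idx] <- info[idx, idx] + cc$info
        minor[idx] <- minor[idx] + cc$minor_count
        n2 <- n2 + 2 * cc$n
    }
    maf <- pmin(minor / n2, 1 - minor / n2)
    res <- .skatFromComponents(S, info, maf, weight_params)
    cp <- NA_real_
    if (is.na(res$p))
        return(.geneRow(set, "meta", "SKAT", cp = cp))
    .geneRow(set, "meta", "SKAT", cp = cp, p = res$p, q_stat = res$Q,
             evaluable = TRUE)
}

.geneRow <- function(set, scope, test, cp = NA_real_, beta = NA_real_,
                     se = NA_real_, p = NA_real_, q_stat = NA_real_,
                     evaluable = FALSE) {
    has_or <- evaluable && test == "BURDEN"
    data.frame(gene = set@gene, scope = scope, rule = set@rule,
               n_variants = length(set@variants), carrier_prop = cp,
               test = test,
               beta = if (has_or) beta else NA_real_,
               se = if (has_or) se else NA_real_,
               or = if (has_or) exp(beta) else NA_real_,
               ci_lo = if (has_or) exp(beta - 1.96 * se) else NA_real_,
               ci_hi = if (has_or) exp(beta + 1.96 * se) else NA_real_,
               p = p, q_stat = q_stat, evaluable = evaluable,
               stringsAsFactors = FALSE)
}

#' Gene-based rare-variant scan
#'
#' For each gene (and selection rule), runs the burden and SKAT tests within
#' each population (adjusting for that population's principal components,
#' when present) and meta-analyzes across populations: inverse-variance
#' fixed-effect for burden, Hom-Meta-SKAT for SKAT. Genes with empty variant
#' sets are skipped with a message. The returned table carries a
#' \code{significant} attribute-free column computed with the Bonferroni
#' threshold \code{alpha / (number of gene x rule x test meta-results
#' actually evaluated)}.
#'
#' @param ge an annotated \linkS4class{GenotypeExperiment}
#' @param genes genes to test (default: all annotated genes)
#' @param maf_max rarity threshold
#' @param damaging_only restrict sets to predicted-damaging variants
#' @param phenotype \code{"overall"} or \code{"er_neg"}
#' @param tests which tests to run
#' @param alpha family-wise level for the Bonferroni flag
#' @return gene-test result data.frame (per-population and meta rows)
#' @export
rareVariantScan <- function(ge, genes = NULL, maf_max = 0.005,
                            damaging_only = FALSE,
                            phenotype = c("overall", "er_neg", "er_pos"),
                            tests = c("burden", "skat"), alpha = 0.05) {
    phenotype <- match.arg(phenotype)
    tests <- match.arg(tests, several.ok = TRUE)
    rd <- rowData(ge)
    if (is.null(genes))
        genes <- sort(unique(rd$gene[!is.na(rd$gene)]))
    pops <- colData(ge)$population
    if (is.null(pops)) pops <- rep("all", ncol(ge))
    pc_cols <- grep("^PC", colnames(colData(ge)), value = TRUE)
    rows <- list()
    for (gene in genes) {
        set <- selectVariantSet(ge, gene, maf_max, damaging_only)
        if (!length(set@variants)) {
            message("gene ", gene, ": empty ", set@rule, " set, skipped")
            next
        }
        pop_rows <- list(); comps <- list()
        for (pp in unique(pops)) {
            sel <- pops == pp
            ge_p <- ge[, sel]
            covs <- if (length(pc_cols))
                as.matrix(as.data.frame(colData(ge_p)[, pc_cols,
                                                      drop = FALSE]))
            else NULL
            if ("burden" %in% tests)
                pop_rows[[paste0(pp, "_b")]] <-
                    burdenTest(ge_p, set, phenotype, covs, scope = pp)
            if ("skat" %in% tests) {
                pop_rows[[paste0(pp, "_s")]] <- tryCatch(
                    skatTest(ge_p, set, phenotype, covs, scope = pp),
                    error = function(e) .geneRow(set, pp, "SKAT"))
                comps[[pp]] <- tryCatch(
                    skatComponents(ge_p, set, phenotype, covs),
                    error = function(e) NULL)
            }
        }
        prt <- do.call(rbind, pop_rows)
        meta_rows <- list()
        if ("burden" %in% tests && any(prt$evaluable & prt$test == "BURDEN"))
            meta_rows$burden <- metaBurden(prt)
        comps <- comps[!vapply(comps, is.null, TRUE)]
        if ("skat" %in% tests && length(comps))
            meta_rows$skat <- metaSkatHom(comps, set)
        gene_tbl <- rbind(prt, do.call(rbind, meta_rows))
        gene_tbl$carrier_prop[gene_tbl$scope == "meta"] <-
            carrierProportion(ge, set)
        rows[[paste(gene, set@rule)]] <- gene_tbl
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(.geneRow(new("VariantSet", gene = "none",
        variants = character(0), rule = "nonsyn_rare", maf_max = maf_max,
        pop_counts = integer(0)), "meta", "SKAT")[0, ])
    rownames(out) <- NULL
    n_tests <- sum(out$scope == "meta" & out$evaluable)
    out$significant <- out$scope == "meta" & out$evaluable &
        !is.na(out$p) & out$p < alpha / max(n_tests, 1L)
    out
}
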