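#' @importFrom stats rbeta rbinom rpois runif rnbinom plogis qlogis
NULL

# Draw ancestral allele frequencies: common variants uniform on
# [0.005, 0.5], rare variants from a density proportional to 1/x on
# [1/(4K), 0.005] (the neutral-spectrum shape), K = founder pool size.
.drawAncestralFreqs <- function(m, common_fraction, founders) {
    lo <- 1 / (4 * founders)
    if (common_fraction < 1 && lo >= 0.005)
        stop("founder pool too small to represent rare variants: ",
             "1/(4*founder_haplotypes) = ", signif(lo, 3), " >= 0.005")
    is_common <- runif(m) < common_fraction
    p <- numeric(m)
    p[is_common] <- runif(sum(is_common), 0.005, 0.5)
    n_rare <- sum(!is_common)
    if (n_rare > 0)  # inverse CDF of 1/x density: x = lo * (hi/lo)^U
        p[!is_common] <- lo * (0.005 / lo)^runif(n_rare)
    p
}

# Founder-mosaic haplotypes: each sampled haplotype copies a founder and, at
# each adjacent-variant step, switches to a uniformly chosen founder with
# probability switch_prob. Returns an n x m binary matrix.
.mosaicHaplotypes <- function(founders, n, switch_prob) {
    K <- nrow(founders)
    m <- ncol(founders)
    path <- matrix(0L, n, m)
    cur <- sample.int(K, n, replace = TRUE)
    path[, 1L] <- cur
    if (m > 1L) {
        sw <- matrix(runif(n * (m - 1L)) < switch_prob, n)
        for (j in 2:m) {
            s <- sw[, j - 1L]
            if (any(s))
                cur[s] <- sample.int(K, sum(s), replace = TRUE)
            path[, j] <- cur
        }
    }
    idx <- path + rep((seq_len(m) - 1L) * K, each = n)  # linear index
    H <- matrix(founders[idx], n, m)
    storage.mode(H) <- "integer"
    H
}

#' Simulate a per-population haplotype panel for one region
#'
#' Ancestral allele frequencies are drawn from a mixture of a common range
#' (uniform on [0.005, 0.5], with probability \code{common_fraction}) and a
#' rare range (density proportional to 1/x on [1/(4K), 0.005]). Each
#' population's frequencies then diverge under the Balding-Nichols model,
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)}. Founder haplotypes are drawn sitewise
#' independently at the population frequencies, and the returned sample
#' haplotypes are founder mosaics with per-step switch probability
#' \code{switch_prob}, which creates block-like linkage disequilibrium.
#' Optionally, population-private rare variants are injected at a Poisson
#' rate per population.
#'
#' @param region a \linkS4class{RegionSpec}
#' @param pops list of \linkS4class{PopulationSpec}
#' @param seed master seed; all streams are derived deterministically from it
#' @param n_haplotypes haplotypes to generate per population (default:
#'   2 x (n_cases + n_controls) of that population)
#' @return a \linkS4class{HaplotypePanel}
#' @export
simulatePanel <- function(region, pops, seed, n_haplotypes = NULL) {
    stopifnot(is(region, "RegionSpec"))
    if (is(pops, "PopulationSpec")) pops <- list(pops)
    validObject(region)
    lapply(pops, validObject)
    if (missing(seed)) stop("a master seed must be supplied")
    m <- region@n_variants
    K <- region@founder_haplotypes
    labels <- vapply(pops, function(p) p@label, character(1))
    if (anyDuplicated(labels)) stop("population labels must be unique")

    set.seed(childSeed(seed, region@region_id, "freqs"))
    p_anc <- .drawAncestralFreqs(m, region@common_fraction, K)
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

    p_pop <- matrix(0, m, length(pops), dimnames = list(NULL, labels))
    for (k in seq_along(pops)) {
        F <- pops[[k]]@divergence_F
        set.seed(childSeed(seed, region@region_id, labels[k], "bn"))
        p_pop[, k] <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }

    # population-private rare variants: force the site monomorphic reference
    # in every other population
    taken <- integer(0)
    for (k in seq_along(pops)) {
        rate <- pops[[k]]@private_rare_rate
        if (rate <= 0) next
        set.seed(childSeed(seed, region@region_id, labels[k], "private"))
        n_priv <- min(rpois(1L, rate), m - length(taken))
        if (n_priv <= 0) next
        idx <- sample(setdiff(seq_len(m), taken), n_priv)
        taken <- c(taken, idx)
        lo <- 1 / (4 * K)
        p_pop[idx, ] <- 0
        p_pop[idx, k] <- lo * (min(0.005 / lo, 1))^runif(n_priv)
    }

    haps <- vector("list", length(pops))
    names(haps) <- labels
    for (k in seq_along(pops)) {
        n_hap <- if (is.null(n_haplotypes))
            2L * (pops[[k]]@n_cases + pops[[k]]@n_controls)
        else as.integer(n_haplotypes)
        set.seed(childSeed(seed, region@region_id, labels[k], "founders"))
        founders <- matrix(rbinom(K * m, 1L, rep(p_pop[, k], each = K)), K, m)
        haps[[k]] <- .mosaicHaplotypes(founders, n_hap, region@switch_prob)
    }

    new("HaplotypePanel",
        region_id = region@region_id, chrom = region@chrom,
        positions = region@start + (seq_len(m) - 1L) * region@spacing,
        variant_ids = sprintf("%s_v%04d", region@region_id, seq_len(m)),
        ref = unname(ref), alt = unname(alt),
        p_anc = p_anc, p_pop = p_pop, haplotypes = haps)
}

# Calibrate the logistic intercept by bisection on a fixed simulated pool so
# that the pool prevalence matches the target within tol.
.calibrateIntercept <- function(panels, model, pops, seed,
                                pool_size = 50000L, tol = 0.002) {
    beta <- model@causal_effects
    prev <- model@baseline_prevalence
    if (length(beta) == 0L) return(qlogis(prev))
    n_tot <- sum(vapply(pops, function(p) p@n_cases + p@n_controls, 1L))
    eta <- numeric(0)
    for (k in seq_along(pops)) {
        lab <- pops[[k]]@label
        n_k <- max(2L, round(pool_size *
            (pops[[k]]@n_cases + pops[[k]]@n_controls) / n_tot))
        set.seed(childSeed(seed, lab, "calibration"))
        eta_k <- numeric(n_k)
        for (panel in panels) {
            hit <- intersect(names(beta), panel@variant_ids)
            if (!length(hit)) next
            H <- panel@haplotypes[[lab]]
            j <- match(hit, panel@variant_ids)
            i1 <- sample.int(nrow(H), n_k, replace = TRUE)
            i2 <- sample.int(nrow(H), n_k, replace = TRUE)
            g <- H[i1, j, drop = FALSE] + H[i2, j, drop = FALSE]
            eta_k <- eta_k + as.vector(g %*% beta[hit])
        }
        eta <- c(eta, eta_k)
    }
    ee <- exp(-eta)  # the intercept enters only as a scalar factor
    f <- function(a) mean(1 / (1 + ee * exp(-a))) - prev
    lo <- -30; hi <- 30
    for (it in 1:100) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) hi <- mid else lo <- mid
        if (hi - lo < 1e-10) break
    }
    alpha <- (lo + hi) / 2
    if (abs(f(alpha)) > tol)
        stop("intercept calibration failed: pool prevalence off by ",
             signif(abs(f(alpha)), 3))
    alpha
}

#' Simulate a multiethnic case-control cohort from haplotype panels
#'
#' Individuals are formed by pairing two random haplotypes from their
#' population's pool (independently per region, i.e. regions are unlinked).
#' Disease status is Bernoulli with probability
#' \code{plogis(alpha + sum(beta * g))} over the model's causal variants,
#' where the intercept \code{alpha} is calibrated by bisection on a fixed
#' simulated pool of 50,000 individuals so the pool prevalence matches
#' \code{baseline_prevalence} within 0.002. Cases and controls are
#' rejection-sampled to the exact per-population targets; each case is
#' labeled estrogen-receptor negative with probability
#' \code{er_neg_fraction} (controls are "unknown"). Per-genotype read depth
#' and genotype quality are drawn from the supplied samplers to feed the QC
#' module.
#'
#' @param panels a \linkS4class{HaplotypePanel} or list of panels (one per
#'   region), all covering the same populations
#' @param model a \linkS4class{DiseaseModel}
#' @param pops list of \linkS4class{PopulationSpec} with case/control targets
#' @param seed master seed
#' @param depth_sampler,gq_sampler functions \code{n -> integer vector}
#'   generating per-genotype read depth and quality
#' @param max_attempt_factor sampling is abandoned with a diagnostic error
#'   once more than \code{max_attempt_factor * expected draws} individuals
#'   have been simulated without filling the case quota
#' @param sidechannels generate the DP/GQ assays (disable for simulation
#'   studies that never touch QC)
#' @return a \linkS4class{GenotypeExperiment} with dosage, DP, GQ assays and
#'   the sample sheet in \code{colData}
#' @export
simulateCohort <- function(panels, model, pops, seed,
                           depth_sampler = function(n) rnbinom(n, mu = 30, size = 5),
                           gq_sampler = function(n) pmin(99L, as.integer(rpois(n, 60))),
                           max_attempt_factor = 25, sidechannels = TRUE) {
    if (is(panels, "HaplotypePanel")) panels <- list(panels)
    if (is(pops, "PopulationSpec")) pops <- list(pops)
    stopifnot(is(model, "DiseaseModel"))
    validObject(model)
    beta <- model@causal_effects
    all_ids <- unlist(lapply(panels, function(p) p@variant_ids))
    if (length(beta) && !all(names(beta) %in% all_ids))
        stop("causal variants absent from the panels: ",
             paste(setdiff(names(beta), all_ids), collapse = ", "))

    alpha <- .calibrateIntercept(panels, model, pops, seed)
    prev_hat <- model@baseline_prevalence

    dosage_blocks <- list()
    sheets <- list()
    for (k in seq_along(pops)) {
        pop <- pops[[k]]
        lab <- pop@label
        set.seed(childSeed(seed, lab, "cohort"))
        need_case <- pop@n_cases
        need_ctrl <- pop@n_controls
        got_case <- got_ctrl <- 0L
        keep <- list()  # list of (region -> genotype row block) per batch
        drawn <- 0L
        cap <- ceiling(max_attempt_factor *
                       (need_case / max(prev_hat, 1e-6) + need_ctrl))
        B <- max(1000L, need_case + need_ctrl)
        while (got_case < need_case || got_ctrl < need_ctrl) {
            if (drawn > cap)
                stop(sprintf(
        "could not reach %d cases / %d controls for '%s' after %d draws (pool prevalence ~%.3g); raise baseline_prevalence or max_attempt_factor",
                    need_case, need_ctrl, lab, drawn, prev_hat))
            pair_idx <- lapply(panels, function(panel) {
                H <- panel@haplotypes[[lab]]
                if (is.null(H)) stop("panel lacks population ", lab)
                cbind(sample.int(nrow(H), B, replace = TRUE),
                      sample.int(nrow(H), B, replace = TRUE))
            })
            eta <- rep(alpha, B)
            if (length(beta)) for (r in seq_along(panels)) {
                panel <- panels[[r]]
                hit <- intersect(names(beta), panel@variant_ids)
                if (!length(hit)) next
                H <- panel@haplotypes[[lab]]
                j <- match(hit, panel@variant_ids)
                g <- H[pair_idx[[r]][, 1L], j, drop = FALSE] +
                     H[pair_idx[[r]][, 2L], j, drop = FALSE]
                eta <- eta + as.vector(g %*% beta[hit])
            }
            y <- runif(B) < plogis(eta)
            drawn <- drawn + B
            take_case <- which(y)[seq_len(min(sum(y), need_case - got_case))]
            take_ctrl <- which(!y)[seq_len(min(sum(!y), need_ctrl - got_ctrl))]
            take <- c(take_case, take_ctrl)
            if (length(take)) {
                blocks <- lapply(seq_along(panels), function(r) {
                    H <- panels[[r]]@haplotypes[[lab]]
                    H[pair_idx[[r]][take, 1L], , drop = FALSE] +
                        H[pair_idx[[r]][take, 2L], , drop = FALSE]
                })
                keep[[length(keep) + 1L]] <- list(
                    g = blocks,
                    y = c(rep(1L, length(take_case)), rep(0L, length(take_ctrl))))
                got_case <- got_case + length(take_case)
                got_ctrl <- got_ctrl + length(take_ctrl)
            }
        }
        g_pop <- do.call(rbind, lapply(keep, function(b) do.call(cbind, b$g)))
        y_pop <- unlist(lapply(keep, `[[`, "y"))
        # order cases first, then controls, for readable sample ids
        o <- order(-y_pop)
        g_pop <- g_pop[o, , drop = FALSE]
        y_pop <- y_pop[o]
        er <- rep("unknown", length(y_pop))
        is_case <- y_pop == 1L
        er[is_case] <- ifelse(runif(sum(is_case)) < model@er_neg_fraction,
                              "negative", "positive")
        ids <- sprintf("%s_%04d", lab, seq_along(y_pop))
        dosage_blocks[[lab]] <- t(g_pop)  # variants x samples
        sheets[[lab]] <- DataFrame(
            population = lab,
            status = ifelse(y_pop == 1L, "case", "control"),
            er_status = er, row.names = ids)
    }

    dosage <- do.call(cbind, dosage_blocks)
    storage.mode(dosage) <- "integer"
    rownames(dosage) <- all_ids
    sheet <- do.call(rbind, sheets)
    colnames(dosage) <- rownames(sheet)

    DP <- GQ <- NULL
    if (sidechannels) {
        set.seed(childSeed(seed, "sidechannels"))
        DP <- matrix(as.integer(depth_sampler(length(dosage))), nrow(dosage))
        GQ <- matrix(as.integer(gq_sampler(length(dosage))), nrow(dosage))
        dimnames(DP) <- dimnames(GQ) <- dimnames(dosage)
    }

    gr <- GRanges(
        unlist(lapply(panels, function(p) rep(p@chrom, length(p@positions)))),
        IRanges::IRanges(unlist(lapply(panels, function(p) p@positions)),
                         width = 1L))
    names(gr) <- all_ids
    S4Vectors::mcols(gr)$ref <- unlist(lapply(panels, function(p) p@ref))
    S4Vectors::mcols(gr)$alt <- unlist(lapply(panels, function(p) p@alt))
    S4Vectors::mcols(gr)$region <- unlist(lapply(panels, function(p)
        rep(p@region_id, length(p@positions))))

    GenotypeExperiment(dosage, gr, sheet, DP = DP, GQ = GQ)
}

#' Generate gene intervals within simulated regions
#'
#' Splits each region's span into \code{n_genes} equal slices and places one
#' gene over the central 70\% of each slice, leaving intergenic gaps. Purely
#' structural plumbing so that annotation and gene-based tests have intervals
#' to work with.
#'
#' @param regions list of \linkS4class{RegionSpec}
#' @param n_genes genes per region (recycled); the study the simulator
#'   emulates averaged ~6 genes per region
#' @return a named \link[GenomicRanges]{GRanges} with a \code{gene} metadata
#'   column
#' @export
simulateGeneRanges <- function(regions, n_genes = 6L) {
    if (is(regions, "RegionSpec")) regions <- list(regions)
    n_genes <- rep_len(as.integer(n_genes), length(regions))
    out <- list()
    for (i in seq_along(regions)) {
        r <- regions[[i]]
        span_start <- r@start
        span_end <- r@start + (r@n_variants - 1L) * r@spacing
        width <- max(span_end - span_start + 1L, n_genes[i])
        slice <- width / n_genes[i]
        gs <- floor(span_start + (seq_len(n_genes[i]) - 1) * slice +
                    0.15 * slice)
        ge <- floor(span_start + (seq_len(n_genes[i]) - 1) * slice +
                    0.85 * slice)
        gr <- GRanges(r@chrom, IRanges::IRanges(gs, pmax(ge, gs)))
        names(gr) <- sprintf("%s_gene%d", r@region_id, seq_len(n_genes[i]))
        S4Vectors::mcols(gr)$gene <- names(gr)
        out[[i]] <- gr
    }
    do.call(c, out)
}

#' Assign impact class, gene and damaging flag to variants
#'
#' Each variant receives a functional impact class by a multinomial draw over
#' \code{high} (disruptive), \code{moderate} (nonsynonymous), \code{low}
#' (synonymous) and \code{modifier} (noncoding); a gene by interval
#' containment (variants outside every gene get \code{NA}); and, for
#' moderate-impact variants, a damaging prediction flag with probability
#' \code{damaging_prob}. The default class proportions
#' (81, 1983, 1374, 134092)/137530 reproduce the impact-class spectrum of
#' the deep targeted-sequencing study the simulator emulates.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param genes a named \link[GenomicRanges]{GRanges} of gene intervals (see
#'   \code{\link{simulateGeneRanges}})
#' @param proportions probabilities over the four classes, summing to 1
#' @param damaging_prob probability a nonsynonymous variant is predicted
#'   damaging
#' @param seed master seed
#' @return the GenotypeExperiment with \code{impact}, \code{gene} and
#'   \code{damaging} columns in \code{rowData}
#' @export
assignAnnotations <- function(ge, genes,
        proportions = c(high = 81, moderate = 1983, low = 1374,
                        modifier = 134092) / 137530,
        damaging_prob = 0.5, seed) {
    stopifnot(is(ge, "GenotypeExperiment"))
    classes <- c("high", "moderate", "low", "modifier")
    if (!all(names(proportions) %in% classes) || length(proportions) != 4L)
        stop("proportions must be named high/moderate/low/modifier")
    proportions <- proportions[classes]
    if (abs(sum(proportions) - 1) > 1e-9)
        stop("proportions must sum to 1 (within 1e-9)")
    if (missing(seed)) stop("a seed must be supplied")
    set.seed(childSeed(seed, "annotations"))
    m <- nrow(ge)
    impact <- sample(classes, m, replace = TRUE, prob = proportions)
    hits <- GenomicRanges::findOverlaps(rowRanges(ge), genes, select = "first")
    gene <- ifelse(is.na(hits), NA_character_, names(genes)[hits])
    damaging <- rep(NA, m)
    mod <- impact == "moderate"
    damaging[mod] <- runif(sum(mod)) < damaging_prob
    rowData(ge)$impact <- impact
    rowData(ge)$gene <- gene
    rowData(ge)$damaging <- damaging
    ge
}

#' Simulate one single-causal fine-mapping region
#'
#' Convenience wrapper used for credible-set calibration studies: builds a
#' region of common SNVs with founder-mosaic LD in one population, picks the
#' variant whose panel frequency is closest to \code{target_maf} as the
#' causal SNV with per-allele odds ratio \code{or}, and simulates an exact
#' case/control cohort under the logistic disease model.
#'
#' @param seed master seed for this replicate
#' @param n_variants,founder_haplotypes,switch_prob,divergence_F region and
#'   population knobs (defaults: 200 common SNVs, 30 founders, switch 0.01,
#'   F = 0.01)
#' @param n_cases,n_controls cohort targets
#' @param target_maf,or causal-variant frequency and per-allele odds ratio
#' @param prevalence baseline disease prevalence
#' @return list with elements \code{ge} (the cohort), \code{causal}
#'   (causal variant id) and \code{panel}
#' @export
simulateCausalRegion <- function(seed, n_variants = 200L,
                                 founder_haplotypes = 30L,
                                 switch_prob = 0.01, divergence_F = 0.01,
                                 n_cases = 2000L, n_controls = 2000L,
                                 target_maf = 0.2, or = 1.5,
                                 prevalence = 0.1) {
    region <- RegionSpec("R1", n_variants,
                         founder_haplotypes = founder_haplotypes,
                         switch_prob = switch_prob, common_fraction = 1)
    pop <- PopulationSpec("POP1", n_cases, n_controls,
                          divergence_F = divergence_F)
    panel <- simulatePanel(region, list(pop), seed = seed)
    f <- colMeans(panel@haplotypes[["POP1"]])
    maf <- pmin(f, 1 - f)
    causal <- panel@variant_ids[which.min(abs(maf - target_maf))]
    eff <- log(or); names(eff) <- causal
    model <- DiseaseModel(baseline_prevalence = prevalence,
                          causal_effects = eff)
    ge <- simulateCohort(panel, model, list(pop), seed = seed,
                         sidechannels = FALSE)
    list(ge = ge, causal = causal, panel = panel)
}
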