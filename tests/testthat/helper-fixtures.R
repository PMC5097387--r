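# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the package's own writers in the IO tests.

suppressPackageStartupMessages({
    library(SummarizedExperiment)  # rowData/colData/assay in test bodies
})

# A small hand-crafted experiment with known dosages and side-channels.
toyGE <- function(dosage, DP = NULL, GQ = NULL, samples = NULL,
                  chrom = "chr1", pos = NULL, region = "R1") {
    m <- nrow(dosage); n <- ncol(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- sprintf("v%03d", seq_len(m))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("s%03d", seq_len(n))
    if (is.null(pos)) pos <- seq_len(m) * 100L
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(gr) <- rownames(dosage)
    S4Vectors::mcols(gr)$ref <- rep("A", m)
    S4Vectors::mcols(gr)$alt <- rep("G", m)
    S4Vectors::mcols(gr)$region <- rep(region, m)
    if (is.null(samples))
        samples <- S4Vectors::DataFrame(
            population = rep("POP1", n),
            status = rep(c("case", "control"), length.out = n),
            er_status = rep("unknown", n),
            row.names = colnames(dosage))
    GenotypeExperiment(dosage, gr, samples, DP = DP, GQ = GQ)
}

# Balanced case-control cohort with independent genotypes at given MAFs and a
# logistic phenotype; used for test calibration checks that do not need the
# founder-mosaic machinery.
independentCohort <- function(n_cases, n_controls, mafs, beta = NULL,
                              seed = 1) {
    set.seed(seed)
    n <- n_cases + n_controls
    m <- length(mafs)
    d <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
    eta <- if (is.null(beta)) rep(0, n) else as.vector(d %*% beta)
    # prospective sampling, then trim to exact counts
    repeat {
        y <- rbinom(n, 1L, plogis(eta))
        if (sum(y) >= n_cases && sum(1 - y) >= n_controls) break
        eta <- eta + 0.05 * (n_cases - sum(y)) / n
    }
    keep <- c(which(y == 1L)[seq_len(n_cases)],
              which(y == 0L)[seq_len(n_controls)])
    d <- t(d[keep, , drop = FALSE])
    rownames(d) <- sprintf("v%04d", seq_len(m))
    colnames(d) <- sprintf("s%04d", seq_along(keep))
    storage.mode(d) <- "integer"
    ge <- toyGE(d)
    SummarizedExperiment::colData(ge)$status <-
        c(rep("case", n_cases), rep("control", n_controls))
    ge
}

# A cohort with an annotated gene of rare variants, built directly.
rareGeneGE <- function(n = 400L, m_rare = 5L, rare_maf = 0.004,
                       seed = 1, beta = 0, extra = TRUE) {
    set.seed(seed)
    mafs <- rep(rare_maf, m_rare)
    d <- matrix(rbinom(n * m_rare, 2L, rep(mafs, each = n)), n, m_rare)
    labels <- sprintf("r%02d", seq_len(m_rare))
    if (extra) {  # a common nonsynonymous, a rare synonymous, two modifiers
        d <- cbind(d, rbinom(n, 2L, 0.3), rbinom(n, 2L, 0.004),
                   rbinom(n, 2L, 0.1), rbinom(n, 2L, 0.004))
        labels <- c(labels, "common_ns", "rare_syn", "mod1", "mod2")
    }
    d <- t(d)
    storage.mode(d) <- "integer"
    rownames(d) <- labels
    colnames(d) <- sprintf("s%04d", seq_len(n))
    eta <- beta * colSums(d[seq_len(m_rare), , drop = FALSE])
    y <- rbinom(n, 1L, plogis(eta - 0.1))
    ge <- toyGE(d)
    SummarizedExperiment::colData(ge)$status <-
        ifelse(y == 1L, "case", "control")
    rowData(ge)$gene <- c(rep("G1", m_rare),
                          if (extra) c("G1", "G1", NA, "G2"))
    rowData(ge)$impact <- c(rep("moderate", m_rare),
                            if (extra) c("moderate", "low", "modifier",
                                         "modifier"))
    rowData(ge)$damaging <- c(rep(c(TRUE, FALSE), length.out = m_rare),
                              if (extra) rep(NA, 4))
    ge
}

# Exact-enumeration oracle for the Hardy-Weinberg conditional test, written
# independently of the package routine: it computes each heterozygote count's
# probability from the closed-form conditional distribution (with explicit
# factorial normalization) and sums those no more probable than observed.
hweEnumOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    r <- min(nA, 2 * n - nA)
    if (r == 0) return(1)
    hets <- seq(r %% 2, r, by = 2)
    logp <- lfactorial(n) + lfactorial(r) + lfactorial(2 * n - r) -
        lfactorial(2 * n) + hets * log(2) -
        (lfactorial((r - hets) / 2) + lfactorial(hets) +
         lfactorial(n - (r + hets) / 2))
    p <- exp(logp)
    obs <- p[match(nAa, hets)]
    min(1, sum(p[p <= obs * (1 + 1e-12)]))
}
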