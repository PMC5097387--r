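test_that("variant-set selection applies gene, impact, rarity and damaging rules", {
    ge <- rareGeneGE(seed = 3)
    set <- selectVariantSet(ge, "G1", maf_max = 0.05)
    # rare nonsynonymous members only: no common nonsyn (MAF 0.3), no
    # synonymous, no modifier
    expect_setequal(set@variants, sprintf("r%02d", 1:5))
    expect_identical(set@rule, "nonsyn_rare")

    dmg <- selectVariantSet(ge, "G1", maf_max = 0.05, damaging_only = TRUE)
    expect_setequal(dmg@variants, c("r01", "r03", "r05"))
    expect_identical(dmg@rule, "nonsyn_rare_damaging")

    expect_error(selectVariantSet(ge, "NOPE"), "unknown gene")

    # a variant at exactly the MAF threshold is excluded (strict <)
    d <- rbind(vx = c(rep(0L, 99), 1L), vy = c(rep(0L, 98), 1L, 1L))
    colnames(d) <- sprintf("s%03d", 1:100)
    ge2 <- toyGE(d)
    rowData(ge2)$gene <- c("G", "G")
    rowData(ge2)$impact <- c("moderate", "moderate")
    rowData(ge2)$damaging <- c(TRUE, TRUE)
    # vx MAF = 0.005 exactly, vy MAF = 0.01
    expect_identical(selectVariantSet(ge2, "G", maf_max = 0.005)@variants,
                     character(0))
    expect_identical(selectVariantSet(ge2, "G", maf_max = 0.011)@variants,
                     c("vx", "vy"))
})

test_that("carrier proportions count subjects with any minor allele", {
    d <- matrix(0L, 3, 10, dimnames = list(c("a", "b", "c"),
                                           sprintf("s%02d", 1:10)))
    d["a", 1] <- 1L; d["b", 2] <- 2L; d["c", 2:3] <- 1L
    ge <- toyGE(d)
    rowData(ge)$gene <- rep("G", 3)
    rowData(ge)$impact <- rep("moderate", 3)
    rowData(ge)$damaging <- rep(TRUE, 3)
    set <- selectVariantSet(ge, "G", maf_max = 0.4)
    expect_equal(carrierProportion(ge, set), 0.3)  # 3 carriers of 10

    # everyone carries
    d2 <- matrix(1L, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
    ge2 <- toyGE(d2)
    set2 <- new("VariantSet", gene = "G", variants = c("a", "b"),
                rule = "nonsyn_rare", maf_max = 1, pop_counts = integer(0))
    expect_equal(carrierProportion(ge2, set2), 1.0)

    # singleton het among 100
    d3 <- matrix(0L, 1, 100, dimnames = list("a", sprintf("s%03d", 1:100)))
    d3[1, 7] <- 1L
    set3 <- new("VariantSet", gene = "G", variants = "a",
                rule = "nonsyn_rare", maf_max = 1, pop_counts = integer(0))
    expect_equal(carrierProportion(toyGE(d3), set3), 0.01)

    # samples missing at every member leave the denominator
    d4 <- d
    d4[, 10] <- NA
    expect_equal(carrierProportion(toyGE(d4), set), 3 / 9)
    expect_error(carrierProportion(ge, new("VariantSet", gene = "G",
        variants = character(0), rule = "nonsyn_rare", maf_max = 1,
        pop_counts = integer(0))), "empty")
})

test_that("the burden test reduces to the single-variant fit on singletons", {
    ge <- rareGeneGE(n = 600L, seed = 5, rare_maf = 0.02, extra = FALSE,
                     m_rare = 1L)
    set <- selectVariantSet(ge, "G1", maf_max = 0.05)
    expect_length(set@variants, 1L)
    bt <- burdenTest(ge, set)
    ft <- fitLogistic(dosage(ge)[set@variants, ], phenotypeVector(ge))
    expect_equal(bt$p, ft$p, tolerance = 1e-10)
    expect_equal(bt$beta, ft$beta, tolerance = 1e-10)
})

test_that("a crafted case-enriched carrier gene gives a positive, significant burden", {
    # eight of nine carriers are cases (exactly all-case carriers would be
    # quasi-complete separation, which the Wald burden fit flags
    # not-evaluable by contract)
    d <- matrix(0L, 3, 40, dimnames = list(c("a", "b", "c"),
                                           sprintf("s%02d", 1:40)))
    d["a", 1:4] <- 1L; d["b", 5:7] <- 1L; d["c", c(8, 21)] <- 1L
    ge <- toyGE(d)
    SummarizedExperiment::colData(ge)$status <-
        c(rep("case", 20), rep("control", 20))
    rowData(ge)$gene <- rep("G", 3)
    rowData(ge)$impact <- rep("moderate", 3)
    rowData(ge)$damaging <- rep(TRUE, 3)
    set <- selectVariantSet(ge, "G", maf_max = 0.2)
    bt <- burdenTest(ge, set)
    expect_true(bt$evaluable)
    expect_gt(bt$or, 1)
    expect_lt(bt$p, 0.05)
    # flipping the phenotype flips the sign exactly
    flip <- ge
    SummarizedExperiment::colData(flip)$status <-
        rev(colData(ge)$status)
    bf <- burdenTest(flip, set)
    expect_equal(bf$beta, -bt$beta, tolerance = 1e-8)
    # zero-variance burden is not evaluable
    null_set <- set
    d0 <- d; d0[] <- 0L
    ge0 <- toyGE(d0)
    SummarizedExperiment::colData(ge0)$status <- colData(ge)$status
    rowData(ge0)$gene <- rep("G", 3)
    rowData(ge0)$impact <- rep("moderate", 3)
    rowData(ge0)$damaging <- rep(TRUE, 3)
    expect_false(burdenTest(ge0, null_set)$evaluable)
})

test_that("SKAT reduces to the score test on singleton sets", {
    ge <- rareGeneGE(n = 600L, seed = 7, rare_maf = 0.05, extra = FALSE,
                     m_rare = 1L)
    set <- selectVariantSet(ge, "G1", maf_max = 0.2)
    st <- skatTest(ge, set)
    # independent score test: S / sqrt(g' P g) is standard normal
    y <- phenotypeVector(ge)
    g <- as.numeric(dosage(ge)[set@variants, ])
    mu <- mean(y)
    S <- sum(g * (y - mu))
    v <- mu * (1 - mu)
    info <- v * sum((g - mean(g))^2)
    p_score <- 2 * pnorm(-abs(S / sqrt(info)))
    expect_equal(st$p, p_score, tolerance = 1e-4)
    expect_gte(st$q_stat, 0)
})

test_that("SKAT matches a permutation oracle on a toy gene", {
    ge <- rareGeneGE(n = 200L, m_rare = 5L, rare_maf = 0.08, seed = 3,
                     extra = FALSE)
    set <- selectVariantSet(ge, "G1", maf_max = 0.25)
    st <- skatTest(ge, set)
    # permutation oracle: intercept-only null, so permuting phenotypes keeps
    # mu constant and the statistic is a pure cross-product
    y <- phenotypeVector(ge)
    G <- t(dosage(ge)[set@variants, ])
    maf <- colMeans(G) / 2
    w2 <- dbeta(maf, 1, 25)^2
    mu <- mean(y)
    n_perm <- 10000L
    set.seed(2024)
    Yp <- replicate(n_perm, sample(y)) - mu
    Sp <- crossprod(G, Yp)                 # m x n_perm
    Qp <- colSums(w2 * Sp^2)
    q_obs <- sum(w2 * as.vector(crossprod(G, y - mu))^2)
    p_perm <- (sum(Qp >= q_obs) + 1) / (n_perm + 1)
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(st$p - p_perm), 3 * se)
})

test_that("SKAT is invariant to which allele is labeled minor", {
    ge <- rareGeneGE(n = 300L, m_rare = 4L, rare_maf = 0.04, seed = 13,
                     extra = FALSE)
    set <- selectVariantSet(ge, "G1", maf_max = 0.1)
    st <- skatTest(ge, set)
    flipped <- ge
    d <- dosage(ge)
    d[set@variants[2], ] <- 2L - d[set@variants[2], ]
    SummarizedExperiment::assay(flipped, "dosage") <- d
    st2 <- skatTest(flipped, set)
    expect_equal(st2$q_stat, st$q_stat, tolerance = 1e-10)
    expect_equal(st2$p, st$p, tolerance = 1e-8)
})

test_that("burden meta-analysis combines inverse-variance weights", {
    rows <- rbind(
        data.frame(gene = "G", scope = "A", rule = "nonsyn_rare",
                   n_variants = 4L, carrier_prop = 0.02, test = "BURDEN",
                   beta = 0.2, se = 0.1, or = exp(0.2), ci_lo = 1,
                   ci_hi = 1.5, p = 0.04, q_stat = NA, evaluable = TRUE),
        data.frame(gene = "G", scope = "B", rule = "nonsyn_rare",
                   n_variants = 4L, carrier_prop = 0.03, test = "BURDEN",
                   beta = 0.4, se = 0.2, or = exp(0.4), ci_lo = 1,
                   ci_hi = 2.2, p = 0.05, q_stat = NA, evaluable = TRUE))
    mb <- metaBurden(rows)
    expect_equal(mb$beta, 0.24, tolerance = 1e-10)
    expect_equal(mb$se, 0.08944, tolerance = 1e-4)
    one <- metaBurden(rows[1, ])
    expect_equal(one$beta, 0.2)
    rows$evaluable <- FALSE
    expect_error(metaBurden(rows), "no evaluable")
})

test_that("Hom-Meta-SKAT equals SKAT for one cohort and under split-merge", {
    ge <- rareGeneGE(n = 500L, m_rare = 6L, rare_maf = 0.03, seed = 17,
                     extra = FALSE)
    set <- selectVariantSet(ge, "G1", maf_max = 0.1)
    st <- skatTest(ge, set)
    comp <- skatComponents(ge, set)
    mt <- metaSkatHom(list(comp), set)
    expect_equal(mt$p, st$p, tolerance = 1e-12)
    expect_equal(mt$q_stat, st$q_stat, tolerance = 1e-12)

    # splitting one cohort in half at random and recombining approximates
    # the unsplit analysis
    ratios <- vapply(1:20, function(s) {
        g2 <- rareGeneGE(n = 600L, m_rare = 6L, rare_maf = 0.03,
                         seed = 100 + s, extra = FALSE, beta = 0.4)
        s2 <- selectVariantSet(g2, "G1", maf_max = 0.1)
        if (!length(s2@variants)) return(NA_real_)
        full <- skatTest(g2, s2)
        set.seed(s)
        half <- sample(ncol(g2), ncol(g2) / 2)
        cA <- skatComponents(g2[, half], s2)
        cB <- skatComponents(g2[, -half], s2)
        meta <- metaSkatHom(list(cA, cB), s2)
        log10(meta$p) - log10(full$p)
    }, 1)
    expect_lt(max(abs(ratios), na.rm = TRUE), 0.2)
})

test_that("injected rare-variant risk is detected by both tests", {
    # 30% of a gene's rare variants carry beta = log(3); combined carrier
    # frequency ~5%; both tests should reject at alpha = .05 in most seeds
    rejections <- vapply(1:40, function(s) {
        set.seed(s)
        n <- 2000L
        m <- 10L
        mafs <- rep(0.0052, m)
        G <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
        beta <- c(rep(log(3), 3), rep(0, 7))
        y <- rbinom(n, 1L, plogis(as.vector(G %*% beta) - 0.2))
        d <- t(G); storage.mode(d) <- "integer"
        rownames(d) <- sprintf("r%02d", 1:m)
        colnames(d) <- sprintf("s%04d", 1:n)
        ge <- toyGE(d)
        SummarizedExperiment::colData(ge)$status <-
            ifelse(y == 1, "case", "control")
        rowData(ge)$gene <- rep("G", m)
        rowData(ge)$impact <- rep("moderate", m)
        rowData(ge)$damaging <- rep(TRUE, m)
        set <- selectVariantSet(ge, "G", maf_max = 0.02)
        c(burden = burdenTest(ge, set)$p < 0.05,
          skat = skatTest(ge, set)$p < 0.05)
    }, c(burden = TRUE, skat = TRUE))
    expect_gt(mean(rejections["burden", ]), 0.5)
    expect_gt(mean(rejections["skat", ]), 0.5)
})

test_that("the gene scan assembles per-population and meta rows", {
    region <- RegionSpec("r", 400L, founder_haplotypes = 400L,
                         switch_prob = 0.5, common_fraction = 0.4,
                         start = 1e6L, spacing = 50L)
    pops <- list(PopulationSpec("A", 150L, 150L),
                 PopulationSpec("B", 150L, 150L))
    panel <- simulatePanel(region, pops, seed = 23)
    ge <- simulateCohort(panel, DiseaseModel(baseline_prevalence = 0.3),
                         pops, seed = 23, sidechannels = FALSE)
    genes <- simulateGeneRanges(region, n_genes = 3L)
    ge <- assignAnnotations(ge, genes, proportions = c(
        high = 0.01, moderate = 0.4, low = 0.2, modifier = 0.39), seed = 23)
    suppressMessages(res <- rareVariantScan(ge, maf_max = 0.01))
    expect_true(all(c("meta", "A", "B") %in% res$scope))
    expect_true(all(res$p[res$evaluable] > 0 & res$p[res$evaluable] <= 1))
    expect_true(is.logical(res$significant))
    # result table round-trips through the serializer
    path <- tempfile(fileext = ".tsv")
    writeResults(res, path)
    back <- readResults(path)
    expect_equal(nrow(back), nrow(res))
    expect_equal(back$p, res$p, tolerance = 1e-12)
})
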