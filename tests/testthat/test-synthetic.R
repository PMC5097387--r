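test_that("specification constructors enforce their invariants", {
    expect_error(RegionSpec("r", 0), "n_variants")
    expect_error(RegionSpec("r", 10, founder_haplotypes = 1), "founder")
    expect_error(RegionSpec("r", 10, switch_prob = 1.2), "switch_prob")
    expect_error(PopulationSpec("p", 1, 0), "n_cases")
    expect_error(PopulationSpec("p", 5, 5, divergence_F = 0), "divergence_F")
    expect_error(DiseaseModel(baseline_prevalence = 1.2), "prevalence")
    expect_error(DiseaseModel(causal_effects = c(0.5)), "named")
    pops <- defaultPopulations()
    expect_equal(sum(vapply(pops, function(p) p@n_cases, 1L)), 2288L)
    expect_equal(sum(vapply(pops, function(p) p@n_controls, 1L)), 2323L)
})

test_that("zero switch probability yields pure founder copies", {
    region <- RegionSpec("r", 40L, founder_haplotypes = 5L,
                         switch_prob = 0, common_fraction = 1)
    pop <- PopulationSpec("A", 50L, 50L)
    panel <- simulatePanel(region, pop, seed = 7, n_haplotypes = 300L)
    H <- panel@haplotypes[["A"]]
    # every sampled haplotype must be one of at most 5 distinct founder rows
    expect_lte(nrow(unique(H)), 5L)
})

test_that("population frequencies approach the ancestral ones as F -> 0", {
    region <- RegionSpec("r", 1000L, founder_haplotypes = 100L,
                         common_fraction = 1)
    pop <- PopulationSpec("A", 5L, 5L, divergence_F = 1e-6)
    panel <- simulatePanel(region, pop, seed = 3, n_haplotypes = 10L)
    expect_lt(max(abs(panel@p_pop[, "A"] - panel@p_anc)), 1e-2)
})

test_that("panel frequencies converge to the population frequencies", {
    # both the founder pool and the sampled haplotypes must be large for the
    # realized frequency to approach p_k
    region <- RegionSpec("r", 400L, founder_haplotypes = 5000L,
                         common_fraction = 1)
    pop <- PopulationSpec("A", 10L, 10L, divergence_F = 0.01)
    panel <- simulatePanel(region, pop, seed = 11, n_haplotypes = 20000L)
    f <- colMeans(panel@haplotypes[["A"]])
    expect_lt(mean(abs(f - panel@p_pop[, "A"])), 0.01)
})

test_that("realized rare fraction matches an independent re-simulation oracle", {
    # implementation run at the spectrum defaults
    m <- 10000L
    pops <- list(PopulationSpec("A", 125L, 125L, divergence_F = 0.15),
                 PopulationSpec("B", 125L, 125L, divergence_F = 0.12),
                 PopulationSpec("C", 125L, 125L, divergence_F = 0.08),
                 PopulationSpec("D", 125L, 125L, divergence_F = 0.05))
    region <- RegionSpec("r", m, founder_haplotypes = 200L,
                         common_fraction = 0.128)
    panel <- simulatePanel(region, pops, seed = 5)
    pooled <- colMeans(do.call(rbind, panel@haplotypes))
    frac_impl <- mean(pmin(pooled, 1 - pooled) < 0.005)

    # oracle: independent sitewise Monte-Carlo re-simulation of the same
    # generative law (mixture frequencies -> Balding-Nichols -> founder pool
    # -> multinomial founder usage), run over 10 seeds. Sitewise the mosaic
    # process makes each haplotype copy a uniformly chosen founder,
    # independently across haplotypes, which is what is simulated here.
    K <- 200L
    Fs <- c(0.15, 0.12, 0.08, 0.05)
    n_hap <- 500L
    oracle_one <- function(seed) {
        set.seed(seed)
        lo <- 1 / (4 * K)
        common <- runif(m) < 0.128
        p <- ifelse(common, runif(m, 0.005, 0.5), lo * (0.005 / lo)^runif(m))
        tot <- numeric(m)
        for (F in Fs) {
            pk <- rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
            founders <- matrix(rbinom(K * m, 1, rep(pk, each = K)), K, m)
            usage <- stats::rmultinom(m, n_hap, rep(1 / K, K))
            tot <- tot + colSums(founders * usage)
        }
        fr <- tot / (4 * n_hap)
        mean(pmin(fr, 1 - fr) < 0.005)
    }
    frac_oracle <- mean(vapply(100 + 1:10, oracle_one, 1))
    expect_lt(abs(frac_impl - frac_oracle), 0.03)
})

test_that("adjacent-variant LD decreases as the switch probability grows", {
    mean_r2 <- function(sp) {
        vals <- vapply(1:50, function(s) {
            region <- RegionSpec("r", 50L, founder_haplotypes = 10L,
                                 switch_prob = sp, common_fraction = 1)
            panel <- simulatePanel(region, PopulationSpec("A", 5L, 5L),
                                   seed = s, n_haplotypes = 400L)
            H <- panel@haplotypes[["A"]]
            keep <- apply(H, 2L, stats::var) > 0
            H <- H[, keep, drop = FALSE]
            r <- diag(cor(H[, -ncol(H)], H[, -1]))
            mean(r^2, na.rm = TRUE)
        }, 1)
        mean(vals)
    }
    r2 <- vapply(c(0.001, 0.01, 0.1), mean_r2, 1)
    expect_true(r2[1] > r2[2] && r2[2] > r2[3])
})

test_that("population-private polymorphism increases with divergence", {
    # measured on a common-variant spectrum with well-sampled pools, where
    # privateness reflects drift rather than the sampling sparsity of rare
    # variants (which saturates the private fraction at any F)
    frac_private <- function(F) {
        region <- RegionSpec("r", 2000L, founder_haplotypes = 200L,
                             common_fraction = 1)
        pops <- list(PopulationSpec("A", 50L, 50L, divergence_F = F),
                     PopulationSpec("B", 50L, 50L, divergence_F = F))
        panel <- simulatePanel(region, pops, seed = 17, n_haplotypes = 2000L)
        fa <- colMeans(panel@haplotypes[["A"]])
        fb <- colMeans(panel@haplotypes[["B"]])
        polyA <- fa > 0 & fa < 1
        polyB <- fb > 0 & fb < 1
        sum(xor(polyA, polyB)) / sum(polyA | polyB)
    }
    expect_lt(frac_private(0.01), frac_private(0.1))
})

test_that("cohort sampling hits exact targets and is reproducible", {
    region <- RegionSpec("r", 30L, founder_haplotypes = 50L,
                         common_fraction = 1)
    pops <- list(PopulationSpec("A", 100L, 100L),
                 PopulationSpec("B", 60L, 40L))
    panel <- simulatePanel(region, pops, seed = 2)
    model <- DiseaseModel(baseline_prevalence = 0.2)
    ge1 <- simulateCohort(panel, model, pops, seed = 9)
    ge2 <- simulateCohort(panel, model, pops, seed = 9)
    expect_identical(dosage(ge1), dosage(ge2))
    cd <- colData(ge1)
    expect_equal(sum(cd$population == "A" & cd$status == "case"), 100L)
    expect_equal(sum(cd$population == "A" & cd$status == "control"), 100L)
    expect_equal(sum(cd$population == "B" & cd$status == "case"), 60L)
    expect_equal(sum(cd$population == "B" & cd$status == "control"), 40L)
    expect_true(all(cd$er_status[cd$status == "control"] == "unknown"))
    expect_true(all(cd$er_status[cd$status == "case"] %in%
                    c("positive", "negative")))
    # DP/GQ side-channels populated
    expect_equal(dim(readDepth(ge1)), dim(dosage(ge1)))
    expect_equal(dim(genoQual(ge1)), dim(dosage(ge1)))
})

test_that("an unattainable case quota fails with a diagnostic", {
    region <- RegionSpec("r", 10L, founder_haplotypes = 50L,
                         common_fraction = 1)
    pop <- PopulationSpec("A", 200L, 10L)
    panel <- simulatePanel(region, pop, seed = 4)
    model <- DiseaseModel(baseline_prevalence = 0.001)
    expect_error(
        simulateCohort(panel, model, list(pop), seed = 4,
                       max_attempt_factor = 0.01),
        "could not reach")
})

test_that("null cohorts show standard-normal association z-scores", {
    region <- RegionSpec("r", 1000L, founder_haplotypes = 1000L,
                         switch_prob = 0.5, common_fraction = 1)
    pop <- PopulationSpec("A", 400L, 400L)
    panel <- simulatePanel(region, pop, seed = 21)
    ge <- simulateCohort(panel, DiseaseModel(baseline_prevalence = 0.3),
                         list(pop), seed = 21, sidechannels = FALSE)
    sc <- scanRegion(ge, maf_min = 0.005)
    z <- sc$z[sc$evaluable]
    expect_gt(length(z), 800)
    # perfect-LD duplicates create tied z values; the KS statistic is still
    # the right summary of the marginal law
    ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
    expect_gt(ks$p.value, 0.01)
})

test_that("a known causal effect is recovered by refitting", {
    betas <- vapply(1:20, function(s) {
        r <- simulateCausalRegion(seed = s, n_variants = 20L,
                                  founder_haplotypes = 100L,
                                  switch_prob = 0.5)
        y <- phenotypeVector(r$ge)
        fitLogistic(dosage(r$ge)[r$causal, ], y)$beta
    }, 1)
    expect_lt(abs(mean(betas) - log(1.5)), 0.1)
})

test_that("annotations follow the requested proportions and gene intervals", {
    region <- RegionSpec("r", 3000L, founder_haplotypes = 100L,
                         common_fraction = 1, start = 10000L, spacing = 10L)
    pop <- PopulationSpec("A", 30L, 30L)
    panel <- simulatePanel(region, pop, seed = 6)
    ge <- simulateCohort(panel, DiseaseModel(baseline_prevalence = 0.3),
                         list(pop), seed = 6, sidechannels = FALSE)
    genes <- simulateGeneRanges(region, n_genes = 4L)

    expect_error(assignAnnotations(ge, genes, proportions = c(
        high = 0.3, moderate = 0.3, low = 0.3, modifier = 0.2), seed = 1),
        "sum to 1")

    all_mod <- assignAnnotations(ge, genes, proportions = c(
        high = 0, moderate = 0, low = 0, modifier = 1), seed = 1)
    expect_true(all(rowData(all_mod)$impact == "modifier"))

    # realized default-proportion class counts within the exact multinomial
    # 99% envelope (Bonferroni-split binomial marginals)
    props <- c(high = 81, moderate = 1983, low = 1374, modifier = 134092) /
        137530
    ann <- assignAnnotations(ge, genes, proportions = props,
                             damaging_prob = 0.5, seed = 123)
    counts <- table(factor(rowData(ann)$impact,
                           levels = names(props)))
    for (k in names(props)) {
        lo <- stats::qbinom(0.00125, nrow(ge), props[[k]])
        hi <- stats::qbinom(0.99875, nrow(ge), props[[k]])
        expect_gte(counts[[k]], lo)
        expect_lte(counts[[k]], hi)
    }
    # gene assignment respects interval containment; outside -> NA
    rd <- rowData(ann)
    pos <- GenomicRanges::start(rowRanges(ann))
    inside <- !is.na(rd$gene)
    ov <- GenomicRanges::findOverlaps(rowRanges(ann), genes, select = "first")
    expect_identical(inside, !is.na(ov))
    # damaging flags only on moderate variants
    expect_true(all(is.na(rd$damaging[rd$impact != "moderate"])))
    expect_false(anyNA(rd$damaging[rd$impact == "moderate"]))
})
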