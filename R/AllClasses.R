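#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData rowData<- rowRanges colData colData<-
#' @importFrom GenomicRanges GRanges
NULL

# ---------------------------------------------------------------------------
# GenotypeExperiment: the central container.
#
# A RangedSummarizedExperiment whose rows are SNVs and columns are subjects.
# Assays:
#   dosage -- alt-allele count 0/1/2, NA = missing call
#   DP     -- per-genotype read depth (optional)
#   GQ     -- per-genotype quality (optional)
# rowData carries ref/alt alleles, region id and (after annotation) gene,
# impact class and damaging flag; colData is the sample sheet (population,
# status, er_status, principal components).
# ---------------------------------------------------------------------------

#' GenotypeExperiment: SNV dosages with depth/quality side-channels
#'
#' An S4 container (extending \linkS4class{RangedSummarizedExperiment}) for
#' targeted-sequencing genotype data: a variants-by-samples dosage matrix with
#' optional per-genotype read depth (\code{DP}) and genotype quality
#' (\code{GQ}) assays, variant metadata on the rows and the sample sheet on
#' the columns.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; no extra slots.
#' @aliases GenotypeExperiment-class
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- NULL
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (length(d) && !all(is.na(d))) {
            r <- range(d, na.rm = TRUE)
            if (r[1] < 0 || r[2] > 2 ||
                (!is.integer(d) && any(d != floor(d), na.rm = TRUE)))
                msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
        }
    }
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "variants must be named (unique variant ids)")
    if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
        msg <- c(msg, "variant ids must be unique")
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    st <- colData(object)$status
    if (!is.null(st) && !all(st %in% c("case", "control")))
        msg <- c(msg, "colData$status must be 'case' or 'control'")
    er <- colData(object)$er_status
    if (!is.null(er) && !all(er %in% c("positive", "negative", "unknown")))
        msg <- c(msg, "colData$er_status must be positive/negative/unknown")
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# Simulation specifications
# ---------------------------------------------------------------------------

#' Region specification for the genotype simulator
#'
#' Describes one sequenced region: its size, the founder haplotype pool that
#' controls linkage disequilibrium, the per-step recombination (founder
#' switch) probability and the fraction of variants drawn from the common
#' allele-frequency range.
#'
#' @aliases RegionSpec-class
#' @exportClass RegionSpec
setClass("RegionSpec", representation(
    region_id = "character",
    chrom = "character",
    start = "integer",
    spacing = "integer",
    n_variants = "integer",
    founder_haplotypes = "integer",
    switch_prob = "numeric",
    common_fraction = "numeric"))

setValidity("RegionSpec", function(object) {
    msg <- NULL
    if (object@n_variants < 1L) msg <- c(msg, "n_variants must be >= 1")
    if (object@founder_haplotypes < 2L)
        msg <- c(msg, "founder_haplotypes must be >= 2")
    if (object@switch_prob < 0 || object@switch_prob > 1)
        msg <- c(msg, "switch_prob must be in [0, 1]")
    if (object@common_fraction < 0 || object@common_fraction > 1)
        msg <- c(msg, "common_fraction must be in [0, 1]")
    if (object@spacing < 1L) msg <- c(msg, "spacing must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Population specification for the genotype simulator
#'
#' One ancestry stratum: its case/control targets, the Balding-Nichols
#' divergence parameter F controlling drift from the ancestral allele
#' frequencies, and the expected per-region count of population-private rare
#' variants.
#'
#' @aliases PopulationSpec-class
#' @exportClass PopulationSpec
setClass("PopulationSpec", representation(
    label = "character",
    n_cases = "integer",
    n_controls = "integer",
    divergence_F = "numeric",
    private_rare_rate = "numeric"))

setValidity("PopulationSpec", function(object) {
    msg <- NULL
    if (object@n_cases + object@n_controls < 2L)
        msg <- c(msg, "n_cases + n_controls must be >= 2")
    if (object@divergence_F <= 0 || object@divergence_F >= 1)
        msg <- c(msg, "divergence_F must be in (0, 1)")
    if (object@private_rare_rate < 0)
        msg <- c(msg, "private_rare_rate must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Logistic disease model for the genotype simulator
#'
#' Baseline disease prevalence, per-allele log odds ratios of the causal SNVs
#' (named by variant id) and the probability that a case is estrogen-receptor
#' negative.
#'
#' @aliases DiseaseModel-class
#' @exportClass DiseaseModel
setClass("DiseaseModel", representation(
    baseline_prevalence = "numeric",
    causal_effects = "numeric",
    er_neg_fraction = "numeric"))

setValidity("DiseaseModel", function(object) {
    msg <- NULL
    if (object@baseline_prevalence <= 0 || object@baseline_prevalence >= 1)
        msg <- c(msg, "baseline_prevalence must be in (0, 1)")
    if (length(object@causal_effects) && !all(is.finite(object@causal_effects)))
        msg <- c(msg, "causal effects must be finite")
    if (length(object@causal_effects) &&
        is.null(names(object@causal_effects)))
        msg <- c(msg, "causal_effects must be named by variant id")
    if (object@er_neg_fraction < 0 || object@er_neg_fraction > 1)
        msg <- c(msg, "er_neg_fraction must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Per-population haplotype panel
#'
#' Binary haplotype pools (one matrix of phased haplotypes per population,
#' haplotypes in rows, variants in columns), the ancestral allele frequencies
#' and the realized per-population frequencies, plus the variant coordinates
#' and alleles needed to emit VCF.
#'
#' @aliases HaplotypePanel-class
#' @exportClass HaplotypePanel
setClass("HaplotypePanel", representation(
    region_id = "character",
    chrom = "character",
    positions = "integer",
    variant_ids = "character",
    ref = "character",
    alt = "character",
    p_anc = "numeric",
    p_pop = "matrix",
    haplotypes = "list"))

setValidity("HaplotypePanel", function(object) {
    msg <- NULL
    m <- length(object@p_anc)
    if (length(object@positions) != m || length(object@variant_ids) != m)
        msg <- c(msg, "positions/variant_ids length must match p_anc")
    if (nrow(object@p_pop) != m)
        msg <- c(msg, "p_pop must have one row per variant")
    for (h in object@haplotypes) {
        if (ncol(h) != m) msg <- c(msg, "haplotype matrices need m columns")
        if (length(h)) {
            r <- range(h)
            if (r[1] < 0 || r[2] > 1)
                msg <- c(msg, "haplotypes must be binary")
        }
    }
    if (any(object@p_pop < 0 | object@p_pop > 1))
        msg <- c(msg, "p_pop entries must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# QC
# ---------------------------------------------------------------------------

#' Thresholds of the genotype / variant / sample QC cascade
#'
#' Defaults follow a deep targeted-sequencing design: genotypes are masked at
#' read depth < 5 or genotype quality < 10 (exclusive: DP = 5 passes);
#' variants are dropped when more than 10\% of samples have no reads, the
#' summed depth is below 20,000 reads, missingness exceeds 10\%, or the exact
#' Hardy-Weinberg test gives p < 1e-6 in any ancestry group; samples are
#' dropped below 90\% call rate or below 90\% concordance with an external
#' genotype set, and one of each near-duplicate pair (concordance > 0.99) is
#' removed.
#'
#' @aliases QcThresholds-class
#' @exportClass QcThresholds
setClass("QcThresholds", representation(
    min_depth = "numeric",
    min_gq = "numeric",
    max_missing = "numeric",
    min_total_reads = "numeric",
    max_nodata_samples = "numeric",
    hwe_p_min = "numeric",
    min_call_rate = "numeric",
    min_concordance = "numeric",
    duplicate_concordance = "numeric"),
    prototype(
    min_depth = 5, min_gq = 10, max_missing = 0.10,
    min_total_reads = 20000, max_nodata_samples = 0.10,
    hwe_p_min = 1e-6, min_call_rate = 0.90, min_concordance = 0.90,
    duplicate_concordance = 0.99))

setValidity("QcThresholds", function(object) {
    props <- c(object@max_missing, object@max_nodata_samples,
               object@hwe_p_min, object@min_call_rate,
               object@min_concordance, object@duplicate_concordance)
    if (any(props < 0 | props > 1))
        return("all proportions/probabilities must lie in [0, 1]")
    TRUE
})

#' Accounting of a QC pass
#'
#' Per-rule removal counts for genotypes, variants and samples, together with
#' the input and output matrix dimensions, so that the cascade reconciles
#' exactly.
#'
#' @aliases QcReport-class
#' @exportClass QcReport
setClass("QcReport", representation(
    genotypes_masked = "integer",
    variant_rules = "integer",
    sample_rules = "integer",
    dim_in = "integer",
    dim_out = "integer"),
    prototype(genotypes_masked = 0L,
              variant_rules = integer(0), sample_rules = integer(0),
              dim_in = c(0L, 0L), dim_out = c(0L, 0L)))

setValidity("QcReport", function(object) {
    msg <- NULL
    if (sum(object@variant_rules) != object@dim_in[1] - object@dim_out[1])
        msg <- c(msg, "variant removals do not reconcile with dimensions")
    if (sum(object@sample_rules) != object@dim_in[2] - object@dim_out[2])
        msg <- c(msg, "sample removals do not reconcile with dimensions")
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# Fine-mapping
# ---------------------------------------------------------------------------

#' Single-causal posterior probabilities and the credible (posterior
#' probability) set of a region
#'
#' Holds per-variant posterior probabilities under the single-causal
#' approximate-Bayes model, the descending ranking, credible-set membership
#' flags and the cumulative mass at the set boundary.
#'
#' @aliases PosteriorSet-class
#' @exportClass PosteriorSet
setClass("PosteriorSet", representation(
    region = "character",
    table = "DataFrame",
    mass = "numeric",
    cum_mass = "numeric"))

setValidity("PosteriorSet", function(object) {
    msg <- NULL
    tb <- object@table
    need <- c("variant", "pi", "rank", "member")
    if (!all(need %in% colnames(tb)))
        return(paste("table needs columns:", paste(need, collapse = ", ")))
    if (abs(sum(tb$pi) - 1) > 1e-9)
        msg <- c(msg, "posterior probabilities must sum to 1 (within 1e-9)")
    o <- order(tb$rank)
    memb <- tb$member[o]
    k <- sum(memb)
    if (k > 0 && !all(memb[seq_len(k)]))
        msg <- c(msg, "members must be a prefix of the descending ranking")
    if (object@mass <= 0 || object@mass >= 1)
        msg <- c(msg, "mass must be in (0, 1)")
    if (k > 0) {
        cums <- cumsum(tb$pi[o])
        if (!(cums[k] > object@mass - 1e-12))
            msg <- c(msg, "cumulative member mass must exceed the mass target")
        if (k > 1 && cums[k - 1L] > object@mass + 1e-12)
            msg <- c(msg, "set is not minimal: dropping the last member keeps mass above target")
    }
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# Rare-variant sets
# ---------------------------------------------------------------------------

#' A gene's rare-variant set
#'
#' Member variants of one gene selected for aggregate testing: nonsynonymous
#' (moderate-impact) SNVs with pooled MAF below the rarity threshold,
#' optionally restricted to those predicted damaging; per-population counts of
#' polymorphic members are recorded.
#'
#' @aliases VariantSet-class
#' @exportClass VariantSet
setClass("VariantSet", representation(
    gene = "character",
    variants = "character",
    rule = "character",
    maf_max = "numeric",
    pop_counts = "integer"))

setValidity("VariantSet", function(object) {
    if (!object@rule %in% c("nonsyn_rare", "nonsyn_rare_damaging"))
        return("rule must be 'nonsyn_rare' or 'nonsyn_rare_damaging'")
    if (anyDuplicated(object@variants))
        return("member variants must be unique")
    TRUE
})
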