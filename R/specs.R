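#' Region specification
#'
#' @param region_id region label, e.g. \code{"2q35"}
#' @param n_variants number of SNVs in the region
#' @param founder_haplotypes size of the founder haplotype pool; smaller pools
#'   give stronger linkage disequilibrium. The rare-frequency density lives on
#'   \code{[1/(4 * founder_haplotypes), 0.005]}, so pools of at least ~50
#'   founders are needed when \code{common_fraction < 1}.
#' @param switch_prob per adjacent-variant probability that a sampled
#'   haplotype switches to a new random founder (mosaic recombination)
#' @param common_fraction proportion of variants whose ancestral frequency is
#'   drawn uniformly from the common range [0.005, 0.5]; the rest are drawn
#'   from a density proportional to 1/x on the rare range. The default 0.128
#'   reproduces a spectrum in which ~87.2\% of SNVs are rare (MAF < 0.005).
#' @param chrom,start,spacing coordinates used when emitting VCF/BED: variants
#'   are placed at \code{start + (0:(n_variants-1)) * spacing} on \code{chrom}.
#' @return a \linkS4class{RegionSpec}
#' @export
RegionSpec <- function(region_id, n_variants,
                       founder_haplotypes = 200L, switch_prob = 0.01,
                       common_fraction = 0.128,
                       chrom = "chr1", start = 1000000L, spacing = 100L) {
    new("RegionSpec", region_id = as.character(region_id),
        chrom = as.character(chrom), start = as.integer(start),
        spacing = as.integer(spacing), n_variants = as.integer(n_variants),
        founder_haplotypes = as.integer(founder_haplotypes),
        switch_prob = switch_prob, common_fraction = common_fraction)
}

#' Population specification
#'
#' @param label population name, e.g. \code{"AFR"}
#' @param n_cases,n_controls case/control targets for the simulated cohort
#' @param divergence_F Balding-Nichols divergence parameter in (0, 1)
#' @param private_rare_rate expected number (Poisson) of population-private
#'   rare variants per region
#' @return a \linkS4class{PopulationSpec}
#' @export
PopulationSpec <- function(label, n_cases, n_controls,
                           divergence_F = 0.01, private_rare_rate = 0) {
    new("PopulationSpec", label = as.character(label),
        n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
        divergence_F = divergence_F, private_rare_rate = private_rare_rate)
}

#' The four-population study design emulated by the simulator
#'
#' Cohort sizes follow the targeted-sequencing study design the package
#' models: 937 African American, 1256 Japanese American, 907 Hispanic and
#' 1511 European women, 2288 cases and 2323 controls in total. Case/control
#' splits within populations are chosen to reproduce those margins.
#'
#' @param divergence_F per-population Balding-Nichols F values (recycled)
#' @return list of \linkS4class{PopulationSpec}
#' @export
defaultPopulations <- function(divergence_F = c(0.15, 0.12, 0.08, 0.05)) {
    divergence_F <- rep_len(divergence_F, 4L)
    list(
        PopulationSpec("AFR", 468L, 469L, divergence_F[1]),
        PopulationSpec("JPT", 622L, 634L, divergence_F[2]),
        PopulationSpec("HIS", 452L, 455L, divergence_F[3]),
        PopulationSpec("EUR", 746L, 765L, divergence_F[4]))
}

#' Logistic disease model
#'
#' @param baseline_prevalence marginal disease probability the simulated pool
#'   is calibrated to
#' @param causal_effects named numeric vector of per-allele log odds ratios
#'   (names are variant ids); empty for a null model
#' @param er_neg_fraction probability that a case is estrogen-receptor
#'   negative (assigned independently of genotype); default 393/2288, the
#'   ER-negative fraction of the modeled study
#' @return a \linkS4class{DiseaseModel}
#' @export
DiseaseModel <- function(baseline_prevalence = 0.1,
                         causal_effects = numeric(0),
                         er_neg_fraction = 393 / 2288) {
    new("DiseaseModel", baseline_prevalence = baseline_prevalence,
        causal_effects = causal_effects, er_neg_fraction = er_neg_fraction)
}

#' QC thresholds
#'
#' See \linkS4class{QcThresholds} for the defaults and their meaning; any
#' field can be overridden by name.
#'
#' @param ... named overrides of the slots, e.g. \code{min_depth = 8}
#' @return a \linkS4class{QcThresholds}
#' @export
QcThresholds <- function(...) {
    args <- list(...)
    bad <- setdiff(names(args), slotNames("QcThresholds"))
    if (length(bad))
        stop("unknown QC threshold(s): ", paste(bad, collapse = ", "))
    do.call(new, c(list("QcThresholds"), args))
}

# Deterministic stream splitting: every simulation routine derives its own
# sub-seed from the master seed and a path of labels, so adding populations
# or regions never perturbs the streams of the others.
childSeed <- function(seed, ...) {
    key <- paste(c(seed, ...), collapse = "/")
    h <- 5381
    for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
    as.integer(h)
}
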