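#' Construct a GenotypeExperiment
#'
#' @param dosage integer matrix of alt-allele counts (variants x samples);
#'   values 0/1/2 with \code{NA} for missing calls. Row names are variant ids,
#'   column names sample ids.
#' @param variants a \link[GenomicRanges]{GRanges} of variant positions
#'   (width-1), named like the dosage rows, with optional metadata columns
#'   \code{ref}, \code{alt}, \code{region}, \code{gene}, \code{impact},
#'   \code{damaging}.
#' @param samples a \code{DataFrame}/\code{data.frame} sample sheet with row
#'   names matching the dosage columns; typically columns \code{population},
#'   \code{status} ("case"/"control"), \code{er_status}
#'   ("positive"/"negative"/"unknown") and principal-component covariates
#'   \code{PC1}, \code{PC2}, ...
#' @param DP,GQ optional integer matrices (same shape as \code{dosage}) of
#'   per-genotype read depth and genotype quality.
#'
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("v1", "v2"), c("s1", "s2")))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' names(gr) <- rownames(d)
#' ge <- GenotypeExperiment(d, gr,
#'     S4Vectors::DataFrame(status = c("case", "control"),
#'                          row.names = colnames(d)))
#' dosage(ge)
#' @export
GenotypeExperiment <- function(dosage, variants, samples, DP = NULL, GQ = NULL) {
    if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
        stop("dosage must have row (variant) and column (sample) names")
    if (is.null(names(variants)))
        names(variants) <- rownames(dosage)
    if (!identical(names(variants), rownames(dosage)))
        variants <- variants[rownames(dosage)]
    samples <- as(samples, "DataFrame")
    if (is.null(rownames(samples)))
        rownames(samples) <- colnames(dosage)
    assays <- SimpleList(dosage = dosage)
    if (!is.null(DP)) assays[["DP"]] <- DP
    if (!is.null(GQ)) assays[["GQ"]] <- GQ
    se <- SummarizedExperiment(assays = assays, rowRanges = variants,
                               colData = samples)
    new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment Alt-allele dosage matrix (0/1/2, NA missing).
#' @param x,ge a GenotypeExperiment
#' @export
dosage <- function(x) assay(x, "dosage")

#' @describeIn GenotypeExperiment Per-genotype read depth, or NULL if absent.
#' @export
readDepth <- function(x)
    if ("DP" %in% assayNames(x)) assay(x, "DP") else NULL

#' @describeIn GenotypeExperiment Per-genotype quality, or NULL if absent.
#' @export
genoQual <- function(x)
    if ("GQ" %in% assayNames(x)) assay(x, "GQ") else NULL

#' @describeIn GenotypeExperiment The sample sheet (colData) as a DataFrame.
#' @export
sampleSheet <- function(x) colData(x)

#' Case/control phenotype vector
#'
#' Returns the 0/1 disease indicator for the requested phenotype definition.
#' \code{"overall"} codes every case 1 and every control 0.
#' \code{"er_neg"} (\code{"er_pos"}) restricts cases to estrogen-receptor
#' negative (positive) ones; cases of the other or unknown subtype are
#' excluded (NA) rather than recoded as controls.
#'
#' @param ge a \linkS4class{GenotypeExperiment} with \code{status} (and, for
#'   the subtype phenotypes, \code{er_status}) in its sample sheet
#' @param phenotype \code{"overall"}, \code{"er_neg"} or \code{"er_pos"}
#' @return numeric vector (one per sample) of 0/1 with NA for excluded samples
#' @export
phenotypeVector <- function(ge, phenotype = c("overall", "er_neg",
                                              "er_pos")) {
    phenotype <- match.arg(phenotype)
    st <- colData(ge)$status
    if (is.null(st)) stop("sample sheet has no 'status' column")
    y <- ifelse(st == "case", 1, 0)
    if (phenotype != "overall") {
        er <- colData(ge)$er_status
        if (is.null(er)) stop(phenotype, " phenotype needs an 'er_status' column")
        want <- if (phenotype == "er_neg") "negative" else "positive"
        y[st == "case" & er != want] <- NA
    }
    y
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d SNVs x %d samples\n",
                nrow(object), ncol(object)))
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    st <- colData(object)$status
    if (!is.null(st))
        cat(sprintf("  %d cases / %d controls\n",
                    sum(st == "case"), sum(st == "control")))
    pop <- colData(object)$population
    if (!is.null(pop))
        cat("  populations:", paste(unique(pop), collapse = ", "), "\n")
    rg <- rowData(object)$region
    if (!is.null(rg))
        cat("  regions:", length(unique(rg)), "\n")
})

setMethod("show", "QcReport", function(object) {
    cat("QC report\n")
    cat(sprintf("  input : %d variants x %d samples\n",
                object@dim_in[1], object@dim_in[2]))
    cat(sprintf("  output: %d variants x %d samples\n",
                object@dim_out[1], object@dim_out[2]))
    if (object@genotypes_masked > 0)
        cat(sprintf("  genotypes masked: %d\n", object@genotypes_masked))
    if (length(object@variant_rules)) {
        cat("  variants removed:\n")
        for (r in names(object@variant_rules))
            cat(sprintf("    %-12s %d\n", r, object@variant_rules[[r]]))
    }
    if (length(object@sample_rules)) {
        cat("  samples removed:\n")
        for (r in names(object@sample_rules))
            cat(sprintf("    %-12s %d\n", r, object@sample_rules[[r]]))
    }
})

setMethod("show", "PosteriorSet", function(object) {
    k <- sum(object@table$member)
    cat(sprintf(
        "PosteriorSet '%s': %d of %d SNVs in the %.0f%% credible set (mass %.4f)\n",
        object@region, k, nrow(object@table), 100 * object@mass,
        object@cum_mass))
})

setMethod("show", "VariantSet", function(object) {
    cat(sprintf("VariantSet '%s' (%s): %d variants, pooled MAF < %g\n",
                object@gene, object@rule, length(object@variants),
                object@maf_max))
})

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel '%s': %d variants, %d population(s)\n",
                object@region_id, length(object@p_anc),
                length(object@haplotypes)))
    for (k in names(object@haplotypes))
        cat(sprintf("  %s: %d haplotypes\n", k, nrow(object@haplotypes[[k]])))
})
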