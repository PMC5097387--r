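#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader geno geno<-
#'   meta meta<- ref alt vcfWhich
#' @importFrom Biostrings DNAStringSet DNAStringSetList
#' @importFrom IRanges IRanges DataFrameList
#' @importFrom GenomicRanges seqnames start findOverlaps
#' @importFrom utils read.delim write.table count.fields
NULL

.gtToDosage <- function(gt, alt_index) {
    # count alleles equal to alt_index in a GT string vector ("0/1", "1|1", ...)
    clean <- gsub("|", "/", gt, fixed = TRUE)
    parts <- strsplit(clean, "/", fixed = TRUE)
    vapply(parts, function(a) {
        if (any(a == "." | a == "")) return(NA_integer_)
        sum(a == as.character(alt_index))
    }, integer(1))
}

#' Read a VCF into a GenotypeExperiment
#'
#' Parses a VCF 4.2 file (via \pkg{VariantAnnotation}), converting GT calls to
#' alt-allele dosages 0/1/2 with \code{./.} mapped to missing. Multiallelic
#' records are split into one pseudo-variant per ALT allele (dosage counts
#' that allele). Non-SNV records (indels, symbolic alleles) are skipped with
#' a message giving the count. DP and GQ FORMAT fields populate the depth and
#' quality assays when present.
#'
#' @param path VCF file
#' @param region_filter optional \link[GenomicRanges]{GRanges}; only variants
#'   whose position falls inside are kept
#' @return a \linkS4class{GenotypeExperiment} (sample sheet columns are not
#'   populated; merge a sheet with \code{\link{readSampleSheet}})
#' @export
readVcfGE <- function(path, region_filter = NULL) {
    vcf <- readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(ref(vcf))
    alts <- alt(vcf)  # DNAStringSetList (one entry per ALT)
    gt <- geno(vcf)$GT
    has_dp <- "DP" %in% names(geno(vcf))
    has_gq <- "GQ" %in% names(geno(vcf))
    nalt <- lengths(alts)

    rows <- list(); ids <- character(0)
    grs <- list(); meta_ref <- character(0); meta_alt <- character(0)
    dp_rows <- list(); gq_rows <- list()
    n_skipped <- 0L
    for (i in seq_len(nrow(vcf))) {
        alts_i <- as.character(alts[[i]])
        for (k in seq_len(nalt[i])) {
            a <- alts_i[k]
            if (nchar(refs[i]) != 1L || nchar(a) != 1L ||
                !refs[i] %in% c("A", "C", "G", "T") ||
                !a %in% c("A", "C", "G", "T")) {
                n_skipped <- n_skipped + 1L
                next
            }
            id <- names(rr)[i]
            if (is.na(id) || id == "." || nalt[i] > 1L || id %in% ids)
                id <- sprintf("%s:%d_%s_%s", as.character(seqnames(rr)[i]),
                              start(rr)[i], refs[i], a)
            ids <- c(ids, id)
            rows[[length(rows) + 1L]] <- .gtToDosage(gt[i, ], k)
            grs[[length(grs) + 1L]] <- i
            meta_ref <- c(meta_ref, refs[i]); meta_alt <- c(meta_alt, a)
            if (has_dp) dp_rows[[length(dp_rows) + 1L]] <- geno(vcf)$DP[i, ]
            if (has_gq) gq_rows[[length(gq_rows) + 1L]] <- geno(vcf)$GQ[i, ]
        }
    }
    if (n_skipped > 0L)
        message(n_skipped, " non-SNV record(s) skipped")
    if (!length(rows))
        stop("no SNV records found in ", path)
    dosage <- do.call(rbind, rows)
    storage.mode(dosage) <- "integer"
    rownames(dosage) <- ids
    colnames(dosage) <- colnames(gt)
    gr <- GRanges(seqnames(rr)[unlist(grs)],
                  IRanges(start(rr)[unlist(grs)], width = 1L))
    names(gr) <- ids
    S4Vectors::mcols(gr)$ref <- meta_ref
    S4Vectors::mcols(gr)$alt <- meta_alt
    DP <- if (has_dp) {
        x <- do.call(rbind, dp_rows); dimnames(x) <- dimnames(dosage)
        storage.mode(x) <- "integer"; x
    } else NULL
    GQ <- if (has_gq) {
        x <- do.call(rbind, gq_rows); dimnames(x) <- dimnames(dosage)
        storage.mode(x) <- "integer"; x
    } else NULL
    ge <- GenotypeExperiment(dosage, gr,
                             DataFrame(row.names = colnames(dosage)),
                             DP = DP, GQ = GQ)
    if (!is.null(region_filter)) {
        keep <- !is.na(findOverlaps(rowRanges(ge), region_filter,
                                    select = "first"))
        ge <- ge[keep, ]
    }
    ge
}

#' Write a GenotypeExperiment as VCF 4.2
#'
#' Emits one biallelic SNV record per row with GT (and DP/GQ when present)
#' per-genotype fields; missing dosages become \code{./.}.
#'
#' @param ge a \linkS4class{GenotypeExperiment} whose rowData has \code{ref}
#'   and \code{alt} columns
#' @param path output file (plain text)
#' @return \code{path}, invisibly
#' @export
writeVcfGE <- function(ge, path) {
    rd <- rowData(ge)
    if (is.null(rd$ref) || is.null(rd$alt))
        stop("rowData must carry 'ref' and 'alt' alleles")
    d <- dosage(ge)
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d),
                 dimnames = dimnames(d))
    gt[is.na(d)] <- "./."
    gl <- SimpleList(GT = gt)
    fmt <- DataFrame(Number = "1", Type = "String",
                     Description = "Genotype", row.names = "GT")
    if (!is.null(readDepth(ge))) {
        gl[["DP"]] <- readDepth(ge)
        fmt <- rbind(fmt, DataFrame(Number = "1", Type = "Integer",
                                    Description = "Read depth",
                                    row.names = "DP"))
    }
    if (!is.null(genoQual(ge))) {
        gl[["GQ"]] <- genoQual(ge)
        fmt <- rbind(fmt, DataFrame(Number = "1", Type = "Integer",
                                    Description = "Genotype quality",
                                    row.names = "GQ"))
    }
    hdr <- VCFHeader(samples = colnames(ge))
    geno(hdr) <- fmt
    # writeVcf drops the mandatory ##fileformat line unless seeded explicitly
    meta(hdr) <- DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    fx <- DataFrame(REF = DNAStringSet(rd$ref),
                    ALT = DNAStringSetList(as.list(rd$alt)),
                    QUAL = rep(NA_real_, nrow(ge)),
                    FILTER = rep("PASS", nrow(ge)))
    vcf <- VCF(rowRanges = rowRanges(ge)[, NULL],
               colData = DataFrame(Samples = seq_len(ncol(ge)),
                                   row.names = colnames(ge)),
               exptData = list(header = hdr), fixed = fx, geno = gl)
    writeVcf(vcf, path)
    invisible(path)
}

#' Read region definitions from BED
#'
#' BED's half-open 0-based intervals are converted to the package's 1-based
#' closed convention (a BED line \code{chr2 100 200} becomes [101, 200]), so
#' containment of VCF positions is consistent across formats.
#'
#' @param path BED file (3+ columns; column 4, when present, names regions)
#' @return a \link[GenomicRanges]{GRanges} (possibly empty)
#' @export
readRegionsBed <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(GRanges())
    fields <- strsplit(lines, "\t")
    if (any(lengths(fields) < 3L))
        stop("BED lines must have at least 3 columns")
    st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (any(is.na(st) | is.na(en)))
        stop("malformed BED: non-numeric start/end")
    if (any(st >= en))
        stop("malformed BED: start >= end")
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(S4Vectors::mcols(gr)$name))
        names(gr) <- S4Vectors::mcols(gr)$name
    gr
}

#' Write regions to BED
#'
#' @param regions a named \link[GenomicRanges]{GRanges}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeRegionsBed <- function(regions, path) {
    if (length(names(regions)))
        S4Vectors::mcols(regions)$name <- names(regions)
    rtracklayer::export(regions, path, format = "BED")
    invisible(path)
}

.SHEET_COLS <- c("sample_id", "population", "status", "er_status")

#' Read / write the tab-separated sample sheet
#'
#' Columns: \code{sample_id}, \code{population}, \code{status}
#' (case/control), \code{er_status} (positive/negative/unknown) and any
#' number of numeric covariate columns (principal components \code{PC1},
#' \code{PC2}, ...). Sample ids must be unique; malformed values are
#' rejected.
#'
#' @param path TSV file
#' @return a \code{DataFrame} keyed by sample id
#' @export
readSampleSheet <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(.SHEET_COLS %in% colnames(df)))
        stop("sample sheet needs columns: ",
             paste(.SHEET_COLS, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in sample sheet")
    if (!all(df$status %in% c("case", "control")))
        stop("status must be 'case' or 'control'")
    if (!all(df$er_status %in% c("positive", "negative", "unknown")))
        stop("er_status must be positive/negative/unknown")
    extra <- setdiff(colnames(df), .SHEET_COLS)
    for (cc in extra) {
        if (!is.numeric(df[[cc]]))
            stop("covariate column '", cc, "' is not numeric")
    }
    out <- DataFrame(df[setdiff(colnames(df), "sample_id")],
                     row.names = df$sample_id)
    out
}

#' @rdname readSampleSheet
#' @param sheet a DataFrame as stored in \code{colData} of a
#'   \linkS4class{GenotypeExperiment}
#' @export
writeSampleSheet <- function(sheet, path) {
    df <- as.data.frame(sheet)
    df <- cbind(sample_id = rownames(df), df)
    rownames(df) <- NULL
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write the variant annotation table
#'
#' Tab-separated with columns \code{variant}, \code{gene}, \code{impact}
#' (high/moderate/low/modifier), \code{damaging} (TRUE/FALSE/NA).
#'
#' @param path TSV file
#' @return data.frame
#' @export
readAnnotations <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    need <- c("variant", "gene", "impact", "damaging")
    if (!all(need %in% colnames(df)))
        stop("annotation table needs columns: ", paste(need, collapse = ", "))
    ok <- df$impact %in% c("high", "moderate", "low", "modifier")
    if (!all(ok))
        stop("invalid impact class: ", paste(unique(df$impact[!ok]), collapse = ", "))
    df$damaging <- as.logical(df$damaging)
    df
}

#' @rdname readAnnotations
#' @param ge a \linkS4class{GenotypeExperiment} with annotation columns in
#'   \code{rowData}
#' @export
writeAnnotations <- function(ge, path) {
    rd <- rowData(ge)
    df <- data.frame(variant = rownames(ge),
                     gene = if (is.null(rd$gene)) NA else rd$gene,
                     impact = if (is.null(rd$impact)) NA else rd$impact,
                     damaging = if (is.null(rd$damaging)) NA else rd$damaging)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# Column layouts of the three result kinds; a table must be exactly one kind.
.RESULT_KINDS <- list(
    assoc = c("variant", "population", "beta", "se", "z", "p", "loglik",
              "null_loglik", "n", "maf", "evaluable"),
    meta = c("variant", "population", "beta", "se", "z", "p", "n", "k_pops",
             "populations"),
    gene = c("gene", "scope", "rule", "n_variants", "carrier_prop", "test",
             "beta", "se", "or", "ci_lo", "ci_hi", "p", "q_stat",
             "evaluable"))

.resultKind <- function(tbl) {
    cn <- colnames(tbl)
    for (kind in names(.RESULT_KINDS)) {
        lay <- .RESULT_KINDS[[kind]]
        if (identical(cn, lay)) return(kind)
        if (kind == "gene" && identical(cn, c(lay, "significant")))
            return(kind)
    }
    stop("not a recognized result table; mixed or reordered columns")
}

#' Write / read pipeline result tables
#'
#' Tab-separated with a fixed column order per result kind (per-SNV
#' association, meta-analysis, or gene-based test). Numeric columns are
#' serialized in scientific notation with 15 significant digits so a
#' write/read roundtrip is lossless to better than 1e-12 relative;
#' not-evaluable p-values are written as \code{NA}.
#'
#' @param tbl a result data.frame produced by the association, meta or
#'   rare-variant modules
#' @param path TSV file
#' @return \code{writeResults}: \code{path} invisibly; \code{readResults}:
#'   the table with numeric types restored
#' @export
writeResults <- function(tbl, path) {
    .resultKind(tbl)  # validates a single, recognized kind
    out <- tbl
    for (cc in colnames(out)) {
        if (is.numeric(out[[cc]]))
            out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                                formatC(out[[cc]], format = "e", digits = 14))
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    kind <- .resultKind(df)
    char_cols <- list(assoc = c("variant", "population"),
                      meta = c("variant", "population", "populations"),
                      gene = c("gene", "scope", "rule", "test"))[[kind]]
    for (cc in colnames(df)) {
        if (cc %in% char_cols) {
            df[[cc]] <- as.character(df[[cc]])
        } else if (cc %in% c("evaluable", "significant")) {
            df[[cc]] <- as.logical(df[[cc]])
        } else {
            df[[cc]] <- as.numeric(df[[cc]])
        }
    }
    df
}

#' Read a simulation configuration file
#'
#' YAML with keys mirroring the specification classes: a \code{regions} list
#' (fields of \code{\link{RegionSpec}}), a \code{populations} list (fields of
#' \code{\link{PopulationSpec}}) and a \code{model} block (fields of
#' \code{\link{DiseaseModel}}; \code{causal_effects} is a map from variant id
#' to per-allele log odds ratio).
#'
#' @param path YAML file
#' @return list with elements \code{regions}, \code{populations}, \code{model}
#' @export
readSimConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$regions) || is.null(cfg$populations))
        stop("config needs 'regions' and 'populations' blocks")
    regions <- lapply(cfg$regions, function(r) do.call(RegionSpec, r))
    pops <- lapply(cfg$populations, function(p) do.call(PopulationSpec, p))
    model <- if (is.null(cfg$model)) DiseaseModel() else {
        m <- cfg$model
        ce <- if (is.null(m$causal_effects)) numeric(0) else
            unlist(m$causal_effects)
        DiseaseModel(
            baseline_prevalence = if (is.null(m$baseline_prevalence)) 0.1
                                  else m$baseline_prevalence,
            causal_effects = ce,
            er_neg_fraction = if (is.null(m$er_neg_fraction)) 393 / 2288
                              else m$er_neg_fraction)
    }
    list(regions = regions, populations = pops, model = model)
}
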