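#' @include editscan-package.R
NULL

## ---------------------------------------------------------------------------
## GenomeAnnotation
## ---------------------------------------------------------------------------

#' Gene annotation container
#'
#' Holds transcript models (exons and CDS segments as `GRangesList`, one
#' element per transcript) together with transcript- and gene-level metadata.
#' All coordinates are 1-based closed intervals on the forward reference
#' strand, the GRanges/IRanges convention; GFF3 files use the same convention
#' on disk, so import is coordinate-preserving.
#'
#' @slot transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype` (one of `protein_coding`, `lncRNA`,
#'   `novel`, `other`).
#' @slot genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene span = union of its transcripts).
#' @slot exons [GenomicRanges::GRangesList] named by transcript id; sorted,
#'   non-overlapping, single chromosome per transcript.
#' @slot cds [GenomicRanges::GRangesList] named by transcript id; subset of
#'   the exonic space, possibly empty. For `protein_coding` transcripts the
#'   spliced CDS length must be non-zero and divisible by 3.
#'
#' @seealso [GenomeAnnotation()], [readAnnotation()], [exonsOf()], [cdsOf()]
#' @export
setClass("GenomeAnnotation",
    slots = c(
        transcripts = "data.frame",
        genes = "data.frame",
        exons = "CompressedGRangesList",
        cds = "CompressedGRangesList"
    )
)

validGenomeAnnotation <- function(object) {
    msg <- character()
    tx <- object@transcripts
    need <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
    if (!all(need %in% names(tx))) {
        return(paste("transcripts table must have columns",
                     paste(need, collapse = ", ")))
    }
    if (anyDuplicated(tx$transcript_id)) {
        msg <- c(msg, "duplicate transcript ids")
    }
    if (!setequal(names(object@exons), tx$transcript_id) ||
        !identical(names(object@exons), tx$transcript_id)) {
        msg <- c(msg, "exons list names must equal transcripts$transcript_id")
    }
    if (!identical(names(object@cds), tx$transcript_id)) {
        msg <- c(msg, "cds list names must equal transcripts$transcript_id")
    }
    if (!all(tx$gene_id %in% object@genes$gene_id)) {
        msg <- c(msg, "every transcript's gene must exist in the genes table")
    }
    if (!all(tx$strand %in% c("+", "-"))) {
        msg <- c(msg, "transcript strand must be '+' or '-'")
    }
    for (i in seq_len(nrow(tx))) {
        ex <- object@exons[[i]]
        if (length(ex) == 0L) {
            msg <- c(msg, paste0("transcript ", tx$transcript_id[i],
                                 " has no exons"))
            next
        }
        if (length(unique(as.character(seqnames(ex)))) != 1L ||
            as.character(seqnames(ex)[1]) != tx$chrom[i]) {
            msg <- c(msg, paste0("exons of ", tx$transcript_id[i],
                                 " must lie on its single chromosome"))
        }
        if (is.unsorted(start(ex)) || any(start(ex)[-1] <= end(ex)[-length(ex)])) {
            msg <- c(msg, paste0("exons of ", tx$transcript_id[i],
                                 " must be sorted and non-overlapping"))
        }
        cd <- object@cds[[i]]
        if (length(cd) > 0L) {
            inside <- overlapsAny(cd, ex, type = "within")
            if (!all(inside)) {
                msg <- c(msg, paste0("CDS of ", tx$transcript_id[i],
                                     " extends outside its exons"))
            }
        }
        if (tx$biotype[i] == "protein_coding") {
            clen <- sum(width(object@cds[[i]]))
            if (clen == 0L || clen %% 3L != 0L) {
                msg <- c(msg, paste0("protein_coding transcript ",
                                     tx$transcript_id[i],
                                     " must have CDS length > 0 and divisible by 3"))
            }
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenomeAnnotation", validGenomeAnnotation)

#' Construct a GenomeAnnotation
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`.
#' @param exons named `GRangesList` (or list of `GRanges`) of exons per
#'   transcript, names matching `transcripts$transcript_id`.
#' @param cds named `GRangesList` of CDS segments per transcript; missing
#'   transcripts get an empty CDS.
#' @return A [GenomeAnnotation-class] object. The gene table (spans, strand)
#'   is derived from the transcripts.
#' @export
GenomeAnnotation <- function(transcripts, exons, cds = NULL) {
    transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
    rownames(transcripts) <- transcripts$transcript_id
    if (!methods::is(exons, "GRangesList")) exons <- GRangesList(exons)
    exons <- exons[transcripts$transcript_id]
    ## exon/CDS ranges carry the transcript strand
    setStrand <- function(grl) {
        GRangesList(lapply(seq_along(grl), function(i) {
            g <- grl[[i]]
            if (length(g)) strand(g) <- transcripts$strand[
                match(names(grl)[i], transcripts$transcript_id)]
            g
        }), compress = TRUE) |> stats::setNames(names(grl))
    }
    exons <- setStrand(exons)
    if (is.null(cds)) cds <- GRangesList()
    if (!methods::is(cds, "GRangesList")) cds <- GRangesList(cds)
    empty <- setdiff(transcripts$transcript_id, names(cds))
    if (length(empty)) {
        filler <- GRangesList(lapply(empty, function(x) GRanges()))
        names(filler) <- empty
        cds <- c(cds, filler)
    }
    cds <- setStrand(cds[transcripts$transcript_id])
    genes <- do.call(rbind, lapply(split(seq_len(nrow(transcripts)),
                                         transcripts$gene_id),
        function(idx) {
            ex <- unlist(exons[idx])
            data.frame(
                gene_id = transcripts$gene_id[idx[1]],
                chrom = transcripts$chrom[idx[1]],
                strand = transcripts$strand[idx[1]],
                start = min(start(ex)),
                end = max(end(ex)),
                stringsAsFactors = FALSE
            )
        }))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- genes$gene_id
    methods::new("GenomeAnnotation", transcripts = transcripts, genes = genes,
                 exons = exons, cds = cds)
}

#' @describeIn GenomeAnnotation transcript metadata table.
#' @param x,object a `GenomeAnnotation`.
#' @export
txTable <- function(x) x@transcripts

#' @describeIn GenomeAnnotation gene metadata table (spans).
#' @export
geneTable <- function(x) x@genes

#' @describeIn GenomeAnnotation exon ranges of one transcript.
#' @param transcript_id single transcript id.
#' @export
exonsOf <- function(x, transcript_id) {
    if (!transcript_id %in% names(x@exons)) {
        stop("unknown transcript: ", transcript_id)
    }
    x@exons[[transcript_id]]
}

#' @describeIn GenomeAnnotation CDS ranges of one transcript (may be empty).
#' @export
cdsOf <- function(x, transcript_id) {
    if (!transcript_id %in% names(x@cds)) {
        stop("unknown transcript: ", transcript_id)
    }
    x@cds[[transcript_id]]
}

#' @describeIn GenomeAnnotation all exon ranges as a `GRangesList`.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GenomeAnnotation all CDS ranges as a `GRangesList`.
#' @export
cdsRanges <- function(x) x@cds

#' Transcript spans as a GRanges
#'
#' One range per transcript covering its first to last exon, with
#' `transcript_id`, `gene_id` and `biotype` metadata columns.
#'
#' @param x a `GenomeAnnotation`.
#' @return A named [GenomicRanges::GRanges].
#' @export
transcriptSpans <- function(x) {
    tx <- x@transcripts
    gr <- GRanges(tx$chrom,
                  IRanges(min(start(x@exons)), max(end(x@exons))),
                  strand = tx$strand)
    names(gr) <- tx$transcript_id
    mcols(gr)$transcript_id <- tx$transcript_id
    mcols(gr)$gene_id <- tx$gene_id
    mcols(gr)$biotype <- tx$biotype
    gr
}

#' Gene spans as a GRanges
#'
#' @param x a `GenomeAnnotation`.
#' @return A named [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
geneSpans <- function(x) {
    g <- x@genes
    gr <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand)
    names(gr) <- g$gene_id
    mcols(gr)$gene_id <- g$gene_id
    gr
}

#' Transcripts overlapping an interval
#'
#' Returns the ids of transcripts whose span (first to last exon) intersects
#' the query interval.
#'
#' @param x a `GenomeAnnotation`.
#' @param chrom chromosome name.
#' @param start,end 1-based closed query interval.
#' @return Character vector of transcript ids (possibly empty).
#' @export
overlappingTranscripts <- function(x, chrom, start, end) {
    spans <- transcriptSpans(x)
    q <- GRanges(chrom, IRanges(start, end))
    hits <- findOverlaps(q, spans, ignore.strand = TRUE)
    names(spans)[subjectHits(hits)]
}

setMethod("show", "GenomeAnnotation", function(object) {
    tx <- object@transcripts
    cat("GenomeAnnotation with", nrow(tx), "transcripts in",
        nrow(object@genes), "genes\n")
    bt <- table(tx$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
    cat("  chromosomes:", paste(unique(tx$chrom), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## VariantSet
## ---------------------------------------------------------------------------

#' Set of biallelic SNVs with per-sample allele depths
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' row per biallelic SNV (width-1 `GRanges`, 1-based position) and three
#' integer assays:
#' `refDepth` (reads supporting the reference base), `altDepth` (reads
#' supporting the alternative base) and `DP` (total filtered depth).
#' Row metadata carries the alleles (`ref`, `alt`, single upper-case bases),
#' site-level quality annotations (`QD`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum`; `NA` means the annotation was not emitted for the site
#' and the corresponding hard filter passes), and an optional known-SNP
#' identifier `rs_id` (`NA` when the site has no dbSNP annotation).
#'
#' @seealso [VariantSet()], [readVariants()], [computeAAF()],
#'   [runEditingCascade()]
#' @export
setClass("VariantSet", contains = "RangedSummarizedExperiment")

validVariantSet <- function(object) {
    msg <- character()
    need <- c("refDepth", "altDepth", "DP")
    if (!all(need %in% names(assays(object)))) {
        return("assays must include refDepth, altDepth, DP")
    }
    rd <- rowData(object)
    cols <- c("ref", "alt", "QD", "MQ", "MQRankSum", "ReadPosRankSum", "rs_id")
    if (!all(cols %in% names(rd))) {
        return(paste("rowData must include", paste(cols, collapse = ", ")))
    }
    if (nrow(object) > 0L) {
        if (any(width(rowRanges(object)) != 1L)) {
            msg <- c(msg, "all sites must have width 1")
        }
        if (!all(rd$ref %in% c("A", "C", "G", "T")) ||
            !all(rd$alt %in% c("A", "C", "G", "T"))) {
            msg <- c(msg, "ref and alt must be single A/C/G/T bases")
        }
        if (any(rd$ref == rd$alt)) {
            msg <- c(msg, "ref must differ from alt")
        }
        rdp <- assay(object, "refDepth")
        adp <- assay(object, "altDepth")
        dp <- assay(object, "DP")
        if (any(rdp < 0, na.rm = TRUE) || any(adp < 0, na.rm = TRUE) ||
            any(dp < 0, na.rm = TRUE)) {
            msg <- c(msg, "depths must be non-negative")
        }
        if (any(rdp + adp > dp, na.rm = TRUE)) {
            msg <- c(msg, "refDepth + altDepth must not exceed DP")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("VariantSet", validVariantSet)

#' Construct a VariantSet
#'
#' @param chrom,pos chromosome and 1-based position per site.
#' @param ref,alt single reference/alternative bases per site.
#' @param refDepth,altDepth,DP integer matrices, sites x samples.
#' @param samples sample ids (column names).
#' @param QD,MQ,MQRankSum,ReadPosRankSum numeric site-level annotations;
#'   `NA` marks an absent annotation (treated as pass by [hardFilter()]).
#' @param rs_id character known-SNP ids or `NA`.
#' @return A [VariantSet-class].
#' @export
VariantSet <- function(chrom, pos, ref, alt, refDepth, altDepth, DP,
                       samples = colnames(DP),
                       QD = NA_real_, MQ = NA_real_, MQRankSum = NA_real_,
                       ReadPosRankSum = NA_real_, rs_id = NA_character_) {
    n <- length(pos)
    asMat <- function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "integer"
        dimnames(m) <- list(NULL, samples)
        m
    }
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        QD = rep_len(as.numeric(QD), n), MQ = rep_len(as.numeric(MQ), n),
        MQRankSum = rep_len(as.numeric(MQRankSum), n),
        ReadPosRankSum = rep_len(as.numeric(ReadPosRankSum), n),
        rs_id = rep_len(as.character(rs_id), n)
    )
    names(gr) <- paste0(chrom, ":", pos, "_", ref, ">", alt)
    se <- SummarizedExperiment(
        assays = list(refDepth = asMat(refDepth), altDepth = asMat(altDepth),
                      DP = asMat(DP)),
        rowRanges = gr,
        colData = DataFrame(row.names = samples)
    )
    methods::new("VariantSet", se)
}

#' @describeIn VariantSet reference-allele depth matrix (sites x samples).
#' @param x a `VariantSet`.
#' @export
refDepth <- function(x) assay(x, "refDepth")

#' @describeIn VariantSet alternative-allele depth matrix.
#' @export
altDepth <- function(x) assay(x, "altDepth")

#' @describeIn VariantSet total filtered depth matrix.
#' @export
siteDepth <- function(x) assay(x, "DP")

setMethod("show", "VariantSet", function(object) {
    cat("VariantSet with", nrow(object), "SNVs across", ncol(object),
        "samples\n")
    if (nrow(object) > 0L) {
        nrs <- sum(!is.na(rowData(object)$rs_id))
        cat("  rs-annotated sites:", nrs, "\n")
        cat("  mean per-sample depth:",
            round(mean(assay(object, "DP")), 1), "\n")
    }
})
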