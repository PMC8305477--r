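#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Genome sequence (FASTA)
## ---------------------------------------------------------------------------

#' Read a genome FASTA file
#'
#' Sequences are upper-cased on ingest and restricted to the A/C/G/T/N
#' alphabet. Header lines are truncated at the first whitespace to obtain
#' chromosome names.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
readGenome <- function(path) {
    seqs <- readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs))) {
        stop("duplicate FASTA headers in ", path)
    }
    if (any(width(seqs) == 0L)) {
        stop("empty sequence record in ", path)
    }
    seqs <- DNAStringSet(toupper(as.character(seqs)))
    bad <- grepl("[^ACGTN]", as.character(seqs))
    if (any(bad)) {
        stop("non-A/C/G/T/N characters in sequences: ",
             paste(names(seqs)[bad], collapse = ", "))
    }
    seqs
}

#' Write a genome FASTA file
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path, width = 70L) {
    writeXStringSet(genome, path, width = width)
    invisible(path)
}

#' Extract a genomic subsequence
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval; must lie inside the chromosome.
#' @return Character string of exactly `end - start + 1` bases.
#' @export
genomeSlice <- function(genome, chrom, start, end) {
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    if (start < 1L || end > length(genome[[chrom]]) || start > end) {
        stop("interval [", start, ", ", end, "] out of range on ", chrom)
    }
    as.character(subseq(genome[[chrom]], start, end))
}

## ---------------------------------------------------------------------------
## Annotation (GFF3)
## ---------------------------------------------------------------------------

biotypeToFeature <- c(protein_coding = "mRNA", lncRNA = "lnc_RNA",
                      novel = "transcript", other = "transcript")

#' Read a GFF3 gene annotation
#'
#' Expects gene / transcript (`mRNA`, `lnc_RNA` or `transcript`) / `exon` /
#' `CDS` features with `ID`/`Parent` links and an optional `biotype`
#' attribute on transcripts. GFF3 coordinates are 1-based closed, the same
#' convention used in memory, so no conversion is applied.
#'
#' @param path path to a GFF3 file.
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    ids <- as.character(gr$ID)
    parent <- vapply(gr$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1))

    is_tx <- type %in% c("mRNA", "lnc_RNA", "transcript")
    is_gene <- type == "gene"
    gene_ids <- ids[is_gene]
    tx_idx <- which(is_tx)
    if (any(!parent[tx_idx] %in% gene_ids)) {
        stop("orphan transcript feature(s): parent gene not found")
    }
    tx_ids <- ids[tx_idx]
    biotype <- as.character(gr$biotype)[tx_idx]
    fallback <- c(mRNA = "protein_coding", lnc_RNA = "lncRNA",
                  transcript = "novel")
    biotype[is.na(biotype)] <- fallback[type[tx_idx][is.na(biotype)]]

    child_parent <- parent[type %in% c("exon", "CDS")]
    if (any(!child_parent %in% tx_ids)) {
        stop("orphan exon/CDS feature(s): parent transcript not found")
    }

    collectChildren <- function(what) {
        idx <- which(type == what)
        lst <- split(granges(gr[idx]), factor(parent[idx], levels = tx_ids))
        GRangesList(lapply(lst, function(g) sort(g, ignore.strand = TRUE)))
    }
    exons <- collectChildren("exon")
    cds <- collectChildren("CDS")

    for (t in tx_ids) {
        if (length(cds[[t]]) &&
            !all(overlapsAny(cds[[t]], exons[[t]], type = "within"))) {
            stop("CDS of ", t, " falls outside its exons")
        }
    }
    transcripts <- data.frame(
        transcript_id = tx_ids,
        gene_id = parent[tx_idx],
        chrom = as.character(seqnames(gr))[tx_idx],
        strand = as.character(strand(gr))[tx_idx],
        biotype = biotype,
        stringsAsFactors = FALSE
    )
    GenomeAnnotation(transcripts, exons, cds)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits gene, transcript (typed by biotype), exon and CDS features with
#' `ID`/`Parent` attributes; deterministic line order (genes by position,
#' children after parents).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
    tx <- txTable(annotation)
    genes <- geneTable(annotation)
    lines <- c("##gff-version 3")
    row9 <- function(chrom, src, type, start, end, strand, attrs) {
        paste(chrom, src, type, start, end, ".", strand, ".", attrs,
              sep = "\t")
    }
    for (g in genes$gene_id) {
        grow <- genes[g, ]
        lines <- c(lines, row9(grow$chrom, "editscan", "gene", grow$start,
                               grow$end, grow$strand,
                               paste0("ID=", g)))
        for (t in tx$transcript_id[tx$gene_id == g]) {
            trow <- tx[t, ]
            ex <- exonsOf(annotation, t)
            cd <- cdsOf(annotation, t)
            ftype <- biotypeToFeature[[trow$biotype]]
            lines <- c(lines, row9(trow$chrom, "editscan", ftype,
                                   min(start(ex)), max(end(ex)), trow$strand,
                                   paste0("ID=", t, ";Parent=", g,
                                          ";biotype=", trow$biotype)))
            for (i in seq_along(ex)) {
                lines <- c(lines, row9(trow$chrom, "editscan", "exon",
                                       start(ex)[i], end(ex)[i], trow$strand,
                                       paste0("ID=", t, ".exon", i,
                                              ";Parent=", t)))
            }
            for (i in seq_along(cd)) {
                lines <- c(lines, row9(trow$chrom, "editscan", "CDS",
                                       start(cd)[i], end(cd)[i], trow$strand,
                                       paste0("ID=", t, ".cds", i,
                                              ";Parent=", t)))
            }
        }
    }
    writeLines(lines, path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Variants (VCF)
## ---------------------------------------------------------------------------

extractAD <- function(vcf) {
    ad <- geno(vcf)$AD
    if (is.null(ad)) stop("VCF is missing the FORMAT AD field")
    n <- nrow(vcf); m <- ncol(vcf)
    refd <- matrix(NA_integer_, n, m)
    altd <- matrix(NA_integer_, n, m)
    if (is.list(ad)) {
        for (j in seq_len(m)) for (i in seq_len(n)) {
            v <- ad[[i, j]]
            refd[i, j] <- as.integer(v[1])
            altd[i, j] <- as.integer(v[2])
        }
    } else {
        refd[] <- as.integer(ad[, , 1])
        altd[] <- as.integer(ad[, , 2])
    }
    list(ref = refd, alt = altd)
}

readOneVcf <- function(path) {
    vcf <- suppressWarnings(readVcf(path))
    ids <- rep(names(rowRanges(vcf)),
               S4Vectors::elementNROWS(alt(vcf)))
    vcf <- VariantAnnotation::expand(vcf)
    refb <- as.character(ref(vcf))
    altb <- as.character(alt(vcf))
    keep <- nchar(refb) == 1L & nchar(altb) == 1L &
        refb %in% c("A", "C", "G", "T") & altb %in% c("A", "C", "G", "T")
    n_skipped <- sum(!keep)
    vcf <- vcf[keep]
    refb <- refb[keep]; altb <- altb[keep]
    getInfo <- function(key) {
        v <- info(vcf)[[key]]
        if (is.null(v)) rep(NA_real_, nrow(vcf)) else as.numeric(v)
    }
    dp <- geno(vcf)$DP
    if (is.null(dp)) stop("VCF is missing the FORMAT DP field")
    storage.mode(dp) <- "integer"
    ad <- extractAD(vcf)
    nm <- ids[keep]
    rs <- ifelse(grepl("^rs[0-9]+", nm), sub("_.*$", "", nm), NA_character_)
    vs <- VariantSet(
        chrom = as.character(seqnames(vcf)),
        pos = start(rowRanges(vcf)),
        ref = refb, alt = altb,
        refDepth = ad$ref, altDepth = ad$alt, DP = dp,
        samples = colnames(vcf),
        QD = getInfo("QD"), MQ = getInfo("MQ"),
        MQRankSum = getInfo("MQRankSum"),
        ReadPosRankSum = getInfo("ReadPosRankSum"),
        rs_id = rs
    )
    metadata(vs)$n_skipped_non_snv <- n_skipped
    vs
}

#' Read SNVs from one or more VCF files
#'
#' Multi-allelic records are split into biallelic SNVs; non-SNV records
#' (indels, symbolic alleles) are skipped and counted in
#' `metadata(x)$n_skipped_non_snv`. Several files (e.g. one per sample) are
#' merged by site: samples are concatenated and a site absent from one file
#' gets zero depths for that file's samples. Known-SNP status is taken from
#' the VCF ID column (`rs...` identifiers).
#'
#' @param paths character vector of VCF paths.
#' @param sample_ids optional: restrict/reorder to these samples after
#'   reading.
#' @return A [VariantSet-class].
#' @export
readVariants <- function(paths, sample_ids = NULL) {
    sets <- lapply(paths, readOneVcf)
    vs <- if (length(sets) == 1L) sets[[1]] else mergeVariantSets(sets)
    if (!is.null(sample_ids)) {
        missing <- setdiff(sample_ids, colnames(vs))
        if (length(missing)) {
            stop("samples not present in VCF(s): ",
                 paste(missing, collapse = ", "))
        }
        md <- metadata(vs)
        vs <- vs[, sample_ids]
        metadata(vs) <- md
    }
    vs
}

mergeVariantSets <- function(sets) {
    keys <- lapply(sets, function(s) names(rowRanges(s)))
    all_keys <- unique(unlist(keys))
    samples <- unlist(lapply(sets, colnames))
    if (anyDuplicated(samples)) stop("duplicate sample ids across VCF files")
    n <- length(all_keys); m <- length(samples)
    zero <- function() matrix(0L, n, m, dimnames = list(all_keys, samples))
    refd <- zero(); altd <- zero(); dp <- zero()
    first <- match(all_keys, unlist(keys))
    meta <- NULL
    col0 <- 0L
    for (s in sets) {
        idx <- match(names(rowRanges(s)), all_keys)
        cols <- col0 + seq_len(ncol(s))
        refd[idx, cols] <- assay(s, "refDepth")
        altd[idx, cols] <- assay(s, "altDepth")
        dp[idx, cols] <- assay(s, "DP")
        col0 <- col0 + ncol(s)
    }
    ## site-level fields from the first file carrying each site
    pieces <- do.call(rbind, lapply(sets, function(s) {
        rr <- rowRanges(s)
        data.frame(key = names(rr), chrom = as.character(seqnames(rr)),
                   pos = start(rr), as.data.frame(mcols(rr)),
                   stringsAsFactors = FALSE)
    }))
    pieces <- pieces[!duplicated(pieces$key), ]
    pieces <- pieces[match(all_keys, pieces$key), ]
    vs <- VariantSet(pieces$chrom, pieces$pos, pieces$ref, pieces$alt,
                     refd, altd, dp, samples = samples,
                     QD = pieces$QD, MQ = pieces$MQ,
                     MQRankSum = pieces$MQRankSum,
                     ReadPosRankSum = pieces$ReadPosRankSum,
                     rs_id = pieces$rs_id)
    metadata(vs)$n_skipped_non_snv <-
        sum(vapply(sets, function(s) metadata(s)$n_skipped_non_snv, 0L))
    ord <- order(as.character(seqnames(rowRanges(vs))), start(rowRanges(vs)))
    md <- metadata(vs)
    vs <- vs[ord, ]
    metadata(vs) <- md
    vs
}

fmtNum <- function(x) {
    ifelse(is.na(x), NA_character_,
           sub("\\.?0+$", "", sprintf("%.6f", x)))
}

#' Write a VariantSet as a multi-sample VCF 4.2 file
#'
#' Site annotations go to INFO (`QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`;
#' absent annotations are omitted), `rs_id` to the ID column, and per-sample
#' depths to `DP:AD` FORMAT fields.
#'
#' @param variants a [VariantSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path) {
    rr <- rowRanges(variants)
    rd <- rowData(variants)
    header <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
        "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank-sum\">",
        "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(variants)), collapse = "\t")
    )
    n <- nrow(variants)
    body <- character(n)
    refd <- assay(variants, "refDepth")
    altd <- assay(variants, "altDepth")
    dp <- assay(variants, "DP")
    ikeys <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum")
    for (i in seq_len(n)) {
        vals <- vapply(ikeys, function(k) fmtNum(rd[[k]][i]), character(1))
        info_str <- paste(paste0(ikeys[!is.na(vals)], "=", vals[!is.na(vals)]),
                          collapse = ";")
        if (info_str == "") info_str <- "."
        fmt <- paste0(dp[i, ], ":", refd[i, ], ",", altd[i, ])
        body[i] <- paste(c(
            as.character(seqnames(rr))[i], start(rr)[i],
            ifelse(is.na(rd$rs_id[i]), ".", rd$rs_id[i]),
            rd$ref[i], rd$alt[i], ".", ".", info_str, "DP:AD", fmt
        ), collapse = "\t")
    }
    writeLines(c(header, body), path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Counts and design (TSV)
## ---------------------------------------------------------------------------

#' Read a TAR x sample count matrix
#'
#' Tab-separated, first column TAR (transcriptionally active region) ids,
#' remaining columns one per sample. Counts must be non-negative integers.
#'
#' @param path path to a TSV file.
#' @return Integer matrix with TAR rownames and sample colnames.
#' @export
readCountsMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
        stop("counts must be non-negative integers")
    }
    storage.mode(m) <- "integer"
    m
}

#' Read a sample-to-group design table
#'
#' Tab-separated with columns `sample` and `group`; exactly two groups are
#' required. The returned factor places the control group first, so that
#' fold changes and AAF differences read treatment-over-control.
#'
#' @param path path to a TSV file.
#' @param treatment optional name of the treatment group; defaults to the
#'   second group in sorted order.
#' @return data.frame with columns `sample` and `group` (factor, control
#'   level first).
#' @export
readDesign <- function(path, treatment = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(df))) {
        stop("design table needs columns 'sample' and 'group'")
    }
    lev <- sort(unique(df$group))
    if (length(lev) != 2L) stop("design must define exactly two groups")
    if (is.null(treatment)) treatment <- lev[2]
    if (!treatment %in% lev) stop("treatment group '", treatment,
                                  "' not in design")
    df$group <- factor(df$group, levels = c(setdiff(lev, treatment),
                                            treatment))
    df
}

#' Assemble counts and design into a SummarizedExperiment
#'
#' @param counts integer matrix (TARs x samples).
#' @param design data.frame from [readDesign()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and `colData$group`.
#' @export
countsExperiment <- function(counts, design) {
    missing <- setdiff(design$sample, colnames(counts))
    if (length(missing)) {
        stop("design samples absent from count matrix: ",
             paste(missing, collapse = ", "))
    }
    counts <- counts[, design$sample, drop = FALSE]
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(group = design$group, row.names = design$sample)
    )
}

#' @rdname readCountsMatrix
#' @param counts integer matrix to write.
#' @export
writeCountsMatrix <- function(counts, path) {
    df <- data.frame(tar_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readDesign
#' @param design design data.frame to write.
#' @export
writeDesign <- function(design, path) {
    write.table(design[, c("sample", "group")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Region masks (BED)
## ---------------------------------------------------------------------------

#' Read region masks from BED files
#'
#' Each file becomes one mask labelled by its file name (without extension),
#' e.g. `ssr.bed`, `paralog.bed`, `bidirectional.bed`. Intervals within a
#' mask are merged. BED files are 0-based half-open on disk; rtracklayer
#' converts to the in-memory 1-based closed convention.
#'
#' @param paths a directory containing `*.bed` files, or a character vector
#'   of BED paths.
#' @return A named [GenomicRanges::GRangesList], one element per mask.
#' @export
readMasks <- function(paths) {
    if (length(paths) == 1L && dir.exists(paths)) {
        paths <- sort(list.files(paths, pattern = "\\.bed$",
                                 full.names = TRUE))
    }
    out <- lapply(paths, function(p) {
        reduce(granges(rtracklayer::import(p, format = "bed")),
               ignore.strand = TRUE)
    })
    names(out) <- file_path_sans_ext(basename(paths))
    GRangesList(out)
}

#' Write region masks as BED files
#'
#' @param masks named `GRangesList` (or list of `GRanges`).
#' @param dir output directory (created if needed); one `<label>.bed` per
#'   mask.
#' @return The written paths, invisibly.
#' @export
writeMasks <- function(masks, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(masks), function(lab) {
        p <- file.path(dir, paste0(lab, ".bed"))
        gr <- reduce(granges(masks[[lab]]), ignore.strand = TRUE)
        strand(gr) <- "*"
        rtracklayer::export(sort(gr), p, format = "bed")
        p
    }, character(1))
    invisible(paths)
}

## ---------------------------------------------------------------------------
## Library summary arithmetic
## ---------------------------------------------------------------------------

#' Summarize raw library sizes
#'
#' @param raw_read_totals positive integer vector of raw read counts, one
#'   per library.
#' @return list with `total` (sum) and `mean_mln` (mean in millions,
#'   rounded to 2 decimals).
#' @export
summarizeLibraries <- function(raw_read_totals) {
    if (length(raw_read_totals) == 0L) stop("no libraries supplied")
    if (any(is.na(raw_read_totals)) || any(raw_read_totals <= 0)) {
        stop("library totals must be positive")
    }
    total <- sum(as.numeric(raw_read_totals))
    list(total = total,
         mean_mln = round(total / length(raw_read_totals) / 1e6, 2))
}
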