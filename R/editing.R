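#' @include core_io.R
NULL

#' Editing-cascade filter configuration
#'
#' Thresholds for the site-discovery cascade. Hard filters use strict
#' inequalities exactly as printed in the GATK convention: a site is
#' removed when depth `< min_dp`, `MQ < min_mq`, `QD < min_qd`,
#' `MQRankSum < min_mqranksum` or `ReadPosRankSum < min_readposranksum`;
#' absent annotations pass. `dp_rule` selects whether `min_dp` applies to
#' the mean per-sample depth (default) or the per-sample minimum.
#'
#' @param min_dp minimum depth (reads).
#' @param min_mq minimum RMS mapping quality.
#' @param min_qd minimum quality-by-depth.
#' @param min_mqranksum,min_readposranksum rank-sum lower bounds.
#' @param splice_window splice-junction exclusion half-window (nt).
#' @param min_alt_sample_fraction minimum fraction of samples with at least
#'   one alternative read (prevalence filter; `ceil` rounding).
#' @param max_sample_aaf remove the site when any sample's AAF exceeds this
#'   (strict `>`), the hypervariable/germline guard.
#' @param aaf_scope which samples the `max_sample_aaf` rule inspects:
#'   `"any"` (default) or `"treated"`.
#' @param daaf_threshold minimum `|dAAF|` (strict `>`) for a candidate.
#' @param fdr_threshold maximum FDR (strict `<`) for a candidate.
#' @param upstream_downstream_window window (nt) for upstream/downstream
#'   consequence assignment.
#' @param dp_rule `"mean"` or `"min"`.
#' @return A validated list of class `filterConfig`.
#' @export
filterConfig <- function(min_dp = 10, min_mq = 40, min_qd = 2,
                         min_mqranksum = -12.5, min_readposranksum = -8,
                         splice_window = 4L,
                         min_alt_sample_fraction = 0.5,
                         max_sample_aaf = 0.7,
                         aaf_scope = c("any", "treated"),
                         daaf_threshold = 0.1,
                         fdr_threshold = 0.001,
                         upstream_downstream_window = 5000L,
                         dp_rule = c("mean", "min")) {
    cfg <- list(
        min_dp = min_dp, min_mq = min_mq, min_qd = min_qd,
        min_mqranksum = min_mqranksum,
        min_readposranksum = min_readposranksum,
        splice_window = as.integer(splice_window),
        min_alt_sample_fraction = min_alt_sample_fraction,
        max_sample_aaf = max_sample_aaf,
        aaf_scope = match.arg(aaf_scope),
        daaf_threshold = daaf_threshold,
        fdr_threshold = fdr_threshold,
        upstream_downstream_window = as.integer(upstream_downstream_window),
        dp_rule = match.arg(dp_rule)
    )
    num <- unlist(cfg[c("min_dp", "min_mq", "min_qd", "min_mqranksum",
                        "min_readposranksum", "splice_window",
                        "min_alt_sample_fraction", "max_sample_aaf",
                        "daaf_threshold", "fdr_threshold",
                        "upstream_downstream_window")])
    if (any(!is.finite(num))) stop("all thresholds must be finite")
    if (cfg$splice_window < 0L) stop("splice_window must be >= 0")
    if (cfg$min_alt_sample_fraction <= 0 || cfg$min_alt_sample_fraction > 1) {
        stop("min_alt_sample_fraction must be in (0, 1]")
    }
    if (cfg$max_sample_aaf <= 0 || cfg$max_sample_aaf > 1) {
        stop("max_sample_aaf must be in (0, 1]")
    }
    structure(cfg, class = "filterConfig")
}

.auditRow <- function(stage, n_in, n_out) {
    data.frame(stage = stage, n_in = n_in, n_removed = n_in - n_out,
               n_out = n_out, stringsAsFactors = FALSE)
}

.subsetVS <- function(vs, keep) {
    md <- metadata(vs)
    out <- vs[keep, ]
    metadata(out) <- md
    out
}

#' Site-quality hard filter
#'
#' Removes a site when its depth (mean per-sample, or per-sample minimum
#' under `dp_rule = "min"`) is below `min_dp`, or any of the quality
#' annotations falls below its threshold (strict `<`); sites with an
#' absent annotation pass that criterion.
#'
#' @param variants a [VariantSet-class].
#' @param cfg a [filterConfig()].
#' @return list with `variants` (survivors) and a one-row `audit`
#'   data.frame (`stage`, `n_in`, `n_removed`, `n_out`).
#' @export
hardFilter <- function(variants, cfg = filterConfig()) {
    rd <- rowData(variants)
    dp <- assay(variants, "DP")
    depth <- if (cfg$dp_rule == "mean") rowMeans(dp) else
        apply(dp, 1, min)
    ltNA <- function(x, thr) !is.na(x) & x < thr
    fail <- depth < cfg$min_dp |
        ltNA(rd$MQ, cfg$min_mq) |
        ltNA(rd$QD, cfg$min_qd) |
        ltNA(rd$MQRankSum, cfg$min_mqranksum) |
        ltNA(rd$ReadPosRankSum, cfg$min_readposranksum)
    list(variants = .subsetVS(variants, !fail),
         audit = .auditRow("hard_filter", nrow(variants), sum(!fail)))
}

#' Splice-junction coordinates of an annotation
#'
#' One genomic position per exon--intron boundary (last base of each
#' internal exon end and first base of each internal exon start), over all
#' multi-exon transcripts.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return [GenomicRanges::GRanges] of width-1 junction positions.
#' @export
spliceJunctions <- function(annotation) {
    ex <- exonRanges(annotation)
    multi <- ex[vapply(ex, length, 0L) >= 2L]
    if (length(multi) == 0L) return(GRanges())
    pts <- lapply(multi, function(g) {
        k <- length(g)
        pos <- c(end(g)[-k], start(g)[-1])
        GRanges(seqnames(g)[1], IRanges(pos, width = 1L))
    })
    sort(unique(unlist(GRangesList(pts))))
}

#' Genomic-context filter
#'
#' Removes sites within `splice_window` nt of any exon--intron boundary,
#' or overlapping any region mask (simple-sequence repeats, paralogs,
#' bidirectional-gene neighbourhoods, custom).
#'
#' @inheritParams hardFilter
#' @param annotation a [GenomeAnnotation-class].
#' @param masks named `GRangesList` of region masks (may be empty).
#' @return list with `variants` and `audit` as in [hardFilter()].
#' @export
contextFilter <- function(variants, annotation, masks = GRangesList(),
                          cfg = filterConfig()) {
    sites <- granges(rowRanges(variants))
    jn <- spliceJunctions(annotation)
    near_jn <- rep(FALSE, length(sites))
    if (length(jn) > 0L) {
        win <- GRanges(seqnames(jn),
                       IRanges(start(jn) - cfg$splice_window,
                               start(jn) + cfg$splice_window))
        near_jn <- overlapsAny(sites, win, ignore.strand = TRUE)
    }
    in_mask <- rep(FALSE, length(sites))
    if (length(masks) > 0L) {
        allm <- unlist(masks, use.names = FALSE)
        if (length(allm) > 0L) {
            in_mask <- overlapsAny(sites, allm, ignore.strand = TRUE)
        }
    }
    keep <- !(near_jn | in_mask)
    list(variants = .subsetVS(variants, keep),
         audit = .auditRow("context_filter", nrow(variants), sum(keep)))
}

#' Alternative-allele prevalence filter
#'
#' Keeps a site iff the alternative allele is observed (alt depth > 0) in
#' at least `ceil(min_alt_sample_fraction * n_samples)` samples.
#'
#' @inheritParams hardFilter
#' @export
prevalenceFilter <- function(variants, cfg = filterConfig()) {
    need <- ceiling(cfg$min_alt_sample_fraction * ncol(variants))
    keep <- rowSums(assay(variants, "altDepth") > 0) >= need
    list(variants = .subsetVS(variants, keep),
         audit = .auditRow("prevalence_filter", nrow(variants), sum(keep)))
}

#' Per-sample alternative allele fractions
#'
#' `AAF = alt / (alt + ref)` per sample; `NA` where the site has no
#' informative reads in that sample (excluded from group means).
#'
#' @param variants a [VariantSet-class].
#' @return Numeric matrix, sites x samples.
#' @export
aafMatrix <- function(variants) {
    a <- assay(variants, "altDepth")
    r <- assay(variants, "refDepth")
    tot <- a + r
    out <- a / tot
    out[tot == 0] <- NA_real_
    out
}

#' Group-mean alternative allele fractions
#'
#' @param aaf matrix from [aafMatrix()].
#' @param groups two-level factor over samples (control level first).
#' @return Two-column matrix of group means over samples with defined AAF
#'   (columns named by group level).
#' @export
groupMeanAAF <- function(aaf, groups) {
    groups <- as.factor(groups)
    if (nrow(aaf) == 0L) {
        return(matrix(numeric(0), 0, nlevels(groups),
                      dimnames = list(NULL, levels(groups))))
    }
    out <- vapply(levels(groups), function(g) {
        rowMeans(aaf[, groups == g, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(aaf)))
    out <- matrix(out, nrow = nrow(aaf),
                  dimnames = list(rownames(aaf), levels(groups)))
    out[is.nan(out)] <- NA_real_
    out
}

#' Known-SNP and hypervariable-AAF filter
#'
#' Removes a site when it carries a known-SNP identifier (`rs_id`), or when
#' any inspected sample's AAF exceeds `max_sample_aaf` (strict `>`), the
#' guard against germline variants and fixed differences.
#'
#' @inheritParams hardFilter
#' @param groups two-level factor over samples; only needed when
#'   `cfg$aaf_scope = "treated"` (then only treatment samples, the second
#'   level, are inspected).
#' @export
snpAafFilter <- function(variants, cfg = filterConfig(), groups = NULL) {
    aaf <- aafMatrix(variants)
    if (cfg$aaf_scope == "treated") {
        if (is.null(groups)) stop("groups required for aaf_scope='treated'")
        groups <- as.factor(groups)
        aaf <- aaf[, groups == levels(groups)[2], drop = FALSE]
    }
    hi <- apply(aaf, 1, function(x) any(!is.na(x) & x > cfg$max_sample_aaf))
    is_snp <- !is.na(rowData(variants)$rs_id)
    keep <- !(is_snp | hi)
    list(variants = .subsetVS(variants, keep),
         audit = .auditRow("snp_aaf_filter", nrow(variants), sum(keep)))
}

#' Chi-square allelic-imbalance statistic for pooled 2x2 depth tables
#'
#' The homogeneity chi-square (df = 1, no continuity correction) of the
#' table `rbind(c(alt1, ref1), c(alt2, ref2))`,
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)`. Degenerate tables (a zero margin)
#' yield statistic 0 and p = 1.
#'
#' @param alt1,ref1 pooled alt/ref depths in group 1 (vectorized).
#' @param alt2,ref2 pooled alt/ref depths in group 2.
#' @return list with `stat` and `p` (two-sided, upper tail of chisq df 1).
#' @export
allelicImbalanceChisq <- function(alt1, ref1, alt2, ref2) {
    a <- as.numeric(alt1); b <- as.numeric(ref1)
    c <- as.numeric(alt2); d <- as.numeric(ref2)
    n <- a + b + c + d
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    p[denom == 0] <- 1
    list(stat = stat, p = p)
}

#' Differential editing test across two groups
#'
#' Per site, pools alt/ref depths within each group into a 2x2 table and
#' applies the chi-square allelic-imbalance test; p-values are adjusted by
#' Benjamini-Hochberg across all tested sites. The effect size `daaf` is
#' the difference of group means of per-sample AAFs (treatment minus
#' control), robust to per-sample depth imbalance, and is reported next to
#' the pooled-depth test. Sites with zero informative depth in a group get
#' `p = 1` and are flagged.
#'
#' @param variants a [VariantSet-class] (typically post-filter survivors).
#' @param groups two-level factor over samples (control first).
#' @param cfg a [filterConfig()]; supplies the `|dAAF|` and FDR candidate
#'   thresholds.
#' @return data.frame with one row per site: `site_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `aaf_control`, `aaf_treated`, `daaf`, `chi2_stat`, `p`,
#'   `fdr`, `zero_depth_group`, `significant` (FDR and `|dAAF|` rule, before
#'   the canonical restriction).
#' @export
differentialEditing <- function(variants, groups, cfg = filterConfig()) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stop("exactly two groups are required")
    gA <- groups == levels(groups)[1]   # control
    gB <- groups == levels(groups)[2]   # treatment
    altm <- assay(variants, "altDepth")
    refm <- assay(variants, "refDepth")
    altA <- rowSums(altm[, gA, drop = FALSE]); refA <- rowSums(refm[, gA, drop = FALSE])
    altB <- rowSums(altm[, gB, drop = FALSE]); refB <- rowSums(refm[, gB, drop = FALSE])
    test <- allelicImbalanceChisq(altB, refB, altA, refA)
    zero <- (altA + refA) == 0 | (altB + refB) == 0
    test$p[zero] <- 1
    test$stat[zero] <- 0
    aaf <- aafMatrix(variants)
    gm <- groupMeanAAF(aaf, groups)
    daaf <- gm[, 2] - gm[, 1]
    fdr <- bhAdjust(test$p)
    rr <- rowRanges(variants)
    rd <- rowData(variants)
    data.frame(
        site_id = names(rr),
        chrom = as.character(seqnames(rr)),
        pos = start(rr),
        ref = rd$ref, alt = rd$alt,
        aaf_control = unname(gm[, 1]),
        aaf_treated = unname(gm[, 2]),
        daaf = unname(daaf),
        chi2_stat = test$stat,
        p = test$p,
        fdr = fdr,
        zero_depth_group = zero,
        significant = fdr < cfg$fdr_threshold &
            !is.na(daaf) & abs(daaf) > cfg$daaf_threshold & !zero,
        row.names = NULL, stringsAsFactors = FALSE
    )
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Canonical substitution class of an SNV
#'
#' A-to-I editing reads as A->G on the sense strand, so it appears as A->G
#' for plus-strand host genes and T->C for minus-strand hosts; C-to-U reads
#' as C->T (plus) / G->A (minus). Everything else is noncanonical.
#' Intergenic sites are assessed on the genomic plus strand.
#'
#' @param ref,alt single reference/alternative bases (vectorized).
#' @param host_strand `"+"` or `"-"` per site.
#' @return Character vector: `"A_to_I"`, `"C_to_U"` or `"noncanonical"`.
#' @export
classifySubstitution <- function(ref, alt, host_strand = "+") {
    n <- max(length(ref), length(alt), length(host_strand))
    ref <- rep_len(toupper(ref), n)
    alt <- rep_len(toupper(alt), n)
    host_strand <- rep_len(host_strand, n)
    ## express the substitution on the host gene's sense strand
    sref <- ifelse(host_strand == "-", COMPLEMENT[ref], ref)
    salt <- ifelse(host_strand == "-", COMPLEMENT[alt], alt)
    out <- rep("noncanonical", n)
    out[sref == "A" & salt == "G"] <- "A_to_I"
    out[sref == "C" & salt == "T"] <- "C_to_U"
    out
}

## map a genomic position into spliced CDS coordinates (1-based, 5'->3')
.cdsCoordinate <- function(cd, strand, pos) {
    w <- width(cd)
    seg <- which(pos >= start(cd) & pos <= end(cd))
    if (length(seg) == 0L) return(NA_integer_)
    if (strand == "+") {
        sum(w[seq_len(seg - 1L)]) + (pos - start(cd)[seg] + 1L)
    } else {
        k <- length(cd)
        after <- if (seg < k) sum(w[(seg + 1L):k]) else 0L
        after + (end(cd)[seg] - pos + 1L)
    }
}

.severity <- c(missense = 1, synonymous = 2, five_prime_utr = 3,
               three_prime_utr = 4, noncoding_exonic = 5, intron = 6,
               upstream = 7, downstream = 8, intergenic = 9)

.consequenceInTranscript <- function(annotation, genome, tx_id, chrom, pos,
                                     ref, alt) {
    tx <- txTable(annotation)[tx_id, ]
    ex <- exonsOf(annotation, tx_id)
    cd <- cdsOf(annotation, tx_id)
    in_exon <- any(pos >= start(ex) & pos <= end(ex))
    if (!in_exon) return("intron")
    if (length(cd) == 0L) return("noncoding_exonic")
    cpos <- .cdsCoordinate(cd, tx$strand, pos)
    if (is.na(cpos)) {
        ## exonic but outside the CDS: UTR side depends on strand
        if (tx$strand == "+") {
            return(if (pos < min(start(cd))) "five_prime_utr"
                   else "three_prime_utr")
        }
        return(if (pos > max(end(cd))) "five_prime_utr"
               else "three_prime_utr")
    }
    cds_seq <- splicedCds(annotation, genome, tx_id)
    codon_i <- (cpos - 1L) %/% 3L
    offset <- (cpos - 1L) %% 3L
    ref_codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_base <- if (tx$strand == "-") COMPLEMENT[[toupper(alt)]] else
        toupper(alt)
    alt_codon <- ref_codon
    substr(alt_codon, offset + 1L, offset + 1L) <- alt_base
    aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
    aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
    if (identical(aa_ref, aa_alt)) "synonymous" else "missense"
}

#' Variant consequence annotation
#'
#' Classifies each site against the annotation: CDS positions are
#' translated on the coding strand (standard genetic code) to call
#' missense vs synonymous; exonic non-CDS positions become 5'/3' UTR (for
#' coding transcripts) or `noncoding_exonic`; intra-gene non-exonic
#' positions are intronic; sites within `upstream_downstream_window` nt of
#' a gene but outside it are upstream/downstream relative to the gene's
#' strand; everything else is intergenic. When several transcripts or
#' genes overlap a site, the most severe consequence wins
#' (missense > synonymous > 5'UTR > 3'UTR > noncoding exon > intron >
#' upstream > downstream > intergenic).
#'
#' @param variants a [VariantSet-class] or a data.frame with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param annotation a [GenomeAnnotation-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param cfg a [filterConfig()] (supplies the upstream/downstream window).
#' @return data.frame with columns `consequence` and `host_gene` (`NA` for
#'   intergenic sites).
#' @export
annotateConsequence <- function(variants, annotation, genome,
                                cfg = filterConfig()) {
    if (methods::is(variants, "VariantSet")) {
        rr <- rowRanges(variants)
        df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                         ref = rowData(variants)$ref,
                         alt = rowData(variants)$alt,
                         stringsAsFactors = FALSE)
    } else {
        df <- as.data.frame(variants, stringsAsFactors = FALSE)
    }
    spans <- transcriptSpans(annotation)
    gspans <- geneSpans(annotation)
    n <- nrow(df)
    consequence <- character(n)
    host <- rep(NA_character_, n)
    win <- cfg$upstream_downstream_window
    for (i in seq_len(n)) {
        pos <- df$pos[i]; chrom <- df$chrom[i]
        site <- GRanges(chrom, IRanges(pos, width = 1L))
        hits <- subjectHits(findOverlaps(site, spans, ignore.strand = TRUE))
        if (length(hits) > 0L) {
            cands <- vapply(hits, function(h) {
                .consequenceInTranscript(annotation, genome, names(spans)[h],
                                         chrom, pos, df$ref[i], df$alt[i])
            }, character(1))
            best <- which.min(.severity[cands])
            consequence[i] <- cands[best]
            host[i] <- mcols(spans)$gene_id[hits[best]]
            next
        }
        near <- subjectHits(findOverlaps(
            GRanges(chrom, IRanges(max(1L, pos - win), pos + win)),
            gspans, ignore.strand = TRUE))
        if (length(near) > 0L) {
            cands <- vapply(near, function(h) {
                g <- gspans[h]
                before <- pos < start(g)   # genomically left of the gene
                plus <- as.character(strand(g)) != "-"
                if (before == plus) "upstream" else "downstream"
            }, character(1))
            best <- which.min(.severity[cands])
            consequence[i] <- cands[best]
            host[i] <- mcols(gspans)$gene_id[near[best]]
        } else {
            consequence[i] <- "intergenic"
        }
    }
    data.frame(consequence = consequence, host_gene = host,
               stringsAsFactors = FALSE)
}

#' Run the full editing-site discovery cascade
#'
#' Applies, in order: hard filters, genomic-context filters, the
#' alternative-allele prevalence filter, the known-SNP / hypervariable-AAF
#' filter, the differential chi-square allelic-imbalance test with FDR and
#' `|dAAF|` thresholds, and the canonical A-to-I / C-to-U restriction.
#' Surviving candidates receive a consequence annotation. Each stage
#' appends one audit row and the audit chains (`n_out` of one stage equals
#' `n_in` of the next).
#'
#' @param variants a [VariantSet-class] (all called SNVs).
#' @param annotation a [GenomeAnnotation-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param masks named `GRangesList` of region masks.
#' @param groups two-level factor over samples (control level first).
#' @param cfg a [filterConfig()].
#' @return list with `candidates` (data.frame of surviving editing
#'   candidates with AAF statistics, canonical class, consequence and host
#'   gene), `tested` (the full [differentialEditing()] table for all sites
#'   reaching the test), and `audit` (stage-by-stage counts).
#' @export
runEditingCascade <- function(variants, annotation, genome,
                              masks = GRangesList(), groups,
                              cfg = filterConfig()) {
    s1 <- hardFilter(variants, cfg)
    s2 <- contextFilter(s1$variants, annotation, masks, cfg)
    s3 <- prevalenceFilter(s2$variants, cfg)
    s4 <- snpAafFilter(s3$variants, cfg, groups)
    audit <- rbind(s1$audit, s2$audit, s3$audit, s4$audit)

    tested <- differentialEditing(s4$variants, groups, cfg)
    sig <- tested[tested$significant, , drop = FALSE]
    audit <- rbind(audit, .auditRow("daaf_test", nrow(tested), nrow(sig)))

    if (nrow(sig) > 0L) {
        hostinfo <- .hostStrand(sig, annotation)
        sig$canonical_class <- classifySubstitution(sig$ref, sig$alt,
                                                    hostinfo$strand)
    } else {
        sig$canonical_class <- character(0)
    }
    cand <- sig[sig$canonical_class != "noncanonical", , drop = FALSE]
    audit <- rbind(audit, .auditRow("canonical", nrow(sig), nrow(cand)))

    if (nrow(cand) > 0L) {
        cons <- annotateConsequence(cand, annotation, genome, cfg)
        cand$consequence <- cons$consequence
        cand$host_gene <- cons$host_gene
    } else {
        cand$consequence <- character(0)
        cand$host_gene <- character(0)
    }
    rownames(cand) <- NULL
    list(candidates = cand, tested = tested, audit = audit)
}

## strand of the host gene for each site; intergenic sites default to "+"
.hostStrand <- function(df, annotation) {
    gspans <- geneSpans(annotation)
    sites <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    hits <- findOverlaps(sites, gspans, ignore.strand = TRUE)
    strand_out <- rep("+", nrow(df))
    gene_out <- rep(NA_character_, nrow(df))
    first <- !duplicated(queryHits(hits))
    strand_out[queryHits(hits)[first]] <-
        as.character(strand(gspans))[subjectHits(hits)[first]]
    gene_out[queryHits(hits)[first]] <-
        names(gspans)[subjectHits(hits)[first]]
    list(strand = strand_out, gene = gene_out)
}
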