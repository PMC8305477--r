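suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

## one shared default simulation, generated once per session
.fixture_env <- new.env(parent = emptyenv())
defaultSim <- function() {
    if (is.null(.fixture_env$sim)) {
        .fixture_env$sim <- simulateStudy(simulationConfig(seed = 22))
    }
    .fixture_env$sim
}

## small hand-built annotation: `txs` is a list of lists with fields
## id, gene, chrom, strand, biotype, exons (2-col matrix), cds (or NULL)
toyAnnotation <- function(txs) {
    tab <- do.call(rbind, lapply(txs, function(t) data.frame(
        transcript_id = t$id, gene_id = t$gene, chrom = t$chrom,
        strand = t$strand, biotype = t$biotype, stringsAsFactors = FALSE)))
    exons <- GRangesList(lapply(txs, function(t)
        GRanges(t$chrom, IRanges(t$exons[, 1], t$exons[, 2]))))
    names(exons) <- tab$transcript_id
    cds <- GRangesList(lapply(txs, function(t) {
        if (is.null(t$cds)) GRanges() else
            GRanges(t$chrom, IRanges(t$cds[, 1], t$cds[, 2]))
    }))
    names(cds) <- tab$transcript_id
    GenomeAnnotation(tab, exons, cds)
}

## one-call VariantSet builder; depth matrices may be vectors for one site
toyVariants <- function(chrom = "chr1", pos, ref = "A", alt = "G",
                        refD, altD, DP = NULL,
                        QD = 20, MQ = 50, MQRankSum = 0,
                        ReadPosRankSum = 0, rs_id = NA_character_) {
    refD <- rbind(refD); altD <- rbind(altD)
    if (is.null(DP)) DP <- refD + altD else DP <- rbind(DP)
    samples <- paste0("s", seq_len(ncol(refD)))
    VariantSet(chrom = rep_len(chrom, length(pos)), pos = pos,
               ref = rep_len(ref, length(pos)),
               alt = rep_len(alt, length(pos)),
               refDepth = refD, altDepth = altD, DP = DP,
               samples = samples, QD = QD, MQ = MQ,
               MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
               rs_id = rs_id)
}

## ---- independent brute-force oracles --------------------------------------

## BH step-up computed literally from the definition
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    padj <- numeric(n)
    sorted <- p[o] * n / seq_len(n)
    for (i in seq_len(n)) padj[i] <- min(1, min(sorted[i:n]))
    out <- numeric(n)
    out[o] <- padj
    out
}

## longest ATG..stop ORF by scanning every start position codon-by-codon
bruteOrf <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq)
    stops <- c("TAA", "TAG", "TGA")
    best <- 0L
    for (i in seq_len(max(0L, n - 2L))) {
        if (substr(seq, i, i + 2L) != "ATG") next
        j <- i
        len <- 0L
        while (j + 2L <= n) {
            cod <- substr(seq, j, j + 2L)
            if (cod %in% stops && j > i) break
            len <- len + 1L
            j <- j + 3L
        }
        if (j + 2L <= n && substr(seq, j, j + 2L) %in% stops) {
            best <- max(best, len)
        }
    }
    best
}

## all-pairs Pearson on log2(x+1) computed with explicit loops
brutePearsonPairs <- function(lnc, mrna, threshold) {
    la <- log2(lnc + 1); lb <- log2(mrna + 1)
    out <- list()
    for (i in seq_len(nrow(la))) for (j in seq_len(nrow(lb))) {
        x <- la[i, ]; y <- lb[j, ]
        if (sd(x) == 0 || sd(y) == 0) next
        r <- sum((x - mean(x)) * (y - mean(y))) /
            ((length(x) - 1) * sd(x) * sd(y))
        if (abs(r) >= threshold) {
            out[[length(out) + 1L]] <- data.frame(
                lncrna_id = rownames(la)[i], target_gene_id = rownames(lb)[j],
                r = r, stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L) {
        return(data.frame(lncrna_id = character(),
                          target_gene_id = character(), r = numeric()))
    }
    do.call(rbind, out)
}

## splice-junction removal decided by an explicit distance scan
bruteJunctionRemoved <- function(site_chrom, site_pos, jn_chrom, jn_pos,
                                 window) {
    vapply(seq_along(site_pos), function(i) {
        same <- jn_chrom == site_chrom[i]
        any(same & abs(jn_pos - site_pos[i]) <= window)
    }, logical(1))
}

## an annotation+genome pair with known consequences, used by the
## consequence and spliced-sequence tests
consequenceFixture <- function() {
    len <- 15000L
    base <- paste(rep("ACGT", len / 4L), collapse = "")
    ## + strand gene: exons 8001-8060 / 8101-8160, CDS 8011-8040 = AAA x10
    substr(base, 8011, 8040) <- paste(rep("A", 30), collapse = "")
    ## - strand gene: exon 9501-9560, CDS 9511-9540 = TTT x10 (AAA on -)
    substr(base, 9511, 9540) <- paste(rep("T", 30), collapse = "")
    genome <- DNAStringSet(c(chrT = base))
    ann <- toyAnnotation(list(
        list(id = "txP", gene = "gP", chrom = "chrT", strand = "+",
             biotype = "protein_coding",
             exons = rbind(c(8001, 8060), c(8101, 8160)),
             cds = rbind(c(8011, 8040))),
        list(id = "txM", gene = "gM", chrom = "chrT", strand = "-",
             biotype = "protein_coding",
             exons = rbind(c(9501, 9560)),
             cds = rbind(c(9511, 9540)))
    ))
    list(genome = genome, annotation = ann)
}
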