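#' @include core_io.R
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic two-group study: a toy genome with
#' multi-exon coding genes, multi-exon low-coding-potential lncRNAs,
#' head-to-head bidirectional gene pairs and repeat regions; NB-distributed
#' counts with planted log2 fold changes; and per-sample allele depths at
#' planted editing sites (group-differential editing rates), germline SNPs
#' and sequencing-noise sites. Defaults mirror the study design this
#' package targets: 2 groups x 3 replicates, biological CV 0.1
#' (`nb_dispersion = 0.01`), planted fold change 4 (`lfc_magnitude = 2`),
#' site depth 50, editing rates 0.40 (treated) vs 0.05 (control), 50
#' editing sites, 200 SNP sites and 500 noise sites.
#'
#' @param seed RNG seed; stage generators use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param n_chroms,chrom_min_length toy genome shape (chromosomes are
#'   padded to at least `chrom_min_length` bases).
#' @param n_coding_genes,n_lncrnas,n_bidirectional_pairs gene content.
#' @param replicates_per_group samples per group (>= 2).
#' @param de_fraction fraction of TARs with a planted fold change.
#' @param lfc_magnitude planted |log2FC| (random sign).
#' @param nb_dispersion NB dispersion of counts (CV^2 at high mean).
#' @param size_factor_range per-sample library size factors are drawn
#'   log-uniformly from this range.
#' @param mean_depth_at_sites Poisson mean of per-sample depth at variant
#'   sites.
#' @param n_editing_sites,editing_rate_treated,editing_rate_control planted
#'   editing sites and their per-group per-read editing probabilities.
#' @param editing_overdispersion beta-binomial overdispersion (intra-class
#'   correlation) of alt counts at editing sites; 0 = pure binomial.
#' @param n_snp_sites germline SNP sites (rs-annotated; per-site AAF class
#'   near 0, 0.5 or 1).
#' @param n_noise_sites sequencing-noise sites (alt reads at rate
#'   `noise_rate`).
#' @param noise_rate per-read error rate at noise sites.
#' @param hard_filter_fail_fraction fraction of noise sites whose INFO
#'   annotations are drawn to fail one hard filter.
#' @param lncrna_annotated_fraction fraction of lncRNAs emitted with the
#'   `lncRNA` biotype; the rest are emitted as `novel` so the
#'   coding-potential cascade must recover them.
#' @return A validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 22L,
                             n_chroms = 2L,
                             chrom_min_length = 50000L,
                             n_coding_genes = 30L,
                             n_lncrnas = 30L,
                             n_bidirectional_pairs = 3L,
                             replicates_per_group = 3L,
                             de_fraction = 0.1,
                             lfc_magnitude = 2,
                             nb_dispersion = 0.01,
                             size_factor_range = c(0.7, 1.4),
                             mean_depth_at_sites = 50,
                             n_editing_sites = 50L,
                             editing_rate_treated = 0.4,
                             editing_rate_control = 0.05,
                             editing_overdispersion = 0,
                             n_snp_sites = 200L,
                             n_noise_sites = 500L,
                             noise_rate = 0.01,
                             hard_filter_fail_fraction = 0.1,
                             lncrna_annotated_fraction = 0) {
    cfg <- as.list(environment())
    counts <- unlist(cfg[c("n_chroms", "n_coding_genes", "n_lncrnas",
                           "n_bidirectional_pairs", "n_editing_sites",
                           "n_snp_sites", "n_noise_sites")])
    if (any(counts < 0)) stop("all counts must be >= 0")
    if (cfg$n_chroms < 1L) stop("need at least one chromosome")
    if (cfg$replicates_per_group < 2L) stop("need >= 2 replicates per group")
    rates <- unlist(cfg[c("editing_rate_treated", "editing_rate_control",
                          "noise_rate")])
    if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
    if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    structure(cfg, class = "simulationConfig")
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) {
    paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## fixed codon-usage bias for synthetic CDS: the alphabetically first codon
## of each amino acid is strongly preferred, giving coding sequence a
## reproducible hexamer signature across seeds
.codonTable <- local({
    codons <- do.call(paste0, expand.grid(.BASES, .BASES, .BASES,
                                          stringsAsFactors = FALSE)[, 3:1])
    codons <- sort(codons)
    aa <- vapply(codons, function(cd) Biostrings::GENETIC_CODE[[cd]],
                 character(1))
    keep <- aa != "*" & aa != "M"   # no stops; ATG reserved for starts
    codons <- codons[keep]; aa <- aa[keep]
    w <- numeric(length(codons))
    for (a in unique(aa)) {
        idx <- which(aa == a)
        w[idx] <- 1
        w[idx[1]] <- 6
    }
    list(codons = codons, weights = w / sum(w))
})

.randCds <- function(n_codons) {
    body <- sample(.codonTable$codons, n_codons - 2L, replace = TRUE,
                   prob = .codonTable$weights)
    paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

## random sequence with stop codons planted in all three frames at least
## every `every` bases, keeping any sense-strand ORF short
.randNoncodingSeq <- function(n, every = 60L) {
    s <- .randSeq(n)
    blocker <- "TTAATTAATTAA"   # stops in all three frames
    p <- 1L
    while (p + nchar(blocker) - 1L <= n) {
        substr(s, p, p + nchar(blocker) - 1L) <- blocker
        p <- p + every
    }
    s
}

## split a length into k chunks, each >= min_len
.splitLength <- function(L, k, min_len = 30L) {
    if (k == 1L) return(L)
    free <- L - k * min_len
    cuts <- sort(sample.int(free + 1L, k - 1L, replace = TRUE) - 1L)
    diff(c(0L, cuts, free)) + min_len
}

## lay a spliced transcript onto the genome at cursor `g0`; returns genomic
## sequence of the locus, exon/CDS GRanges, and the locus length
.placeTranscript <- function(spliced, exon_lens, strand, chrom, g0,
                             cds_span = NULL, intron_range = c(80L, 250L)) {
    k <- length(exon_lens)
    intron_lens <- if (k > 1L) {
        sample(seq(intron_range[1], intron_range[2]), k - 1L, replace = TRUE)
    } else integer(0)
    ## spliced coordinates of each exon, 5'->3'
    sp_end <- cumsum(exon_lens)
    sp_start <- sp_end - exon_lens + 1L
    if (strand == "+") {
        chunks <- substring(spliced, sp_start, sp_end)
        g_order <- seq_len(k)
    } else {
        rc <- function(x) as.character(reverseComplement(DNAString(x)))
        chunks <- vapply(rev(seq_len(k)), function(j)
            rc(substring(spliced, sp_start[j], sp_end[j])), character(1))
        g_order <- rev(seq_len(k))   # g_order[m] = spliced exon at slot m
    }
    g_lens <- exon_lens[g_order]
    g_end <- g0 - 1L + cumsum(g_lens + c(intron_lens, 0L)) -
        c(intron_lens, 0L)
    g_start <- g_end - g_lens + 1L
    pieces <- character(2L * k - 1L)
    pieces[seq(1L, 2L * k - 1L, by = 2L)] <- chunks
    if (k > 1L) {
        pieces[seq(2L, 2L * k - 2L, by = 2L)] <-
            vapply(intron_lens, .randSeq, character(1))
    }
    locus_seq <- paste(pieces, collapse = "")
    exons <- GRanges(chrom, IRanges(g_start, g_end))
    cds <- GRanges()
    if (!is.null(cds_span)) {
        segs <- list()
        for (m in seq_len(k)) {
            j <- g_order[m]
            a <- max(cds_span[1], sp_start[j])
            b <- min(cds_span[2], sp_end[j])
            if (a > b) next
            if (strand == "+") {
                segs[[length(segs) + 1L]] <-
                    c(g_start[m] + (a - sp_start[j]),
                      g_start[m] + (b - sp_start[j]))
            } else {
                segs[[length(segs) + 1L]] <-
                    c(g_end[m] - (b - sp_start[j]),
                      g_end[m] - (a - sp_start[j]))
            }
        }
        segs <- do.call(rbind, segs)
        cds <- sort(GRanges(chrom, IRanges(segs[, 1], segs[, 2])))
    }
    list(seq = locus_seq, exons = exons, cds = cds,
         len = nchar(locus_seq))
}

.codingTemplate <- function() {
    utr5 <- .randNoncodingSeq(sample(40:90, 1L))
    n_codons <- sample(120:250, 1L)
    cds <- .randCds(n_codons)
    utr3 <- .randNoncodingSeq(sample(80:200, 1L))
    spliced <- paste0(utr5, cds, utr3)
    k <- sample(2:4, 1L)
    list(spliced = spliced,
         exon_lens = .splitLength(nchar(spliced), k),
         cds_span = c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds)))
}

.lncTemplate <- function() {
    len <- sample(400:1200, 1L)
    k <- sample(2:3, 1L)
    list(spliced = .randNoncodingSeq(len),
         exon_lens = .splitLength(len, k),
         cds_span = NULL)
}

#' Generate the synthetic genome, annotation and region masks
#'
#' Coding genes carry in-frame CDS with start and stop codons and a fixed
#' codon-usage bias; lncRNAs are multi-exon, > 200 nt and ORF-poor by
#' construction (stop codons planted in all three frames at least every
#' 60 nt of the spliced sequence); bidirectional pairs are head-to-head
#' genes with TSS distance < 1 kb, covered by the `bidirectional` mask;
#' the `ssr` mask covers planted (AC)n runs and the `paralog` mask a few
#' random intergenic intervals.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([GenomeAnnotation-class]), `masks` (named `GRangesList`) and
#'   `lncrna_truth` (data.frame `transcript_id`, `is_lncRNA`).
#' @export
simulateGenomeAnnotation <- function(config) {
    set.seed(config$seed)
    n_pair_genes <- 2L * config$n_bidirectional_pairs
    units <- c(rep("coding", config$n_coding_genes),
               rep("lnc", config$n_lncrnas))
    units <- sample(units)
    n_annot_lnc <- round(config$lncrna_annotated_fraction * config$n_lncrnas)
    lnc_seen <- 0L

    chrom_names <- paste0("chr", seq_len(config$n_chroms))
    chrom_units <- split(units, factor(rep_len(seq_len(config$n_chroms),
                                               length(units)),
                                       levels = seq_len(config$n_chroms)))
    pair_chrom <- rep_len(seq_len(config$n_chroms),
                          config$n_bidirectional_pairs)

    tx_rows <- list(); exon_l <- list(); cds_l <- list()
    masks <- list(ssr = list(), paralog = list(), bidirectional = list())
    genomes <- character(config$n_chroms)
    gi <- 0L; ti <- 0L

    addTx <- function(gene_id, tx_id, chrom, strand, biotype, placed) {
        tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
            transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
            strand = strand, biotype = biotype, stringsAsFactors = FALSE)
        exon_l[[tx_id]] <<- placed$exons
        cds_l[[tx_id]] <<- placed$cds
    }

    for (ci in seq_len(config$n_chroms)) {
        chrom <- chrom_names[ci]
        pieces <- character(0)
        cursor <- 1L
        emitGap <- function(with_ssr = FALSE) {
            gap <- .randSeq(sample(250:700, 1L))
            if (with_ssr) {
                run <- paste(rep("AC", sample(15:30, 1L)), collapse = "")
                at <- sample(50:150, 1L)
                masks$ssr[[length(masks$ssr) + 1L]] <<-
                    GRanges(chrom, IRanges(cursor + at,
                                           cursor + at + nchar(run) - 1L))
                gap <- paste0(substr(gap, 1L, at - 1L), run,
                              substr(gap, at, nchar(gap)))
            }
            pieces[length(pieces) + 1L] <<- gap
            cursor <<- cursor + nchar(gap)
        }
        emitGene <- function(kind, strand, biotype_override = NULL) {
            gi <<- gi + 1L; ti <<- ti + 1L
            tpl <- if (kind == "coding") .codingTemplate() else .lncTemplate()
            placed <- .placeTranscript(tpl$spliced, tpl$exon_lens, strand,
                                       chrom, cursor, tpl$cds_span)
            biotype <- if (!is.null(biotype_override)) biotype_override
                else if (kind == "coding") "protein_coding" else "novel"
            gene_id <- sprintf("G%04d", gi)
            tx_id <- sprintf("T%04d", ti)
            addTx(gene_id, tx_id, chrom, strand, biotype, placed)
            pieces[length(pieces) + 1L] <<- placed$seq
            cursor <<- cursor + placed$len
            list(gene_id = gene_id, tx_id = tx_id,
                 start = cursor - placed$len, end = cursor - 1L,
                 kind = kind)
        }

        ## bidirectional pairs assigned to this chromosome
        for (p in which(pair_chrom == ci)) {
            emitGap()
            g1 <- emitGene("coding", "-")
            tss_gap <- sample(150:800, 1L)
            pieces[length(pieces) + 1L] <- .randSeq(tss_gap)
            cursor <- cursor + tss_gap
            g2 <- emitGene("coding", "+")
            masks$bidirectional[[length(masks$bidirectional) + 1L]] <-
                GRanges(chrom, IRanges(g1$start, g2$end))
        }
        for (kind in chrom_units[[ci]]) {
            emitGap(with_ssr = runif(1) < 0.3)
            strand <- sample(c("+", "-"), 1L)
            override <- NULL
            if (kind == "lnc") {
                lnc_seen <- lnc_seen + 1L
                if (lnc_seen <= n_annot_lnc) override <- "lncRNA"
            }
            emitGene(kind, strand, override)
        }
        emitGap()
        seq <- paste(pieces, collapse = "")
        if (nchar(seq) < config$chrom_min_length) {
            seq <- paste0(seq, .randSeq(config$chrom_min_length - nchar(seq)))
        }
        ## a couple of paralog-mask intervals in the padded tail
        tail0 <- cursor + 50L
        if (tail0 + 400L < nchar(seq)) {
            masks$paralog[[length(masks$paralog) + 1L]] <-
                GRanges(chrom, IRanges(tail0, tail0 + 200L))
        }
        genomes[ci] <- seq
    }

    genome <- DNAStringSet(genomes)
    names(genome) <- chrom_names
    tx <- do.call(rbind, tx_rows)
    annotation <- GenomeAnnotation(tx, GRangesList(exon_l),
                                   GRangesList(cds_l))
    maskGRL <- GRangesList(lapply(masks, function(lst) {
        if (length(lst) == 0L) return(GRanges())
        reduce(unlist(GRangesList(lst)))
    }))
    is_lnc <- tx$biotype %in% c("novel", "lncRNA") &
        vapply(tx$transcript_id, function(t) length(cds_l[[t]]) == 0L,
               logical(1))
    lncrna_truth <- data.frame(transcript_id = tx$transcript_id,
                               is_lncRNA = unname(is_lnc),
                               stringsAsFactors = FALSE)
    list(genome = genome, annotation = annotation, masks = maskGRL,
         lncrna_truth = lncrna_truth)
}

#' Generate the NB count matrix with planted fold changes
#'
#' Counts follow `NB(mean = mu_g * s_j * 2^(LFC_g * treated_j),
#' dispersion)` with per-sample size factors drawn log-uniformly from the
#' configured range; a `de_fraction` of TARs receive `|LFC| =
#' lfc_magnitude` with random sign. Baseline means are log-uniform in
#' [50, 2000].
#'
#' @param config a [simulationConfig()].
#' @param annotation the [GenomeAnnotation-class] providing the TAR
#'   universe (one TAR per transcript).
#' @return list with `counts` (a `SummarizedExperiment`), `design`
#'   (data.frame) and `de_truth` (data.frame `tar_id`, `lfc`,
#'   `direction`).
#' @export
simulateCounts <- function(config, annotation) {
    set.seed(config$seed + 1L)
    tar_ids <- txTable(annotation)$transcript_id
    nt <- length(tar_ids)
    r <- config$replicates_per_group
    samples <- c(paste0("ctl_", seq_len(r)), paste0("emf_", seq_len(r)))
    group <- factor(rep(c("control", "EMF"), each = r),
                    levels = c("control", "EMF"))
    mu <- exp(runif(nt, log(50), log(2000)))
    lfc <- numeric(nt)
    n_de <- round(config$de_fraction * nt)
    if (n_de > 0L) {
        idx <- sample.int(nt, n_de)
        lfc[idx] <- config$lfc_magnitude * sample(c(-1, 1), n_de,
                                                  replace = TRUE)
    }
    sf <- exp(runif(2L * r, log(config$size_factor_range[1]),
                    log(config$size_factor_range[2])))
    m <- matrix(0L, nt, 2L * r, dimnames = list(tar_ids, samples))
    treated <- as.integer(group == "EMF")
    for (j in seq_len(2L * r)) {
        mean_j <- mu * sf[j] * 2^(lfc * treated[j])
        m[, j] <- if (config$nb_dispersion > 0) {
            rnbinom(nt, size = 1 / config$nb_dispersion, mu = mean_j)
        } else {
            rpois(nt, mean_j)
        }
    }
    design <- data.frame(sample = samples, group = group,
                         stringsAsFactors = FALSE)
    de_truth <- data.frame(
        tar_id = tar_ids, lfc = lfc,
        direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
        stringsAsFactors = FALSE)
    se <- countsExperiment(m, design)
    list(counts = se, design = design, de_truth = de_truth)
}

.rbetabinom <- function(n, size, prob, rho) {
    if (rho <= 0) return(rbinom(n, size, prob))
    ab <- (1 - rho) / rho
    p <- stats::rbeta(n, prob * ab, (1 - prob) * ab)
    rbinom(n, size, p)
}

## candidate exonic positions with the required sense-strand base, away from
## exon edges, SNP-safe
.editablePositions <- function(annotation, genome, margin = 6L) {
    tx <- txTable(annotation)
    out <- list()
    for (i in seq_len(nrow(tx))) {
        ex <- exonsOf(annotation, tx$transcript_id[i])
        want <- if (tx$strand[i] == "+") "A" else "T"
        for (j in seq_along(ex)) {
            a <- start(ex)[j] + margin; b <- end(ex)[j] - margin
            if (a > b) next
            bases <- strsplit(genomeSlice(genome, tx$chrom[i], a, b),
                              "")[[1]]
            hit <- which(bases == want)
            if (length(hit)) {
                out[[length(out) + 1L]] <- data.frame(
                    chrom = tx$chrom[i], pos = a + hit - 1L,
                    strand = tx$strand[i], gene_id = tx$gene_id[i],
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, out)
}

#' Generate per-sample variant calls with planted editing sites
#'
#' Editing sites sit at genomic `A` (plus-strand hosts) or `T`
#' (minus-strand hosts) inside transcripts, away from exon edges and
#' masks; alternative reads are drawn `Binomial(DP, group editing rate)`
#' (beta-binomial when `editing_overdispersion > 0`) with
#' `DP ~ Poisson(mean_depth_at_sites)`. Germline SNP sites carry `rs`
#' identifiers and per-site AAF class near 0, 0.5 or 1 shared by all
#' samples; noise sites draw alternative reads at `noise_rate`. INFO
#' annotations pass the hard filters except at a configured fraction of
#' noise sites, where one annotation is drawn failing.
#'
#' @param config a [simulationConfig()].
#' @param annotation,genome from [simulateGenomeAnnotation()].
#' @param masks mask `GRangesList`; planted editing sites avoid masked
#'   regions.
#' @return list with `variants` (a [VariantSet-class]) and
#'   `editing_truth` / `snp_sites` / `noise_sites` truth tables.
#' @export
simulateVariants <- function(config, annotation, genome,
                             masks = GRangesList()) {
    set.seed(config$seed + 2L)
    r <- config$replicates_per_group
    samples <- c(paste0("ctl_", seq_len(r)), paste0("emf_", seq_len(r)))
    treated <- rep(c(FALSE, TRUE), each = r)

    cand <- .editablePositions(annotation, genome)
    if (length(masks) > 0L) {
        allm <- unlist(masks, use.names = FALSE)
        if (length(allm) > 0L) {
            keep <- !overlapsAny(GRanges(cand$chrom,
                                         IRanges(cand$pos, width = 1L)),
                                 allm, ignore.strand = TRUE)
            cand <- cand[keep, , drop = FALSE]
        }
    }
    jn <- spliceJunctions(annotation)
    if (length(jn) > 0L) {
        keep <- !overlapsAny(
            GRanges(cand$chrom, IRanges(cand$pos, width = 1L)),
            GRanges(seqnames(jn), IRanges(start(jn) - 6L, start(jn) + 6L)),
            ignore.strand = TRUE)
        cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) < config$n_editing_sites) {
        stop("not enough editable exonic positions; enlarge the genome")
    }
    ed <- cand[sample.int(nrow(cand), config$n_editing_sites), , drop = FALSE]
    ed$ref <- ifelse(ed$strand == "+", "A", "T")
    ed$alt <- ifelse(ed$strand == "+", "G", "C")

    chrom_len <- setNames(width(genome), names(genome))
    used <- paste(ed$chrom, ed$pos)
    drawSites <- function(n) {
        chrom <- sample(names(genome), n, replace = TRUE)
        pos <- vapply(chrom, function(cn)
            sample.int(chrom_len[[cn]] - 20L, 1L) + 10L, integer(1))
        key <- paste(chrom, pos)
        while (anyDuplicated(key) || any(key %in% used)) {
            bad <- duplicated(key) | key %in% used
            chrom[bad] <- sample(names(genome), sum(bad), replace = TRUE)
            pos[bad] <- vapply(chrom[bad], function(cn)
                sample.int(chrom_len[[cn]] - 20L, 1L) + 10L, integer(1))
            key <- paste(chrom, pos)
        }
        used <<- c(used, key)
        ref <- vapply(seq_len(n), function(i)
            genomeSlice(genome, chrom[i], pos[i], pos[i]), character(1))
        ok <- ref %in% .BASES
        alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L),
                      character(1))
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)[ok, , drop = FALSE]
    }
    snp <- drawSites(config$n_snp_sites)
    snp$aaf_class <- sample(c(0.002, 0.5, 0.995), nrow(snp), replace = TRUE)
    snp$rs_id <- sprintf("rs%06d", seq_len(nrow(snp)))
    noise <- drawSites(config$n_noise_sites)

    n_sites <- nrow(ed) + nrow(snp) + nrow(noise)
    dp <- matrix(rpois(n_sites * 2L * r, config$mean_depth_at_sites),
                 n_sites, 2L * r)
    dp[dp == 0L] <- 1L
    altm <- matrix(0L, n_sites, 2L * r)
    i_ed <- seq_len(nrow(ed))
    i_snp <- nrow(ed) + seq_len(nrow(snp))
    i_noise <- nrow(ed) + nrow(snp) + seq_len(nrow(noise))
    for (j in seq_len(2L * r)) {
        rate <- if (treated[j]) config$editing_rate_treated else
            config$editing_rate_control
        altm[i_ed, j] <- .rbetabinom(nrow(ed), dp[i_ed, j], rate,
                                     config$editing_overdispersion)
        altm[i_snp, j] <- rbinom(nrow(snp), dp[i_snp, j], snp$aaf_class)
        altm[i_noise, j] <- rbinom(nrow(noise), dp[i_noise, j],
                                   config$noise_rate)
    }
    refm <- dp - altm

    sites <- rbind(
        ed[, c("chrom", "pos", "ref", "alt")],
        snp[, c("chrom", "pos", "ref", "alt")],
        noise[, c("chrom", "pos", "ref", "alt")]
    )
    rs <- c(rep(NA_character_, nrow(ed)), snp$rs_id,
            rep(NA_character_, nrow(noise)))
    qd <- round(runif(n_sites, 5, 30), 2)
    mq <- round(runif(n_sites, 50, 60), 2)
    mqrs <- round(rnorm(n_sites), 2)
    rprs <- round(rnorm(n_sites), 2)
    fail <- i_noise[runif(length(i_noise)) < config$hard_filter_fail_fraction]
    if (length(fail)) {
        which_filter <- sample(1:4, length(fail), replace = TRUE)
        qd[fail[which_filter == 1]] <- round(runif(sum(which_filter == 1),
                                                   0.1, 1.9), 2)
        mq[fail[which_filter == 2]] <- round(runif(sum(which_filter == 2),
                                                   20, 39), 2)
        mqrs[fail[which_filter == 3]] <- round(runif(sum(which_filter == 3),
                                                     -20, -13), 2)
        rprs[fail[which_filter == 4]] <- round(runif(sum(which_filter == 4),
                                                     -15, -8.5), 2)
    }
    vs <- VariantSet(sites$chrom, sites$pos, sites$ref, sites$alt,
                     refm, altm, dp, samples = samples,
                     QD = qd, MQ = mq, MQRankSum = mqrs,
                     ReadPosRankSum = rprs, rs_id = rs)
    key <- names(rowRanges(vs))
    editing_truth <- data.frame(
        site_id = key[i_ed], chrom = ed$chrom, pos = ed$pos,
        ref = ed$ref, alt = ed$alt, host_strand = ed$strand,
        host_gene = ed$gene_id,
        rate_control = config$editing_rate_control,
        rate_treated = config$editing_rate_treated,
        canonical_class = "A_to_I",
        stringsAsFactors = FALSE)
    snp_sites <- data.frame(site_id = key[i_snp], rs_id = snp$rs_id,
                            aaf_class = snp$aaf_class,
                            stringsAsFactors = FALSE)
    noise_sites <- data.frame(site_id = key[i_noise],
                              stringsAsFactors = FALSE)
    ord <- order(as.character(seqnames(rowRanges(vs))),
                 start(rowRanges(vs)))
    vs <- vs[ord, ]
    list(variants = vs, editing_truth = editing_truth,
         snp_sites = snp_sites, noise_sites = noise_sites)
}

#' Generate a complete synthetic study
#'
#' Runs the genome/annotation, count and variant generators under the
#' configured seed and optionally writes the full fixture set
#' (`genome.fa`, `annotation.gff3`, `masks/*.bed`, `counts.tsv`,
#' `design.tsv`, `variants.vcf`, `truth.json`) to a directory. Identical
#' configurations produce byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param out_dir optional output directory.
#' @return list with `genome`, `annotation`, `masks`, `counts`
#'   (`SummarizedExperiment`), `design`, `variants` ([VariantSet-class]),
#'   `truth` (list: `de`, `lncrna`, `editing`, `snp_sites`,
#'   `noise_sites`) and `config`.
#' @export
simulateStudy <- function(config = simulationConfig(), out_dir = NULL) {
    ga <- simulateGenomeAnnotation(config)
    cn <- simulateCounts(config, ga$annotation)
    vr <- simulateVariants(config, ga$annotation, ga$genome, ga$masks)
    truth <- list(de = cn$de_truth, lncrna = ga$lncrna_truth,
                  editing = vr$editing_truth, snp_sites = vr$snp_sites,
                  noise_sites = vr$noise_sites)
    out <- list(genome = ga$genome, annotation = ga$annotation,
                masks = ga$masks, counts = cn$counts, design = cn$design,
                variants = vr$variants, truth = truth, config = config)
    if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        writeGenome(ga$genome, file.path(out_dir, "genome.fa"))
        writeAnnotation(ga$annotation, file.path(out_dir, "annotation.gff3"))
        writeMasks(ga$masks, file.path(out_dir, "masks"))
        writeCountsMatrix(assay(cn$counts, "counts"),
                          file.path(out_dir, "counts.tsv"))
        writeDesign(cn$design, file.path(out_dir, "design.tsv"))
        writeVariants(vr$variants, file.path(out_dir, "variants.vcf"))
        write_json(truth, file.path(out_dir, "truth.json"),
                   dataframe = "columns", auto_unbox = TRUE, digits = NA)
    }
    out
}

#' Training corpora for the hexamer model
#'
#' Coding corpus: spliced CDS of all `protein_coding` transcripts.
#' Non-coding corpus: intergenic windows sampled away from genes,
#' representing the background sequence composition.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param n_noncoding number of background windows.
#' @param window_size background window length (nt).
#' @return list with `coding` and `noncoding` character vectors.
#' @export
hexamerTrainingCorpora <- function(annotation, genome, n_noncoding = 50L,
                                   window_size = 600L) {
    tx <- txTable(annotation)
    coding_ids <- tx$transcript_id[tx$biotype == "protein_coding"]
    coding <- vapply(coding_ids, function(t)
        splicedCds(annotation, genome, t), character(1))
    gsp <- geneSpans(annotation)
    noncoding <- character(0)
    for (cn in names(genome)) {
        L <- length(genome[[cn]])
        cov <- reduce(granges(gsp[seqnames(gsp) == cn]),
                      ignore.strand = TRUE)
        gap_start <- c(1L, end(cov) + 1L)
        gap_end <- c(start(cov) - 1L, L)
        for (k in seq_along(gap_start)) {
            a <- gap_start[k] + 5L
            b <- min(gap_end[k] - 5L, a + window_size - 1L)
            if (b - a + 1L >= 60L) {
                noncoding <- c(noncoding, genomeSlice(genome, cn, a, b))
            }
        }
    }
    if (length(noncoding) == 0L) stop("no intergenic windows found")
    if (length(noncoding) > n_noncoding) {
        noncoding <- noncoding[sample.int(length(noncoding), n_noncoding)]
    }
    list(coding = unname(coding), noncoding = noncoding)
}
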