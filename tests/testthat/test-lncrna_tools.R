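test_that("spliced sequences concatenate exons and honour strand", {
    genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCGGGTTT"))
    ann <- toyAnnotation(list(
        list(id = "tp", gene = "g1", chrom = "chr1", strand = "+",
             biotype = "other", exons = rbind(c(1, 3), c(7, 9)), cds = NULL),
        list(id = "tm", gene = "g2", chrom = "chr1", strand = "-",
             biotype = "other", exons = rbind(c(1, 4)), cds = NULL)
    ))
    expect_equal(splicedSequence(ann, genome, "tp"), "ATGGGG")
    expect_equal(splicedSequence(ann, genome, "tm"), "GCAT")
    expect_error(splicedSequence(ann, genome, "nope"), "unknown transcript")
})

test_that("longest ORF scan handles the worked example and edge cases", {
    orf <- longestOrf("ATGAAATAG")
    expect_equal(orf$length_codons, 2L)
    expect_equal(orf$start, 1L)
    expect_equal(orf$frame, 0L)
    expect_equal(orf$coverage, 1.0)

    expect_equal(longestOrf("CCCCCCCCC")$length_codons, 0L)
    expect_equal(longestOrf("ATGAAAAAA")$length_codons, 0L)  # no stop
    expect_equal(longestOrf("")$length_codons, 0L)
})

test_that("longest ORF equals the brute-force substring scan", {
    set.seed(41)
    for (i in 1:300) {
        s <- paste(sample(c("A", "C", "G", "T"), sample(20:120, 1),
                          replace = TRUE), collapse = "")
        expect_equal(longestOrf(s)$length_codons, bruteOrf(s), label = s)
    }
})

test_that("Fickett TESTCODE scores uniform sequence as noncoding", {
    uniform <- paste(rep("ACGT", 75), collapse = "")
    fk <- fickettScore(uniform)
    expect_lt(fk$score, 0.95)
    expect_equal(fk$vote, "noncoding")
    expect_error(fickettScore("ACGT"), "200 nt")
})

test_that("Fickett TESTCODE matches an independent table lookup", {
    ## second, independent coding of the published tables using ascending
    ## thresholds and findInterval
    thr_pos <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)
    thr_con <- c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33)
    pp <- list(A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
               C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
               G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
               T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
    cp <- list(A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
               C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.51, 0.34),
               G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
               T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
    pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
    cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
    oracle <- function(s) {
        v <- strsplit(s, "")[[1]]
        total <- 0
        for (b in c("A", "C", "G", "T")) {
            cnt <- sapply(1:3, function(f)
                sum(v[seq(f, length(v), 3)] == b))
            posp <- max(cnt) / (min(cnt) + 1)
            conp <- sum(cnt) / length(v)
            ip <- 10 - findInterval(posp, thr_pos)   # descending tables
            ic <- 10 - findInterval(conp, thr_con)
            total <- total + pp[[b]][ip] * pw[b] + cp[[b]][ic] * cw[b]
        }
        unname(total)
    }
    set.seed(42)
    for (i in 1:40) {
        s <- paste(sample(c("A", "C", "G", "T"), 200 + 3 * i,
                          replace = TRUE,
                          prob = runif(4, 0.5, 2)), collapse = "")
        expect_equal(fickettScore(s)$score, oracle(s), tolerance = 1e-12)
    }
})

test_that("hexamer model scores zero against itself and flags coding", {
    set.seed(43)
    corpus <- replicate(10, paste(sample(c("A", "C", "G", "T"), 300,
                                         replace = TRUE), collapse = ""))
    m <- trainHexamerModel(corpus, corpus)
    expect_equal(hexamerScore(m, corpus[1])$score, 0)
    expect_error(hexamerScore(m, "ACG"), "shorter than 6")
    expect_error(trainHexamerModel(character(0), corpus), "non-empty")

    ## held-out coding sequence scores positive across seeds
    train <- simulateGenomeAnnotation(simulationConfig(
        seed = 101, n_coding_genes = 15L, n_lncrnas = 15L,
        n_bidirectional_pairs = 0L, chrom_min_length = 20000L))
    set.seed(44)
    corp <- hexamerTrainingCorpora(train$annotation, train$genome)
    model <- trainHexamerModel(corp$coding, corp$noncoding)
    hits <- vapply(1:20, function(s) {
        test <- simulateGenomeAnnotation(simulationConfig(
            seed = 200 + s, n_coding_genes = 2L, n_lncrnas = 1L,
            n_bidirectional_pairs = 0L, chrom_min_length = 6000L))
        tx <- txTable(test$annotation)
        cid <- tx$transcript_id[tx$biotype == "protein_coding"][1]
        hexamerScore(model,
                     splicedCds(test$annotation, test$genome, cid))$score > 0
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("lncRNA calls follow the length, exon and unanimity rules", {
    rep_base <- list(spliced_length = 500L, exon_count = 3L,
                     orf_length = 20L, orf_coverage = 0.1,
                     votes = c(orf = "noncoding", fickett = "noncoding",
                               hexamer = "noncoding"),
                     final_label = "noncoding")
    expect_true(classifyLncRNA(rep_base, "novel"))

    short <- rep_base; short$spliced_length <- 150L
    expect_false(classifyLncRNA(short, "novel"))

    mono <- rep_base; mono$exon_count <- 1L
    expect_false(classifyLncRNA(mono, "novel"))

    one_coding <- rep_base
    one_coding$votes["fickett"] <- "coding"
    one_coding$final_label <- "coding"
    expect_false(classifyLncRNA(one_coding, "novel"))

    ## annotated biotype short-circuits
    expect_true(classifyLncRNA(short, "lncRNA"))
})

test_that("final label is monotone in the individual votes", {
    sim <- defaultSim()
    set.seed(45)
    corp <- hexamerTrainingCorpora(sim$annotation, sim$genome)
    model <- trainHexamerModel(corp$coding, corp$noncoding)
    tx <- txTable(sim$annotation)
    for (t in sample(tx$transcript_id, 10)) {
        rep <- codingPotentialReport(sim$annotation, sim$genome, t, model)
        expect_equal(rep$final_label,
                     if (all(rep$votes == "noncoding")) "noncoding"
                     else "coding")
    }
})

test_that("classifier recovers planted biotypes on one synthetic study", {
    sim <- defaultSim()
    set.seed(46)
    corp <- hexamerTrainingCorpora(sim$annotation, sim$genome)
    model <- trainHexamerModel(corp$coding, corp$noncoding)
    tx <- txTable(sim$annotation)
    truth <- sim$truth$lncrna$is_lncRNA[
        match(tx$transcript_id, sim$truth$lncrna$transcript_id)]
    calls <- vapply(tx$transcript_id, function(t) {
        classifyLncRNA(codingPotentialReport(sim$annotation, sim$genome,
                                             t, model), "novel")
    }, logical(1))
    expect_gte(mean(calls[truth]), 0.9)        # sensitivity
    expect_gte(mean(!calls[!truth]), 0.9)      # specificity
})

test_that("trans-correlation finds exact linear pairs and nothing else", {
    samples <- paste0("s", 1:6)
    ## counts chosen so that the mRNA profile is an exact linear rescaling
    ## of the lncRNA profile on the log2(count + 1) scale
    k <- 1:6
    lnc <- matrix(2^k - 1, 1, dimnames = list("L1", samples))
    mrna <- rbind(M1 = 2^(2 * k) - 1,
                  M2 = c(5, 5, 5, 9, 2, 7))
    pairs <- transCorrelate(lnc, mrna, threshold = 0.9)
    expect_true(any(pairs$lncrna_id == "L1" & pairs$target_gene_id == "M1"))
    got <- pairs[pairs$target_gene_id == "M1", ]
    expect_equal(got$r, 1, tolerance = 1e-9)
    expect_equal(got$sign, "positive")

    expect_warning(
        transCorrelate(rbind(L1 = rep(3, 6)), mrna, threshold = 0.9),
        "zero-variance")
})

test_that("trans-correlation equals the brute-force all-pairs oracle", {
    set.seed(47)
    lnc <- matrix(rpois(10 * 8, 40), 10, 8,
                  dimnames = list(paste0("L", 1:10), paste0("s", 1:8)))
    mrna <- matrix(rpois(10 * 8, 40), 10, 8,
                   dimnames = list(paste0("M", 1:10), paste0("s", 1:8)))
    thr <- 0.5
    got <- transCorrelate(lnc, mrna, threshold = thr)
    want <- brutePearsonPairs(lnc, mrna, thr)
    key <- function(d) paste(d$lncrna_id, d$target_gene_id)
    expect_setequal(key(got), key(want))
    want <- want[match(key(got), key(want)), ]
    expect_equal(got$r, want$r, tolerance = 1e-10)

    ## symmetry: swapping the roles transposes the pair set
    rev <- transCorrelate(mrna, lnc, threshold = thr)
    expect_setequal(paste(rev$target_gene_id, rev$lncrna_id), key(got))
})
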