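grp6 <- factor(rep(c("control", "EMF"), each = 3),
               levels = c("control", "EMF"))

test_that("hard filter applies strict thresholds and absent-as-pass", {
    cfg <- filterConfig()
    ## mean depth 9 -> removed
    vs <- toyVariants(pos = 1:3,
                      refD = matrix(5L, 3, 6), altD = matrix(2L, 3, 6),
                      DP = matrix(c(9L, 10L, 10L), 3, 6),
                      MQ = c(50, 40, 50), QD = c(20, 2, 20),
                      MQRankSum = c(0, 0, NA),
                      ReadPosRankSum = c(0, 0, NA))
    out <- hardFilter(vs, cfg)
    expect_equal(start(rowRanges(out$variants)), c(2L, 3L))  # boundary kept
    expect_equal(out$audit$n_removed, 1L)

    ## each quality annotation below threshold removes
    vs2 <- toyVariants(pos = 1:4,
                       refD = matrix(20L, 4, 6), altD = matrix(5L, 4, 6),
                       MQ = c(39.9, 50, 50, 50), QD = c(20, 1.9, 20, 20),
                       MQRankSum = c(0, 0, -12.6, 0),
                       ReadPosRankSum = c(0, 0, 0, -8.1))
    expect_equal(nrow(hardFilter(vs2, cfg)$variants), 0L)
})

test_that("context filter removes junction-proximal and masked sites", {
    ann <- toyAnnotation(list(list(
        id = "t1", gene = "g1", chrom = "chr1", strand = "+",
        biotype = "other", exons = rbind(c(101, 200), c(301, 400)),
        cds = NULL)))
    cfg <- filterConfig(splice_window = 4)
    masks <- GenomicRanges::GRangesList(
        ssr = GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 520)))
    vs <- toyVariants(pos = c(202L, 150L, 510L, 205L, 297L),
                      refD = matrix(20L, 5, 6), altD = matrix(5L, 5, 6))
    out <- contextFilter(vs, ann, masks, cfg)
    kept <- start(rowRanges(out$variants))
    expect_setequal(kept, c(150L, 205L))   # 202 near junction, 510 masked,
                                           # 297 within 4 of 301
    expect_equal(out$audit$n_removed, 3L)
})

test_that("junction filtering matches a brute-force distance scan", {
    sim <- defaultSim()
    jn <- spliceJunctions(sim$annotation)
    cfg <- filterConfig(splice_window = 4)
    set.seed(61)
    n <- 400
    chrom <- sample(names(sim$genome), n, replace = TRUE)
    pos <- vapply(chrom, function(cn)
        sample.int(length(sim$genome[[cn]]), 1L), integer(1))
    vs <- VariantSet(chrom, pos, rep("A", n), rep("G", n),
                     matrix(20L, n, 6), matrix(5L, n, 6),
                     matrix(25L, n, 6), samples = paste0("s", 1:6))
    out <- contextFilter(vs, sim$annotation, GenomicRanges::GRangesList(),
                         cfg)
    removed_got <- !(names(rowRanges(vs)) %in%
                         names(rowRanges(out$variants)))
    removed_want <- bruteJunctionRemoved(
        chrom, pos, as.character(GenomicRanges::seqnames(jn)),
        GenomicRanges::start(jn), 4)
    expect_equal(removed_got, unname(removed_want))
})

test_that("prevalence filter uses the ceil(at-least-half) rule", {
    cfg <- filterConfig()
    alt <- rbind(c(3L, 2L, 1L, 0L, 0L, 0L),   # 3 of 6 -> kept
                 c(3L, 2L, 0L, 0L, 0L, 0L))   # 2 of 6 -> removed
    vs <- toyVariants(pos = 1:2, refD = matrix(20L, 2, 6), altD = alt)
    out <- prevalenceFilter(vs, cfg)
    expect_equal(start(rowRanges(out$variants)), 1L)

    ## 5 samples: ceil(0.5 * 5) = 3
    alt5 <- rbind(c(1L, 1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L))
    vs5 <- toyVariants(pos = 1:2, refD = matrix(20L, 2, 5), altD = alt5)
    expect_equal(nrow(prevalenceFilter(vs5, cfg)$variants), 1L)
})

test_that("SNP and hypervariable-AAF filter removes rs and AAF > 0.7", {
    cfg <- filterConfig()
    vs <- toyVariants(pos = 1:3,
                      refD = rbind(rep(8L, 6),
                                   c(29L, rep(10L, 5)),
                                   c(30L, rep(10L, 5))),
                      altD = rbind(rep(2L, 6),
                                   c(71L, rep(5L, 5)),
                                   c(70L, rep(5L, 5))),
                      rs_id = c("rs1", NA, NA))
    out <- snpAafFilter(vs, cfg)
    ## site 1 rs-annotated (AAF 0.2): removed; site 2 max AAF 0.71: removed;
    ## site 3 max AAF exactly 0.70: kept
    expect_equal(start(rowRanges(out$variants)), 3L)
})

test_that("AAF computation excludes uncovered samples from group means", {
    vs <- toyVariants(pos = 1L,
                      refD = rbind(c(15L, 8L, 7L, 6L, 0L, 12L)),
                      altD = rbind(c(5L, 2L, 3L, 4L, 0L, 8L)))
    aaf <- aafMatrix(vs)
    expect_equal(unname(aaf[1, 1]), 0.25)
    expect_true(is.na(aaf[1, 5]))
    gm <- groupMeanAAF(aaf, grp6)
    expect_equal(unname(gm[1, "control"]), mean(c(0.25, 0.2, 0.3)))
    expect_equal(unname(gm[1, "EMF"]), mean(c(0.4, 0.4)))
})

test_that("chi-square imbalance reproduces the worked pooled table", {
    got <- allelicImbalanceChisq(30, 70, 10, 90)
    expect_equal(got$stat, 12.5)
    expect_equal(got$p, pchisq(12.5, 1, lower.tail = FALSE))

    same <- allelicImbalanceChisq(25, 75, 25, 75)
    expect_equal(same$stat, 0)
    expect_equal(same$p, 1)
})

test_that("chi-square agrees with the standard contingency test", {
    set.seed(62)
    for (i in 1:300) {
        tab <- matrix(rpois(4, 40) + 1L, 2, 2)
        got <- allelicImbalanceChisq(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2])
        want <- suppressWarnings(chisq.test(tab, correct = FALSE))
        expect_equal(got$stat, unname(want$statistic), tolerance = 1e-10)
        expect_equal(got$p, want$p.value, tolerance = 1e-10)
    }
})

test_that("differential editing reports dAAF, FDR and degenerate flags", {
    ## equal per-sample depths make the mean AAF equal the pooled AAF:
    ## treated 30/100 vs control 10/100 split over 50-read samples... use
    ## 2 samples per group at depth 50
    vs <- toyVariants(pos = 1:2,
                      refD = rbind(c(45L, 45L, 45L, 35L, 35L, 35L),
                                   c(40L, 40L, 40L, 40L, 40L, 40L)),
                      altD = rbind(c(5L, 5L, 5L, 15L, 15L, 15L),
                                   c(10L, 10L, 10L, 10L, 10L, 10L)))
    res <- differentialEditing(vs, grp6, filterConfig())
    expect_equal(res$daaf[1], 0.2)
    expect_equal(res$chi2_stat[1],
                 allelicImbalanceChisq(45, 105, 15, 135)$stat)
    expect_equal(res$daaf[2], 0)
    expect_equal(res$chi2_stat[2], 0)
    expect_false(res$significant[2])
    expect_true(all(res$fdr >= res$p))

    ## zero depth in one group
    vz <- toyVariants(pos = 1L,
                      refD = rbind(c(0L, 0L, 0L, 30L, 30L, 30L)),
                      altD = rbind(c(0L, 0L, 0L, 10L, 10L, 10L)))
    rz <- differentialEditing(vz, grp6, filterConfig())
    expect_true(rz$zero_depth_group)
    expect_equal(rz$p, 1)
})

test_that("canonical classification is strand covariant", {
    expect_equal(classifySubstitution("A", "G", "+"), "A_to_I")
    expect_equal(classifySubstitution("T", "C", "-"), "A_to_I")
    expect_equal(classifySubstitution("C", "T", "+"), "C_to_U")
    expect_equal(classifySubstitution("G", "A", "-"), "C_to_U")
    expect_equal(classifySubstitution("G", "A", "+"), "noncanonical")
    expect_equal(classifySubstitution("A", "C", "+"), "noncanonical")

    comp <- c(A = "T", C = "G", G = "C", T = "A")
    bases <- c("A", "C", "G", "T")
    for (r in bases) for (a in setdiff(bases, r)) {
        plus <- classifySubstitution(r, a, "+")
        mirror <- classifySubstitution(comp[[r]], comp[[a]], "-")
        expect_equal(plus, mirror)
    }
})

test_that("consequences follow the genetic code and severity ranking", {
    fx <- consequenceFixture()
    cfg <- filterConfig()
    cases <- data.frame(
        chrom = "chrT",
        pos = c(8013L,   # codon 1 third base, AAA->AAG
                8012L,   # codon 1 second base, AAA->AGA
                5001L,   # 3000 nt 5' of gP start
                8005L,   # exonic, before CDS, + strand
                8050L,   # exonic, after CDS
                8080L,   # between the exons
                8300L,   # 140 nt 3' of gP end
                200L,    # far from everything
                9538L,   # - strand CDS codon 1 third base (T->C => AAG)
                9537L),  # - strand CDS codon 2 first base... A of next codon
        ref = c("A", "A", "A", "C", "C", "G", "T", "C", "T", "T"),
        alt = c("G", "G", "G", "T", "A", "A", "A", "A", "C", "A"),
        stringsAsFactors = FALSE)
    got <- annotateConsequence(cases, fx$annotation, fx$genome, cfg)
    expect_equal(got$consequence[1], "synonymous")
    expect_equal(got$consequence[2], "missense")
    expect_equal(got$consequence[3], "upstream")
    expect_equal(got$consequence[4], "five_prime_utr")
    expect_equal(got$consequence[5], "three_prime_utr")
    expect_equal(got$consequence[6], "intron")
    expect_equal(got$consequence[7], "downstream")
    expect_equal(got$consequence[8], "intergenic")
    expect_equal(got$consequence[9], "synonymous")
    expect_equal(got$consequence[10], "missense")
    expect_equal(got$host_gene[1], "gP")
    expect_true(is.na(got$host_gene[8]))
})

test_that("cascade stages chain, compose and are idempotent", {
    sim <- defaultSim()
    groups <- factor(sim$design$group, levels = c("control", "EMF"))
    cfg <- filterConfig()
    res <- runEditingCascade(sim$variants, sim$annotation, sim$genome,
                             sim$masks, groups, cfg)
    aud <- res$audit
    expect_equal(aud$n_out, aud$n_in - aud$n_removed)
    expect_equal(aud$n_in[-1], aud$n_out[-nrow(aud)])

    ## composition of stage functions gives the same survivor set
    s1 <- hardFilter(sim$variants, cfg)
    s2 <- contextFilter(s1$variants, sim$annotation, sim$masks, cfg)
    s3 <- prevalenceFilter(s2$variants, cfg)
    s4 <- snpAafFilter(s3$variants, cfg)
    tested <- differentialEditing(s4$variants, groups, cfg)
    expect_equal(res$tested, tested)

    ## idempotency of every pure filter
    for (f in list(function(v) hardFilter(v, cfg),
                   function(v) contextFilter(v, sim$annotation,
                                             sim$masks, cfg),
                   function(v) prevalenceFilter(v, cfg),
                   function(v) snpAafFilter(v, cfg))) {
        once <- f(sim$variants)$variants
        twice <- f(once)
        expect_equal(twice$audit$n_removed, 0L)
    }

    ## empty input
    empty <- sim$variants[integer(0), ]
    res0 <- runEditingCascade(empty, sim$annotation, sim$genome,
                              sim$masks, groups, cfg)
    expect_equal(nrow(res0$candidates), 0L)
    expect_true(all(res0$audit$n_in == 0L))
})

test_that("filter configuration rejects out-of-range values", {
    expect_error(filterConfig(min_alt_sample_fraction = 0), "\\(0, 1\\]")
    expect_error(filterConfig(max_sample_aaf = 1.5), "\\(0, 1\\]")
    expect_error(filterConfig(splice_window = -1), ">= 0")
    expect_error(filterConfig(min_dp = Inf), "finite")
})
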