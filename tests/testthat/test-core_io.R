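test_that("FASTA reading normalizes case and validates records", {
    p <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chr1", "ACGT"), p)
    g <- readGenome(p)
    expect_equal(as.character(g), c(chr1 = "ACGT"))

    writeLines(c(">chr1", "acgt"), p)
    expect_equal(as.character(readGenome(p)[["chr1"]]), "ACGT")

    writeLines(c(">chr1", "ACGT", ">chr2", ""), p)
    expect_error(readGenome(p), "empty")

    writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), p)
    expect_error(readGenome(p), "duplicate")
})

test_that("genome round-trips through FASTA and slices exactly", {
    sim <- defaultSim()
    p <- withr::local_tempfile(fileext = ".fa")
    writeGenome(sim$genome, p)
    back <- readGenome(p)
    expect_equal(as.character(back), as.character(sim$genome))

    s <- genomeSlice(sim$genome, "chr1", 101, 200)
    expect_equal(nchar(s), 100L)
    expect_error(genomeSlice(sim$genome, "chrX", 1, 10), "unknown")
    expect_error(genomeSlice(sim$genome, "chr1", 0, 10), "out of range")
})

test_that("GFF3 import keeps 1-based closed coordinates and CDS structure", {
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=g1",
        "chr1\tx\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1;biotype=protein_coding",
        "chr1\tx\texon\t101\t200\t.\t+\t.\tID=t1.e1;Parent=t1",
        "chr1\tx\texon\t301\t400\t.\t+\t.\tID=t1.e2;Parent=t1",
        "chr1\tx\tCDS\t151\t200\t.\t+\t.\tID=t1.c1;Parent=t1",
        "chr1\tx\tCDS\t301\t352\t.\t+\t.\tID=t1.c2;Parent=t1"
    ), p)
    ann <- readAnnotation(p)
    ex <- exonsOf(ann, "t1")
    expect_equal(start(ex), c(101L, 301L))
    expect_equal(end(ex), c(200L, 400L))
    expect_equal(width(ex), c(100L, 100L))
    expect_equal(length(cdsOf(ann, "t1")), 2L)
    expect_equal(sum(width(cdsOf(ann, "t1"))), 102L)
})

test_that("GFF3 ingest rejects broken feature graphs and bad CDS", {
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=gX",
        "chr1\tx\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1"
    ), p)
    expect_error(readAnnotation(p), "orphan")

    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
        "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1;biotype=protein_coding",
        "chr1\tx\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
        "chr1\tx\tCDS\t101\t104\t.\t+\t.\tID=c1;Parent=t1"
    ), p)
    expect_error(readAnnotation(p), "divisible by 3")
})

test_that("annotation round-trips through GFF3", {
    sim <- defaultSim()
    p <- withr::local_tempfile(fileext = ".gff3")
    writeAnnotation(sim$annotation, p)
    back <- readAnnotation(p)
    expect_equal(txTable(back), txTable(sim$annotation))
    for (t in head(txTable(back)$transcript_id, 10)) {
        expect_equal(as.data.frame(exonsOf(back, t)),
                     as.data.frame(exonsOf(sim$annotation, t)))
        expect_equal(as.data.frame(cdsOf(back, t)),
                     as.data.frame(cdsOf(sim$annotation, t)))
    }
})

test_that("VCF ingest parses AD, splits multi-allelics and skips indels", {
    p <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
        "chr1\t100\t.\tA\tG\t.\t.\tQD=12.5\tDP:AD\t10:7,3",
        "chr1\t200\trs42\tC\tG,T\t.\t.\tQD=20\tDP:AD\t30:10,12,8",
        "chr1\t300\t.\tA\tAT\t.\t.\tQD=20\tDP:AD\t10:5,5"
    ), p)
    vs <- readVariants(p)
    expect_equal(nrow(vs), 3L)           # 1 SNV + 2 from the split
    expect_equal(metadata(vs)$n_skipped_non_snv, 1L)
    expect_equal(unname(refDepth(vs)[1, 1]), 7L)
    expect_equal(unname(altDepth(vs)[1, 1]), 3L)
    split_alts <- rowData(vs)$alt[start(rowRanges(vs)) == 200]
    expect_setequal(split_alts, c("G", "T"))
    expect_true(all(rowData(vs)$rs_id[start(rowRanges(vs)) == 200] == "rs42"))
    expect_equal(rowData(vs)$QD[1], 12.5)
})

test_that("variants round-trip through VCF", {
    sim <- defaultSim()
    p <- withr::local_tempfile(fileext = ".vcf")
    writeVariants(sim$variants, p)
    back <- readVariants(p)
    expect_equal(nrow(back), nrow(sim$variants))
    expect_equal(colnames(back), colnames(sim$variants))
    expect_equal(assay(back, "refDepth"), assay(sim$variants, "refDepth"))
    expect_equal(assay(back, "altDepth"), assay(sim$variants, "altDepth"))
    expect_equal(assay(back, "DP"), assay(sim$variants, "DP"))
    expect_equal(rowData(back)$rs_id, rowData(sim$variants)$rs_id)
    expect_equal(rowData(back)$QD, rowData(sim$variants)$QD)
    expect_equal(rowData(back)$MQRankSum, rowData(sim$variants)$MQRankSum)
    expect_equal(start(rowRanges(back)), start(rowRanges(sim$variants)))
})

test_that("VariantSet validity guards alleles and depths", {
    expect_error(toyVariants(pos = 1, ref = "A", alt = "A",
                             refD = 5, altD = 5), "differ")
    expect_error(toyVariants(pos = 1, refD = 5, altD = 5, DP = 8),
                 "exceed")
})

test_that("counts and design tables read, validate and assemble", {
    pc <- withr::local_tempfile(fileext = ".tsv")
    pd <- withr::local_tempfile(fileext = ".tsv")
    m <- matrix(1:12, 2, 6,
                dimnames = list(c("T1", "T2"), paste0("s", 1:6)))
    writeCountsMatrix(m, pc)
    back <- readCountsMatrix(pc)
    expect_equal(dim(back), c(2L, 6L))
    expect_equal(back, m)

    design <- data.frame(sample = paste0("s", 1:6),
                         group = rep(c("control", "EMF"), each = 3))
    writeDesign(design, pd)
    d <- readDesign(pd, treatment = "EMF")
    expect_equal(nrow(d), 6L)
    expect_equal(levels(d$group), c("control", "EMF"))

    se <- countsExperiment(back, d)
    expect_equal(dim(se), c(2L, 6L))

    writeLines(c("tar_id\ts1", "T1\t-1"), pc)
    expect_error(readCountsMatrix(pc), "non-negative")
    expect_error(countsExperiment(m[, 1:4],
                                  d), "absent from count matrix")
})

test_that("masks round-trip through BED with merged intervals", {
    sim <- defaultSim()
    d <- withr::local_tempdir()
    writeMasks(sim$masks, d)
    back <- readMasks(d)
    expect_setequal(names(back), names(sim$masks))
    for (lab in names(back)) {
        expect_equal(as.data.frame(granges(back[[lab]])),
                     as.data.frame(granges(sim$masks[[lab]])))
    }
})

test_that("library summary reproduces the sequencing-run arithmetic", {
    six <- c(49465271, 49465271, 49465272, 49465271, 49465271, 49465272)
    stopifnot(sum(six) == 296791628)
    s <- summarizeLibraries(six)
    expect_equal(s$total, 296791628)
    expect_equal(s$mean_mln, 49.47)
    expect_equal(summarizeLibraries(1e6)$mean_mln, 1.00)
    expect_error(summarizeLibraries(numeric(0)), "no libraries")
    expect_error(summarizeLibraries(c(10, -2)), "positive")
})

test_that("overlap queries agree with a brute-force interval scan", {
    sim <- defaultSim()
    spans <- transcriptSpans(sim$annotation)
    set.seed(91)
    chroms <- names(sim$genome)
    for (i in seq_len(250)) {
        cn <- sample(chroms, 1)
        a <- sample.int(length(sim$genome[[cn]]) - 500L, 1)
        b <- a + sample.int(500L, 1)
        got <- sort(overlappingTranscripts(sim$annotation, cn, a, b))
        want <- sort(names(spans)[
            as.character(seqnames(spans)) == cn &
                start(spans) <= b & end(spans) >= a])
        expect_identical(got, want)
    }
})
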