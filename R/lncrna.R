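#' @include core_io.R
NULL

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in genomic order and, for minus-strand
#' transcripts, reverse-complements the result, yielding the 5'->3' mature
#' sequence.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param transcript_id transcript to extract.
#' @return Character string (upper-case DNA).
#' @export
splicedSequence <- function(annotation, genome, transcript_id) {
    ex <- exonsOf(annotation, transcript_id)
    tx <- txTable(annotation)[transcript_id, ]
    parts <- vapply(seq_along(ex), function(i) {
        genomeSlice(genome, tx$chrom, start(ex)[i], end(ex)[i])
    }, character(1))
    s <- paste(parts, collapse = "")
    if (tx$strand == "-") {
        s <- as.character(reverseComplement(DNAString(s)))
    }
    s
}

#' Spliced CDS sequence of a coding transcript
#'
#' @inheritParams splicedSequence
#' @return Character string; empty for transcripts without CDS.
#' @export
splicedCds <- function(annotation, genome, transcript_id) {
    cd <- cdsOf(annotation, transcript_id)
    if (length(cd) == 0L) return("")
    tx <- txTable(annotation)[transcript_id, ]
    parts <- vapply(seq_along(cd), function(i) {
        genomeSlice(genome, tx$chrom, start(cd)[i], end(cd)[i])
    }, character(1))
    s <- paste(parts, collapse = "")
    if (tx$strand == "-") {
        s <- as.character(reverseComplement(DNAString(s)))
    }
    s
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the sense strand
#'
#' Scans the three sense-strand frames for the longest ATG..stop ORF. An
#' ORF must terminate at a stop codon; open-ended runs reaching the 3' end
#' are not counted. The reported length counts codons from the start codon
#' (inclusive) to the stop codon (exclusive); coverage is the fraction of
#' the sequence covered by the ORF *including* its stop codon.
#'
#' @param seq character DNA string.
#' @return list with `length_codons`, `start` (1-based position of the A of
#'   ATG; `NA` if no ORF), `frame` (0/1/2), `coverage`.
#' @export
longestOrf <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq)
    best <- list(length_codons = 0L, start = NA_integer_,
                 frame = NA_integer_, coverage = 0)
    for (f in 0:2) {
        if (n < f + 3L) next
        starts <- seq.int(1L + f, n - 2L, by = 3L)
        codons <- substring(seq, starts, starts + 2L)
        atg <- which(codons == "ATG")
        stop_i <- which(codons %in% STOP_CODONS)
        if (length(atg) == 0L || length(stop_i) == 0L) next
        ## first stop codon strictly after each ATG, same frame
        nxt_idx <- findInterval(atg, stop_i) + 1L
        nxt <- ifelse(nxt_idx <= length(stop_i), stop_i[nxt_idx], NA_integer_)
        ok <- !is.na(nxt)
        if (!any(ok)) next
        len <- nxt[ok] - atg[ok]
        len[len < 0L] <- 0L
        i <- which.max(len)
        if (len[i] > best$length_codons) {
            best$length_codons <- len[i]
            best$start <- starts[atg[ok][i]]
            best$frame <- f
            best$coverage <- 3 * (len[i] + 1L) / n
        }
    }
    best
}

## Fickett (1982) TESTCODE lookup tables: probability-of-coding values by
## descending parameter thresholds, and the weights of the eight parameters.
.fickett <- list(
    pos_thr = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
    con_thr = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0),
    pos_prob = list(
        A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
        C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
        G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
        T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
    con_prob = list(
        A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
        C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.51, 0.34),
        G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
        T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
    pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    con_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
)

.fickettLookup <- function(value, thresholds, probs) {
    probs[which(value >= thresholds)[1]]
}

#' Fickett TESTCODE coding-potential score
#'
#' Computes the classic TESTCODE statistic from the position bias (counts
#' of each base in the three codon positions, max/(min+1)) and composition
#' of the four bases, mapped through the published probability tables and
#' weights. Higher scores indicate coding potential.
#'
#' @param seq character DNA string, at least 200 nt.
#' @param cutoff vote threshold: `vote = "coding"` when `score >= cutoff`.
#' @return list with `score` and `vote` (`"coding"`/`"noncoding"`).
#' @export
fickettScore <- function(seq, cutoff = 0.95) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < 200L) stop("Fickett TESTCODE requires >= 200 nt (got ", n, ")")
    bases <- strsplit(seq, "")[[1]]
    phase <- (seq_len(n) - 1L) %% 3L
    score <- 0
    for (b in c("A", "C", "G", "T")) {
        cnt <- vapply(0:2, function(f) sum(bases == b & phase == f),
                      numeric(1))
        pos_par <- max(cnt) / (min(cnt) + 1)
        con_par <- sum(cnt) / n
        score <- score +
            .fickettLookup(pos_par, .fickett$pos_thr, .fickett$pos_prob[[b]]) *
                .fickett$pos_weight[[b]] +
            .fickettLookup(con_par, .fickett$con_thr, .fickett$con_prob[[b]]) *
                .fickett$con_weight[[b]]
    }
    list(score = score,
         vote = if (score >= cutoff) "coding" else "noncoding")
}

.inFrameHexamers <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < 6L) stop("sequence shorter than 6 nt")
    starts <- seq.int(1L, n - 5L, by = 3L)
    hx <- substring(seq, starts, starts + 5L)
    hx[!grepl("N", hx, fixed = TRUE)]
}

#' Train an in-frame hexamer usage model
#'
#' Tabulates in-frame (stride 3, frame 0) hexamer frequencies in a coding
#' corpus (e.g. spliced CDS sequences) and a non-coding corpus, with
#' add-one smoothing over all 4096 hexamers.
#'
#' @param coding_seqs,noncoding_seqs non-empty character vectors of DNA
#'   sequences.
#' @return A `hexamerModel` list carrying the per-hexamer log frequency
#'   ratio `log(f_coding / f_noncoding)`.
#' @export
trainHexamerModel <- function(coding_seqs, noncoding_seqs) {
    if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L) {
        stop("both training corpora must be non-empty")
    }
    all_hex <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                                           stringsAsFactors = FALSE))
    tab <- function(seqs) {
        hx <- unlist(lapply(seqs, .inFrameHexamers))
        cnt <- table(factor(hx, levels = all_hex))
        (as.numeric(cnt) + 1) / (sum(cnt) + length(all_hex))
    }
    lr <- log(tab(coding_seqs) / tab(noncoding_seqs))
    names(lr) <- all_hex
    structure(list(logratio = lr), class = "hexamerModel")
}

#' Hexamer log-likelihood-ratio score
#'
#' Mean per-hexamer log frequency ratio of the sequence's in-frame hexamers
#' under a trained [trainHexamerModel()] model; positive scores vote coding.
#'
#' @param model a `hexamerModel`.
#' @param seq character DNA string, at least 6 nt.
#' @return list with `score` and `vote`.
#' @export
hexamerScore <- function(model, seq) {
    stopifnot(inherits(model, "hexamerModel"))
    hx <- .inFrameHexamers(seq)
    score <- if (length(hx) == 0L) 0 else mean(model$logratio[hx])
    list(score = score, vote = if (score > 0) "coding" else "noncoding")
}

#' Coding-potential report for one transcript
#'
#' Combines the three predictors (longest-ORF metrics, Fickett TESTCODE,
#' hexamer log-likelihood ratio) into per-predictor votes and a final
#' label. The final label is `noncoding` iff all three votes are
#' noncoding. The ORF vote is `coding` iff the longest ORF reaches
#' `orf_min_codons` codons or covers at least `orf_min_coverage` of the
#' transcript. Transcripts shorter than 200 nt get no Fickett score
#' (`NA`) and a noncoding Fickett vote; such transcripts are excluded by
#' the length rule of [classifyLncRNA()] regardless.
#'
#' @inheritParams splicedSequence
#' @param hexamer_model a model from [trainHexamerModel()].
#' @param fickett_cutoff Fickett vote threshold.
#' @param orf_min_codons,orf_min_coverage ORF vote thresholds.
#' @return list mirroring the report fields: `transcript_id`,
#'   `spliced_length`, `exon_count`, `orf_length`, `orf_coverage`,
#'   `fickett_score`, `hexamer_llr`, `votes` (named character), and
#'   `final_label`.
#' @export
codingPotentialReport <- function(annotation, genome, transcript_id,
                                  hexamer_model,
                                  fickett_cutoff = 0.95,
                                  orf_min_codons = 100,
                                  orf_min_coverage = 0.5) {
    s <- splicedSequence(annotation, genome, transcript_id)
    orf <- longestOrf(s)
    orf_vote <- if (orf$length_codons >= orf_min_codons ||
                    orf$coverage >= orf_min_coverage) "coding" else "noncoding"
    if (nchar(s) >= 200L) {
        fk <- fickettScore(s, cutoff = fickett_cutoff)
    } else {
        fk <- list(score = NA_real_, vote = "noncoding")
    }
    hx <- hexamerScore(hexamer_model, s)
    votes <- c(orf = orf_vote, fickett = fk$vote, hexamer = hx$vote)
    list(
        transcript_id = transcript_id,
        spliced_length = nchar(s),
        exon_count = length(exonsOf(annotation, transcript_id)),
        orf_length = orf$length_codons,
        orf_coverage = orf$coverage,
        fickett_score = fk$score,
        hexamer_llr = hx$score,
        votes = votes,
        final_label = if (all(votes == "noncoding")) "noncoding" else "coding"
    )
}

#' lncRNA call for one transcript
#'
#' A transcript is a lncRNA if it carries a known `lncRNA` biotype, or,
#' for unannotated transcripts, if it is longer than `min_length` nt,
#' multi-exonic (`>= min_exons` exons) and voted noncoding by *all three*
#' coding-potential predictors.
#'
#' @param report a list from [codingPotentialReport()].
#' @param known_biotype the annotated biotype (`lncRNA` short-circuits to
#'   `TRUE`).
#' @param min_length minimum spliced length, strict `>` (nt).
#' @param min_exons minimum exon count.
#' @return Logical.
#' @export
classifyLncRNA <- function(report, known_biotype = "novel",
                           min_length = 200L, min_exons = 2L) {
    if (identical(known_biotype, "lncRNA")) return(TRUE)
    report$spliced_length > min_length &&
        report$exon_count >= min_exons &&
        report$final_label == "noncoding"
}

#' Trans-acting lncRNA--mRNA correlation pairs
#'
#' Computes all-pairs Pearson correlations between lncRNA and mRNA
#' expression profiles on the `log2(count + 1)` scale and reports the
#' pairs reaching `|r| >= threshold`. Zero-variance profiles are skipped
#' with a warning.
#'
#' @param lnc_expr,mrna_expr count matrices (features x samples) over the
#'   same samples (>= 3).
#' @param threshold absolute correlation threshold.
#' @return data.frame with columns `lncrna_id`, `target_gene_id`, `r`,
#'   `sign` (`positive`/`negative`).
#' @export
transCorrelate <- function(lnc_expr, mrna_expr, threshold = 0.9) {
    lnc_expr <- as.matrix(lnc_expr); mrna_expr <- as.matrix(mrna_expr)
    if (ncol(lnc_expr) != ncol(mrna_expr)) {
        stop("profiles must cover the same samples")
    }
    if (ncol(lnc_expr) < 3L) stop("need >= 3 samples for correlation")
    la <- log2(lnc_expr + 1); lb <- log2(mrna_expr + 1)
    keepA <- apply(la, 1, sd) > 0
    keepB <- apply(lb, 1, sd) > 0
    if (!all(keepA) || !all(keepB)) {
        warning(sum(!keepA) + sum(!keepB),
                " zero-variance profile(s) skipped")
    }
    la <- la[keepA, , drop = FALSE]; lb <- lb[keepB, , drop = FALSE]
    if (nrow(la) == 0L || nrow(lb) == 0L) {
        return(data.frame(lncrna_id = character(), target_gene_id = character(),
                          r = numeric(), sign = character(),
                          stringsAsFactors = FALSE))
    }
    rmat <- cor(t(la), t(lb))
    hits <- which(abs(rmat) >= threshold, arr.ind = TRUE)
    out <- data.frame(
        lncrna_id = rownames(la)[hits[, 1]],
        target_gene_id = rownames(lb)[hits[, 2]],
        r = rmat[hits],
        stringsAsFactors = FALSE
    )
    out$sign <- ifelse(out$r >= 0, "positive", "negative")
    out[order(out$lncrna_id, out$target_gene_id), , drop = FALSE]
}
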