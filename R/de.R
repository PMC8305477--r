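#' @include core_io.R
NULL

.resolveCounts <- function(x, groups = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        groups <- colData(x)$group
        x <- assay(x, "counts")
    }
    if (is.null(groups)) stop("'groups' is required when x is a matrix")
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stop("exactly two groups are required")
    if (any(table(groups) < 2L)) stop("each group needs >= 2 replicates")
    list(counts = as.matrix(x), groups = droplevels(groups))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across
#' all-positive TARs of the ratio of each sample's count to the
#' geometric-mean pseudo-reference of that TAR.
#'
#' @param counts integer matrix, TARs x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
    counts <- as.matrix(counts)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) stop("no TAR with all-positive counts")
    sub <- counts[pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub, 2, function(col) median(col / ref))
    if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
    sf
}

## pooled within-group moment estimate of the NB dispersion, per TAR, from
## size-factor-normalized counts
.momentDispersion <- function(q, gA, gB) {
    nA <- length(gA); nB <- length(gB)
    mA <- rowMeans(q[, gA, drop = FALSE])
    mB <- rowMeans(q[, gB, drop = FALSE])
    vA <- apply(q[, gA, drop = FALSE], 1, var)
    vB <- apply(q[, gB, drop = FALSE], 1, var)
    s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    m <- (mA + mB) / 2
    alpha <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
    list(mA = mA, mB = mB, alpha = alpha)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Counts are normalized by median-of-ratios size factors; the log2 fold
#' change is `log2((mB + 0.5) / (mA + 0.5))` of the group means of
#' normalized counts (B = second factor level, the treatment). The standard
#' error comes from the delta method applied to the NB variance
#' `m + alpha * m^2` of each group mean, with a pooled within-group moment
#' estimate of the dispersion `alpha`; the Wald statistic is referred to the
#' standard normal, two-sided.
#'
#' @param x count matrix (TARs x samples) or a `SummarizedExperiment` with
#'   assay `counts` and `colData$group`.
#' @param groups two-level factor over samples (control level first);
#'   ignored when `x` is a `SummarizedExperiment`.
#' @return data.frame with columns `tar_id`, `log2FC`, `p`. All-zero TARs
#'   get `log2FC = 0`, `p = 1`.
#' @export
nbWaldTest <- function(x, groups = NULL) {
    inp <- .resolveCounts(x, groups)
    counts <- inp$counts; groups <- inp$groups
    sf <- sizeFactorsMedianRatio(counts)
    q <- sweep(counts, 2, sf, "/")
    gA <- which(groups == levels(groups)[1])
    gB <- which(groups == levels(groups)[2])
    est <- .momentDispersion(q, gA, gB)
    lfc <- log2((est$mB + 0.5) / (est$mA + 0.5))
    vA <- (est$mA + est$alpha * est$mA^2) / length(gA)
    vB <- (est$mB + est$alpha * est$mB^2) / length(gB)
    se2 <- (vA / (est$mA + 0.5)^2 + vB / (est$mB + 0.5)^2) / log(2)^2
    z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    p <- 2 * pnorm(-abs(z))
    zero <- rowSums(counts) == 0
    lfc[zero] <- 0; p[zero] <- 1
    data.frame(tar_id = rownames(counts), log2FC = lfc, p = p,
               row.names = NULL, stringsAsFactors = FALSE)
}

## two-sided conditional exact p for one TAR: group totals modelled as sums
## of iid NB sharing the dispersion; conditioning on the grand total leaves a
## distribution free of the NB probability parameter
.exactConditionalP <- function(kA, N, nA, nB, alpha) {
    if (N == 0L) return(1)
    k <- 0:N
    if (alpha < 1e-8) {
        lw <- dbinom(k, N, nA / (nA + nB), log = TRUE)
    } else {
        sA <- nA / alpha; sB <- nB / alpha
        lw <- lchoose(k + sA - 1, k) + lchoose(N - k + sB - 1, N - k)
    }
    lw <- lw - max(lw)
    pr <- exp(lw); pr <- pr / sum(pr)
    sum(pr[pr <= pr[kA + 1L] * (1 + 1e-7)])
}

#' Negative-binomial conditional exact test (second DE method)
#'
#' Counts are brought to a common effective library size (divided by
#' median-of-ratios size factors and rounded). Per TAR, each group total is
#' modelled as the sum of iid negative binomials with a pooled moment
#' dispersion; conditioning on the grand total yields an exact conditional
#' distribution for the group-A total, and the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one (the
#' binomial/Poisson limit is used when the dispersion estimate vanishes).
#'
#' @inheritParams nbWaldTest
#' @return data.frame with columns `tar_id`, `log2FC`, `p`.
#' @export
nbExactTest <- function(x, groups = NULL) {
    inp <- .resolveCounts(x, groups)
    counts <- inp$counts; groups <- inp$groups
    sf <- sizeFactorsMedianRatio(counts)
    q <- sweep(counts, 2, sf, "/")
    qr <- round(q)
    gA <- which(groups == levels(groups)[1])
    gB <- which(groups == levels(groups)[2])
    est <- .momentDispersion(q, gA, gB)
    lfc <- log2((est$mB + 0.5) / (est$mA + 0.5))
    nA <- length(gA); nB <- length(gB)
    p <- vapply(seq_len(nrow(counts)), function(i) {
        kA <- sum(qr[i, gA]); N <- kA + sum(qr[i, gB])
        .exactConditionalP(kA, N, nA, nB, est$alpha[i])
    }, numeric(1))
    zero <- rowSums(counts) == 0
    lfc[zero] <- 0; p[zero] <- 1
    data.frame(tar_id = rownames(counts), log2FC = lfc, p = p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving
#' and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
        stop("p-values must be in [0, 1]")
    }
    n <- length(p)
    if (n <= 1L) return(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Consensus differential-expression calls from two NB tests
#'
#' Adjusts each method's p-values by Benjamini-Hochberg, then calls a TAR
#' differentially expressed iff *both* methods give an adjusted p-value
#' below `padj_thr` and an absolute log2 fold change above `lfc_thr`, with
#' agreeing fold-change signs (a sign conflict vetoes the call).
#'
#' @param resA,resB data.frames from [nbWaldTest()] / [nbExactTest()] over
#'   the same TAR universe.
#' @param padj_thr adjusted p-value threshold (strict `<`).
#' @param lfc_thr absolute log2 fold-change threshold (strict `>`).
#' @return data.frame with columns `tar_id`, `log2FC_a`, `p_a`, `padj_a`,
#'   `log2FC_b`, `p_b`, `padj_b`, `consensus`, `direction`
#'   (`up`/`down`/`none`).
#' @export
consensusDE <- function(resA, resB, padj_thr = 0.05, lfc_thr = 1) {
    if (!setequal(resA$tar_id, resB$tar_id)) {
        stop("the two result sets cover different TARs")
    }
    resB <- resB[match(resA$tar_id, resB$tar_id), ]
    padjA <- bhAdjust(resA$p)
    padjB <- bhAdjust(resB$p)
    hitA <- padjA < padj_thr & abs(resA$log2FC) > lfc_thr
    hitB <- padjB < padj_thr & abs(resB$log2FC) > lfc_thr
    same_sign <- sign(resA$log2FC) == sign(resB$log2FC)
    consensus <- hitA & hitB & same_sign
    direction <- ifelse(consensus,
                        ifelse(resA$log2FC > 0, "up", "down"), "none")
    data.frame(
        tar_id = resA$tar_id,
        log2FC_a = resA$log2FC, p_a = resA$p, padj_a = padjA,
        log2FC_b = resB$log2FC, p_b = resB$p, padj_b = padjB,
        consensus = consensus, direction = direction,
        row.names = NULL, stringsAsFactors = FALSE
    )
}

#' Summarize a consensus DE call set
#'
#' @param result data.frame with at least `tar_id`, `consensus`,
#'   `direction` (e.g. from [consensusDE()]).
#' @param annotation optional [GenomeAnnotation-class] used to split the DE
#'   set by biotype; TARs not present in the annotation count in neither
#'   biotype bucket.
#' @return list with `n_total`, `n_up`, `n_down`, `pct_down` (percentage,
#'   2 decimals; 0 with a warning when the set is empty),
#'   `n_protein_coding`, `n_lncRNA`.
#' @export
summarizeDE <- function(result, annotation = NULL) {
    de <- result[result$consensus, , drop = FALSE]
    n_up <- sum(de$direction == "up")
    n_down <- sum(de$direction == "down")
    n_total <- nrow(de)
    stopifnot(n_total == n_up + n_down)
    if (n_total == 0L) {
        warning("empty DE set; pct_down reported as 0")
        pct_down <- 0
    } else {
        pct_down <- round(100 * n_down / n_total, 2)
    }
    n_pc <- 0L; n_lnc <- 0L
    if (!is.null(annotation) && n_total > 0L) {
        tx <- txTable(annotation)
        bt <- tx$biotype[match(de$tar_id, tx$transcript_id)]
        n_pc <- sum(bt == "protein_coding", na.rm = TRUE)
        n_lnc <- sum(bt == "lncRNA", na.rm = TRUE)
    }
    list(n_total = n_total, n_up = n_up, n_down = n_down,
         pct_down = pct_down, n_protein_coding = n_pc, n_lncRNA = n_lnc)
}

#' Per-group sample size for an RNA-seq two-group comparison
#'
#' Closed-form sample size for detecting a fold change `effect` at mean
#' per-gene coverage `depth` and biological coefficient of variation `cv`:
#' `n = ceil( 2 (z_{1-alpha/2} + z_{power})^2 (1/depth + cv^2) / ln(effect)^2 )`,
#' floored at 1.
#'
#' @param depth mean per-gene read coverage (> 0).
#' @param cv biological coefficient of variation (>= 0).
#' @param effect target fold change (> 1).
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @return Integer sample size per group.
#' @export
nbSampleSize <- function(depth, cv, effect, alpha = 0.05, power = 0.8) {
    stopifnot(depth > 0, cv >= 0, alpha > 0, alpha < 1,
              power > 0, power < 1)
    if (effect <= 1) stop("'effect' (fold change) must exceed 1")
    z <- qnorm(1 - alpha / 2) + qnorm(power)
    n <- 2 * z^2 * (1 / depth + cv^2) / log(effect)^2
    max(1L, as.integer(ceiling(n)))
}
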