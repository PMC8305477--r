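#' @include simulate.R de.R lncrna.R editing.R
NULL

.runDefaults <- function() {
    list(
        seed = 22L,
        out_dir = "editscan_run",
        simulate = TRUE,
        sim = list(),                 # simulationConfig() overrides
        inputs = list(genome = NULL, annotation = NULL, masks = NULL,
                      counts = NULL, design = NULL, vcf = NULL),
        treatment_group = "EMF",
        de_padj_threshold = 0.05,
        de_lfc_threshold = 1,
        lncrna_min_length = 200,
        lncrna_min_exons = 2,
        fickett_cutoff = 0.95,
        orf_min_codons = 100,
        orf_min_coverage = 0.5,
        correlation_threshold = 0.9,
        filters = list()              # filterConfig() overrides
    )
}

.coerceLike <- function(value, default, key, warnings) {
    if (is.numeric(default) && is.character(value)) {
        num <- suppressWarnings(as.numeric(value))
        if (!is.na(num)) {
            warnings(paste0("coerced '", key, "' from string to number"))
            return(num)
        }
    }
    if (is.logical(default) && is.character(value)) {
        lg <- as.logical(value)
        if (!is.na(lg)) {
            warnings(paste0("coerced '", key, "' from string to logical"))
            return(lg)
        }
    }
    value
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys, coerces stringly-typed numbers with a warning, and reports every
#' violation at once. Numeric thresholds are additionally validated by
#' [filterConfig()] / [simulationConfig()].
#'
#' @param config path to a YAML file, a list, or `NULL` (all defaults).
#' @return A validated configuration list of class `runConfig`.
#' @export
validateRunConfig <- function(config = NULL) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- read_yaml(config)
        if (is.null(config)) config <- list()
    }
    if (is.null(config)) config <- list()
    defaults <- .runDefaults()
    errs <- character()
    warns <- character()
    addWarn <- function(msg) warns <<- c(warns, msg)

    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown)) {
        errs <- c(errs, paste("unknown config key(s):",
                              paste(unknown, collapse = ", ")))
    }
    out <- defaults
    for (k in intersect(names(config), names(defaults))) {
        v <- config[[k]]
        if (k %in% c("sim", "filters", "inputs")) {
            allowed <- if (k == "sim") names(formals(simulationConfig))
                else if (k == "filters") names(formals(filterConfig))
                else names(defaults$inputs)
            bad <- setdiff(names(v), allowed)
            if (length(bad)) {
                errs <- c(errs, paste0("unknown ", k, " key(s): ",
                                       paste(bad, collapse = ", ")))
                v <- v[setdiff(names(v), bad)]
            }
            for (kk in names(v)) {
                v[[kk]] <- .coerceLike(v[[kk]], 0, paste0(k, ".", kk),
                                       addWarn)
            }
            if (k == "inputs") {
                out$inputs[names(v)] <- v
            } else {
                out[[k]] <- v
            }
        } else {
            out[[k]] <- .coerceLike(v, defaults[[k]], k, addWarn)
        }
    }
    tryCatch(do.call(filterConfig, out$filters),
             error = function(e) errs <<- c(errs, conditionMessage(e)))
    tryCatch(do.call(simulationConfig, c(list(seed = as.integer(out$seed)),
                                         out$sim)),
             error = function(e) errs <<- c(errs, conditionMessage(e)))
    for (k in c("de_padj_threshold", "de_lfc_threshold",
                "correlation_threshold", "fickett_cutoff")) {
        if (!is.numeric(out[[k]]) || length(out[[k]]) != 1L ||
            !is.finite(out[[k]]) || out[[k]] < 0) {
            errs <- c(errs, paste0("'", k, "' must be a non-negative number"))
        }
    }
    if (length(errs)) {
        stop("invalid run configuration:\n  - ",
             paste(errs, collapse = "\n  - "))
    }
    for (w in warns) warning(w, call. = FALSE)
    structure(out, class = "runConfig")
}

.stageLog <- function(stage, ...) {
    message("[editscan:", stage, "] ", ...)
}

## hash of the analysis parameters (output location excluded)
.configHash <- function(config) {
    cfg <- unclass(config)
    cfg$out_dir <- NULL
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(as.character(toJSON(cfg, auto_unbox = TRUE,
                                   null = "null", digits = NA)), tmp)
    unname(tools::md5sum(tmp))
}

.loadInputs <- function(cfg) {
    inp <- cfg$inputs
    for (k in c("genome", "annotation", "counts", "design", "vcf")) {
        if (is.null(inp[[k]])) stop("input path '", k, "' is not set")
        for (p in inp[[k]]) {
            if (!file.exists(p)) stop("input file not found: ", p)
        }
    }
    genome <- readGenome(inp$genome)
    annotation <- readAnnotation(inp$annotation)
    masks <- if (!is.null(inp$masks)) readMasks(inp$masks) else GRangesList()
    counts <- readCountsMatrix(inp$counts)
    design <- readDesign(inp$design, treatment = cfg$treatment_group)
    variants <- readVariants(inp$vcf)
    list(genome = genome, annotation = annotation, masks = masks,
         counts = countsExperiment(counts, design), design = design,
         variants = variants, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> consensus differential expression ->
#' lncRNA classification and trans-correlation -> editing-site cascade,
#' writing each stage's outputs (`de.tsv`, `lncrna.tsv`, `pairs.tsv`,
#' `candidates.tsv`, `audit.tsv`) plus a machine-readable `report.json`
#' into `config$out_dir`. Runs with the same configuration and seed are
#' deterministic.
#'
#' @param config a `runConfig` from [validateRunConfig()], a YAML path, a
#'   plain list, or `NULL` for all defaults.
#' @return The run report (list), invisibly.
#' @export
runPipeline <- function(config = NULL) {
    cfg <- if (inherits(config, "runConfig")) config else
        validateRunConfig(config)
    out_dir <- cfg$out_dir
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fcfg <- do.call(filterConfig, cfg$filters)

    if (isTRUE(cfg$simulate)) {
        .stageLog("simulate", "generating synthetic study (seed ",
                  cfg$seed, ")")
        scfg <- do.call(simulationConfig,
                        c(list(seed = as.integer(cfg$seed)), cfg$sim))
        data <- simulateStudy(scfg, out_dir = file.path(out_dir, "sim"))
    } else {
        .stageLog("load", "reading inputs")
        data <- .loadInputs(cfg)
    }
    annotation <- data$annotation
    genome <- data$genome
    se <- data$counts
    groups <- colData(se)$group

    .stageLog("de", "running consensus differential expression on ",
              nrow(se), " TARs")
    resA <- nbWaldTest(se)
    resB <- nbExactTest(se)
    de <- consensusDE(resA, resB, padj_thr = cfg$de_padj_threshold,
                      lfc_thr = cfg$de_lfc_threshold)
    write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    de_summary <- summarizeDE(de, annotation)

    .stageLog("lncrna", "classifying transcripts")
    set.seed(as.integer(cfg$seed) + 3L)   # background-window sampling
    corpora <- hexamerTrainingCorpora(annotation, genome)
    hexmod <- trainHexamerModel(corpora$coding, corpora$noncoding)
    tx <- txTable(annotation)
    reports <- lapply(tx$transcript_id, function(t)
        codingPotentialReport(annotation, genome, t, hexmod,
                              fickett_cutoff = cfg$fickett_cutoff,
                              orf_min_codons = cfg$orf_min_codons,
                              orf_min_coverage = cfg$orf_min_coverage))
    is_lnc <- vapply(seq_along(reports), function(i) {
        classifyLncRNA(reports[[i]], tx$biotype[i],
                       min_length = cfg$lncrna_min_length,
                       min_exons = cfg$lncrna_min_exons)
    }, logical(1))
    lnc_tab <- data.frame(
        transcript_id = tx$transcript_id,
        biotype = tx$biotype,
        spliced_length = vapply(reports, `[[`, 0L, "spliced_length"),
        exon_count = vapply(reports, `[[`, 0L, "exon_count"),
        orf_length = vapply(reports, `[[`, 0L, "orf_length"),
        orf_coverage = vapply(reports, `[[`, 0, "orf_coverage"),
        fickett_score = vapply(reports, `[[`, 0, "fickett_score"),
        hexamer_llr = vapply(reports, `[[`, 0, "hexamer_llr"),
        final_label = vapply(reports, `[[`, "", "final_label"),
        is_lncRNA = is_lnc,
        stringsAsFactors = FALSE)
    write.table(lnc_tab, file.path(out_dir, "lncrna.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    counts <- assay(se, "counts")
    lnc_ids <- tx$transcript_id[is_lnc]
    mrna_ids <- tx$transcript_id[tx$biotype == "protein_coding"]
    pairs <- if (length(lnc_ids) && length(mrna_ids)) {
        transCorrelate(counts[lnc_ids, , drop = FALSE],
                       counts[mrna_ids, , drop = FALSE],
                       threshold = cfg$correlation_threshold)
    } else {
        data.frame(lncrna_id = character(), target_gene_id = character(),
                   r = numeric(), sign = character())
    }
    write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    .stageLog("editing", "running editing-site cascade on ",
              nrow(data$variants), " SNVs")
    vgroups <- data$design$group
    variants <- data$variants[, data$design$sample]
    cascade <- runEditingCascade(variants, annotation, genome, data$masks,
                                 vgroups, fcfg)
    write.table(cascade$candidates, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cascade$audit, file.path(out_dir, "audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    cons_hist <- as.list(table(cascade$candidates$consequence))
    report <- list(
        tool = "editscan",
        version = as.character(utils::packageVersion("editscan")),
        config_hash = .configHash(cfg),
        seed = cfg$seed,
        de_summary = de_summary,
        n_lncRNAs = sum(is_lnc),
        n_trans_pairs = nrow(pairs),
        n_editing_candidates = nrow(cascade$candidates),
        consequence_histogram = cons_hist,
        cascade_audit = cascade$audit
    )
    write_json(report, file.path(out_dir, "report.json"),
               dataframe = "columns", auto_unbox = TRUE, digits = NA)
    .stageLog("done", "report written to ",
              file.path(out_dir, "report.json"))
    invisible(report)
}
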