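#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections \code{cohort} (either
#' \code{synthetic:} with \code{\link{cohortSpec}} arguments or
#' \code{inputs:} with \code{cnv}, \code{expr}, \code{samples},
#' \code{clinical} paths), and optional \code{recurrence} (\code{fracThreshold},
#' \code{minCancers}), \code{de} (\code{alpha}, \code{test}),
#' \code{survival} (\code{horizon}), \code{ordination} (\code{nPerm},
#' \code{seed}, \code{standardize}), \code{enrichment} (\code{gmt},
#' \code{alpha}).  Unknown keys are rejected, not ignored.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
    known <- c("cohort", "recurrence", "de", "survival", "ordination",
               "enrichment")
    extra <- setdiff(names(cfg), known)
    if (length(extra))
        stop("unknown config key(s): ", paste(extra, collapse = ", "))
    if (is.null(cfg$cohort) ||
        is.null(cfg$cohort$synthetic) == is.null(cfg$cohort$inputs))
        stop("config needs cohort: with exactly one of 'synthetic' or 'inputs'")
    if (!is.null(cfg$cohort$synthetic) && is.null(cfg$cohort$synthetic$seed))
        stop("synthetic cohort config must state an explicit seed")
    if (is.null(cfg$ordination)) cfg$ordination <- list()
    if (is.null(cfg$ordination$seed)) cfg$ordination$seed <- 1L
    if (is.null(cfg$ordination$nPerm)) cfg$ordination$nPerm <- 999L
    if (is.null(cfg$de)) cfg$de <- list()
    if (is.null(cfg$de$alpha)) cfg$de$alpha <- 0.05
    if (is.null(cfg$recurrence)) cfg$recurrence <- list()
    if (is.null(cfg$recurrence$fracThreshold))
        cfg$recurrence$fracThreshold <- 0.20
    if (is.null(cfg$survival)) cfg$survival <- list()
    if (is.null(cfg$survival$horizon)) cfg$survival$horizon <- 5
    cfg
}

#' Run the full analysis pipeline
#'
#' Executes the study flow end to end: load or generate the cohort, compute
#' per-cancer alteration fractions and cross-cancer recurrence calls,
#' tumor-versus-normal differential expression, the LoF/GoF gene-set call,
#' mean-expression pathway scores over the derived LoF set, per-cancer
#' Q1/Q4 stratification with log-rank tests and Cox fits, a time-dependent
#' AUC at the configured horizon, tumor/non-tumor ordination with
#' PERMANOVA, and (when a GMT library is configured) Q4-vs-Q1
#' over-representation analysis.  Every artifact is a plain TSV or JSON
#' file; a \code{manifest.json} records the config and MD5 hash of each
#' output, so re-running an identical config reproduces identical hashes.
#'
#' @param config a config list from \code{\link{readPipelineConfig}} (or an
#'   equivalent list, validated internally).
#' @param outDir output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runFullPipeline <- function(config, outDir) {
    config <- validatePipelineConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    notes <- character(0)
    withCallingHandlers({
        results <- runStages(config, outDir)
    }, warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
    files <- setdiff(list.files(outDir, recursive = TRUE),
                     "manifest.json")
    manifest <- list(
        package = "pancanSig",
        version = as.character(utils::packageVersion("pancanSig")),
        config = config,
        warnings = notes,
        hashes = as.list(tools::md5sum(file.path(outDir, sort(files)))))
    names(manifest$hashes) <- sort(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(results, list(manifest = manifest)))
}

runStages <- function(config, outDir) {
    tsv <- function(d, f) utils::write.table(
        d, file.path(outDir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)

    ## stage: cohort
    if (!is.null(config$cohort$synthetic)) {
        spec <- do.call(cohortSpec, config$cohort$synthetic)
        cohort <- generateCohort(spec)
        writeCohort(cohort, file.path(outDir, "cohort"))
        cnvExp <- cnv(cohort); exprExp <- expr(cohort)
        clin <- clinical(cohort)
    } else {
        paths <- config$cohort$inputs
        cnvExp <- readGisticMatrix(paths$cnv, paths$samples)
        exprExp <- readExprMatrix(paths$expr, paths$samples)
        clin <- readClinicalTable(paths$clinical)
        cohort <- NULL
    }

    ## stage: recurrence
    fr <- alterationFractions(cnvExp)
    tsv(fr, "alteration_fractions.tsv")
    K <- length(unique(fr$cancer))
    minC <- config$recurrence$minCancers
    if (is.null(minC)) minC <- minCancerTypes(K)
    del <- recurrentGenes(fr, "deletion", config$recurrence$fracThreshold,
                          minC)
    amp <- recurrentGenes(fr, "amplification",
                          config$recurrence$fracThreshold, minC)
    tsv(rbind(del, amp), "recurrent_genes.tsv")

    ## stage: differential expression
    de <- deTestPerCancer(exprExp, alpha = config$de$alpha)
    tsv(de, "de_results.tsv")
    deCalls <- recurrentDeGenes(de, minC)
    tsv(deCalls, "recurrent_de_genes.tsv")

    ## stage: gene-set call
    call <- callPutativeLofGof(
        del, amp,
        deCalls[deCalls$direction == "down", , drop = FALSE],
        deCalls[deCalls$direction == "up", , drop = FALSE])
    jsonlite::write_json(
        list(lof = lofGenes(call), gof = gofGenes(call),
             conflicts = conflictGenes(call)),
        file.path(outDir, "gene_set_call.json"),
        auto_unbox = FALSE, pretty = TRUE)

    ## stage: scores + strata + survival
    survRows <- list(); strataRows <- list(); score <- NULL
    if (length(lofGenes(call))) {
        sspec <- scoreSpec("derived_LoF", lofGenes(call))
        score <- meanExpressionScore(exprExp, sspec)
        tsv(data.frame(sample = names(score), score = unname(score)),
            "pathway_scores.tsv")
        clinIdx <- match(names(score), clin$sample)
        for (cc in sort(unique(clin$cancer))) {
            sc <- score[!is.na(clinIdx) & clin$cancer[clinIdx] == cc]
            if (length(unique(sc)) < 8L) next
            st <- stratifyByQuantile(sc, 4L)
            strataRows[[cc]] <- cbind(cancer = cc, st)
            eq <- extremeQuartiles(st)
            sub <- clin[clin$sample %in% c(eq$low, eq$high), , drop = FALSE]
            grp <- ifelse(sub$sample %in% eq$high, "Q4", "Q1")
            if (length(unique(grp)) == 2L && sum(sub$event) > 0) {
                lr <- logrankTest(sub$time, sub$event, grp)
                cx <- tryCatch(coxFit(
                    clin$time[clin$cancer == cc],
                    clin$event[clin$cancer == cc],
                    matrix(score[clin$sample[clin$cancer == cc]],
                           ncol = 1, dimnames = list(NULL, "score"))),
                    error = function(e) NULL)
                survRows[[cc]] <- data.frame(
                    cancer = cc, logrankChisq = lr$chisq, logrankP = lr$p,
                    coxHr = if (!is.null(cx)) cx$coefficients$hr else NA,
                    coxP = if (!is.null(cx)) cx$coefficients$waldP else NA)
            }
        }
        if (length(strataRows))
            tsv(do.call(rbind, strataRows), "strata.tsv")
        if (length(survRows))
            tsv(do.call(rbind, survRows), "survival_by_cancer.tsv")

        ## pan-cancer time-dependent AUC of the derived score
        idx <- match(clin$sample, names(score))
        ok <- !is.na(idx)
        roc <- tryCatch(
            tdRocAuc(score[idx[ok]], clin$time[ok], clin$event[ok],
                     config$survival$horizon),
            error = function(e) NULL)
        if (!is.null(roc))
            jsonlite::write_json(
                list(horizon = roc$horizon, auc = roc$auc,
                     orientation = roc$orientation),
                file.path(outDir, "td_roc.json"), auto_unbox = TRUE,
                digits = NA, pretty = TRUE)

        ## stage: ordination (tumor vs non-tumor on the derived gene set)
        ordRows <- list()
        for (cc in sort(unique(cancerOf(exprExp)))) {
            sel <- cancerOf(exprExp) == cc
            lab <- ifelse(tumorFlag(exprExp)[sel], "tumor", "normal")
            if (min(table(lab)) < 2L || length(unique(lab)) < 2L) next
            dmat <- pairwiseDistances(
                exprExp[, sel], lofGenes(call),
                standardize = isTRUE(config$ordination$standardize))
            pv <- permanova(dmat, lab, nPerm = config$ordination$nPerm,
                            seed = config$ordination$seed)
            ordRows[[cc]] <- data.frame(cancer = cc, pseudoF = pv$pseudoF,
                                        R2 = pv$R2, p = pv$p)
        }
        if (length(ordRows))
            tsv(do.call(rbind, ordRows), "permanova_by_cancer.tsv")

        ## stage: enrichment (optional, needs a GMT library)
        if (!is.null(config$enrichment$gmt)) {
            lib <- readGmt(config$enrichment$gmt)
            universe <- rownames(exprExp)
            oraRows <- list()
            for (cc in names(strataRows)) {
                sel <- cancerOf(exprExp) == cc & tumorFlag(exprExp)
                deq <- tryCatch(
                    deBetweenStrata(exprExp[, sel], strataRows[[cc]],
                                    alpha = config$de$alpha),
                    error = function(e) NULL)
                if (is.null(deq)) next
                sig <- deq$gene[deq$direction != "ns"]
                if (!length(sig)) next
                ora <- oraHypergeometric(sig, lib, universe)
                oraRows[[cc]] <- cbind(cancer = cc, ora)
            }
            if (length(oraRows))
                tsv(do.call(rbind, oraRows), "ora_results.tsv")
        }
    }
    invisible(list(cohort = cohort, fractions = fr, de = de, call = call,
                   score = score))
}
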