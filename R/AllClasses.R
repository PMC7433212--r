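#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Gene-level thresholded copy-number container
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"cnv"} of
#' GISTIC-style thresholded calls (integers in \{-2, -1, 0, +1, +2\}, genes in
#' rows, tumor samples in columns) with a mandatory \code{cancer} column in
#' \code{colData} giving each sample's cancer-type code.  NA values are
#' permitted and treated as "not evaluable" downstream.
#'
#' @export
setClass("CnvExperiment", contains = "SummarizedExperiment")

setValidity("CnvExperiment", function(object) {
    msg <- character()
    if (!"cnv" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'cnv' is required")
    else {
        v <- SummarizedExperiment::assay(object, "cnv")
        bad <- !is.na(v) & !(v %in% c(-2L, -1L, 0L, 1L, 2L))
        if (any(bad)) {
            i <- which(bad, arr.ind = TRUE)[1L, ]
            msg <- c(msg, sprintf(
                "CNV value %s outside {-2,...,+2} at gene '%s', sample '%s'",
                format(v[i[1L], i[2L]]), rownames(v)[i[1L]], colnames(v)[i[2L]]))
        }
    }
    if (!"cancer" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'cancer' is required")
    else if (anyNA(colData(object)$cancer))
        msg <- c(msg, "every sample needs a cancer code")
    if (length(msg)) msg else TRUE
})

#' Construct a CnvExperiment
#'
#' @param values integer matrix of thresholded calls, genes x samples, with
#'   dimnames.
#' @param cancer character vector of cancer-type codes, one per column of
#'   \code{values}.
#' @return A \linkS4class{CnvExperiment}.
#' @examples
#' m <- matrix(0L, 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' CnvExperiment(m, cancer = c("BRCA", "BRCA", "STAD"))
#' @export
CnvExperiment <- function(values, cancer) {
    stopifnot(is.matrix(values), length(cancer) == ncol(values))
    storage.mode(values) <- "integer"
    se <- SummarizedExperiment(
        assays = list(cnv = values),
        colData = DataFrame(cancer = as.character(cancer),
                            row.names = colnames(values)))
    new("CnvExperiment", se)
}

#' Expression container with tumor/normal and cancer-type labels
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"expr"} of
#' continuous log2-scale expression (genes x samples) and mandatory
#' \code{colData} columns \code{cancer} (cancer-type code) and \code{tumor}
#' (logical; TRUE for tumor, FALSE for non-tumor samples).
#'
#' @export
setClass("ExprExperiment", contains = "SummarizedExperiment")

setValidity("ExprExperiment", function(object) {
    msg <- character()
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else if (any(!is.finite(SummarizedExperiment::assay(object, "expr"))))
        msg <- c(msg, "expression values must be finite")
    cd <- colData(object)
    if (!all(c("cancer", "tumor") %in% colnames(cd)))
        msg <- c(msg, "colData columns 'cancer' and 'tumor' are required")
    else {
        if (anyNA(cd$cancer)) msg <- c(msg, "every sample needs a cancer code")
        if (!is.logical(cd$tumor) || anyNA(cd$tumor))
            msg <- c(msg, "'tumor' must be logical with no NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExprExperiment
#'
#' @param values numeric matrix of log2-scale expression, genes x samples,
#'   with dimnames.
#' @param cancer character vector of cancer codes, one per sample.
#' @param tumor logical vector, TRUE for tumor samples.
#' @return An \linkS4class{ExprExperiment}.
#' @export
ExprExperiment <- function(values, cancer, tumor) {
    stopifnot(is.matrix(values), length(cancer) == ncol(values),
              length(tumor) == ncol(values))
    se <- SummarizedExperiment(
        assays = list(expr = values),
        colData = DataFrame(cancer = as.character(cancer),
                            tumor = as.logical(tumor),
                            row.names = colnames(values)))
    new("ExprExperiment", se)
}

#' Synthetic multi-cancer cohort
#'
#' Bundles the three tables the pipeline consumes — thresholded copy number
#' (tumors only), expression (tumors and non-tumors) and clinical outcomes —
#' together with the ground-truth record of what was planted.
#'
#' @slot cnv a \linkS4class{CnvExperiment} over tumor samples.
#' @slot expr an \linkS4class{ExprExperiment} over tumor and non-tumor samples.
#' @slot clinical data.frame with columns \code{sample}, \code{cancer},
#'   \code{time}, \code{event}, \code{stage}.
#' @slot truth list recording planted gene sets, affected cancers and the true
#'   log-hazard coefficient.
#' @export
setClass("SyntheticCohort",
    representation(cnv = "CnvExperiment", expr = "ExprExperiment",
                   clinical = "data.frame", truth = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    tum <- colnames(object@expr)[colData(object@expr)$tumor]
    if (!setequal(colnames(object@cnv), tum))
        msg <- c(msg, "CNV samples must be exactly the tumor expression samples")
    if (!all(tum %in% object@clinical$sample))
        msg <- c(msg, "every tumor sample must appear in the clinical table")
    if (length(msg)) msg else TRUE
})

#' Putative loss-/gain-of-function gene-set call
#'
#' Result of intersecting cross-cancer copy-number recurrence with
#' cross-cancer differential-expression recurrence.  Genes qualifying for both
#' directions are excluded from both sets and listed in \code{conflicts}, so
#' \code{lofGenes} and \code{gofGenes} are disjoint by construction.
#'
#' @slot lofGenes character; recurrently deleted and recurrently downregulated.
#' @slot gofGenes character; recurrently amplified and recurrently upregulated.
#' @slot conflicts character; genes qualifying for both calls.
#' @slot evidence list with per-gene recurrence and DE evidence tables.
#' @export
setClass("GeneSetCall",
    representation(lofGenes = "character", gofGenes = "character",
                   conflicts = "character", evidence = "list"))

setValidity("GeneSetCall", function(object) {
    if (length(intersect(object@lofGenes, object@gofGenes)))
        "lofGenes and gofGenes must be disjoint" else TRUE
})

setMethod("show", "CnvExperiment", function(object) {
    callNextMethod()
    cat(sprintf("cancer types: %d\n",
                length(unique(colData(object)$cancer))))
})

setMethod("show", "ExprExperiment", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat(sprintf("cancer types: %d | tumors: %d | non-tumors: %d\n",
                length(unique(cd$cancer)), sum(cd$tumor), sum(!cd$tumor)))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort\n")
    cat(sprintf("  %d genes, %d tumor samples, %d non-tumor samples, %d cancer types\n",
                nrow(object@expr), sum(colData(object@expr)$tumor),
                sum(!colData(object@expr)$tumor),
                length(unique(colData(object@expr)$cancer))))
    cat(sprintf("  planted LoF: %d | planted GoF: %d | beta = %.3f\n",
                length(object@truth$planted_lof),
                length(object@truth$planted_gof), object@truth$beta))
})

setMethod("show", "GeneSetCall", function(object) {
    cat("GeneSetCall\n")
    cat(sprintf("  putative LoF (%d): %s\n", length(object@lofGenes),
                paste(object@lofGenes, collapse = ", ")))
    cat(sprintf("  putative GoF (%d): %s\n", length(object@gofGenes),
                paste(object@gofGenes, collapse = ", ")))
    if (length(object@conflicts))
        cat(sprintf("  conflicts (%d): %s\n", length(object@conflicts),
                    paste(object@conflicts, collapse = ", ")))
})
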