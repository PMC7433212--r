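#' Read a GISTIC-style thresholded copy-number table
#'
#' Expects the "all_thresholded.by_genes" dialect: a header row of sample ids,
#' a first column of gene symbols, and one integer column in
#' \{-2,-1,0,+1,+2\} per sample.  A companion sample table supplies the
#' sample-to-cancer mapping.
#'
#' @param path TSV of thresholded calls.
#' @param samplesPath TSV with columns \code{sample} and \code{cancer} (extra
#'   columns ignored).
#' @return A \linkS4class{CnvExperiment}.
#' @export
readGisticMatrix <- function(path, samplesPath) {
    m <- readMatrixTsv(path)
    if (any(m != round(m), na.rm = TRUE))
        stop("non-integer copy-number value in ", path)
    smp <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "cancer") %in% names(smp)))
        stop("sample table needs 'sample' and 'cancer' columns")
    miss <- setdiff(colnames(m), smp$sample)
    if (length(miss))
        stop("samples missing from mapping: ", paste(miss, collapse = ", "))
    CnvExperiment(m, cancer = smp$cancer[match(colnames(m), smp$sample)])
}

#' Read an expression matrix with sample labels
#'
#' @param path TSV, genes in rows (first column \code{gene}), samples in
#'   columns, continuous log2-scale values.
#' @param samplesPath TSV with columns \code{sample}, \code{cancer} and
#'   \code{tumor} (0/1 or logical).
#' @return An \linkS4class{ExprExperiment}.
#' @export
readExprMatrix <- function(path, samplesPath) {
    m <- readMatrixTsv(path)
    smp <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "cancer", "tumor") %in% names(smp)))
        stop("sample table needs 'sample', 'cancer' and 'tumor' columns")
    i <- match(colnames(m), smp$sample)
    if (anyNA(i))
        stop("samples missing from mapping: ",
             paste(colnames(m)[is.na(i)], collapse = ", "))
    ExprExperiment(m, cancer = smp$cancer[i],
                   tumor = as.logical(smp$tumor[i]))
}

readMatrixTsv <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (names(d)[1L] != "gene")
        stop("first column of ", path, " must be 'gene'")
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$gene
    storage.mode(m) <- "double"
    m
}

#' Read a clinical table
#'
#' @param path TSV with columns \code{sample}, \code{cancer}, \code{time}
#'   (positive, one unit throughout), \code{event} (0/1; 1 = death) and
#'   optionally \code{stage} and \code{subtype}.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "cancer", "time", "event")
    if (!all(need %in% names(d)))
        stop("clinical table needs columns: ", paste(need, collapse = ", "))
    if (any(d$time <= 0)) stop("survival times must be positive")
    if (anyNA(d$event) || !all(d$event %in% c(0, 1)))
        stop("event must be 0/1 with no missing values")
    d
}

#' Write a synthetic cohort to plain-text artifacts
#'
#' Emits \code{cnv.tsv}, \code{expr.tsv}, \code{samples.tsv},
#' \code{clinical.tsv} and \code{truth.json} into \code{dir}; the TSVs
#' round-trip through \code{\link{readGisticMatrix}},
#' \code{\link{readExprMatrix}} and \code{\link{readClinicalTable}}.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("cnv.tsv", "expr.tsv", "samples.tsv",
                              "clinical.tsv", "truth.json"))
    writeMatrixTsv(SummarizedExperiment::assay(cnv(cohort), "cnv"), paths[1L])
    e <- expr(cohort)
    writeMatrixTsv(SummarizedExperiment::assay(e, "expr"), paths[2L])
    smp <- data.frame(sample = colnames(e), cancer = cancerOf(e),
                      tumor = as.integer(tumorFlag(e)))
    utils::write.table(smp, paths[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(clinical(cohort), paths[4L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr <- cohortTruth(cohort)
    tr$score <- NULL
    tr$spec <- unclass(tr$spec)
    jsonlite::write_json(tr, paths[5L], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(paths)
}

writeMatrixTsv <- function(m, path) {
    d <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene-list files
#'
#' \code{readGeneList} reads one symbol per line; \code{readSignedGeneList}
#' reads a two-column TSV (\code{gene}, \code{sign} in \{-1, +1\}).
#'
#' @param path file path.
#' @return character vector of symbols, or a data.frame with \code{gene} and
#'   \code{sign}.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x)]
}

#' @rdname readGeneList
#' @export
readSignedGeneList <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene", "sign") %in% names(d)))
        stop("signed gene list needs 'gene' and 'sign' columns")
    if (!all(d$sign %in% c(-1, 1)))
        stop("signs must be -1 or +1")
    d
}
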