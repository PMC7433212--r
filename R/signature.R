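#' Define a pathway score specification
#'
#' A named, optionally signed gene list.  Mean-expression scores use all
#' +1 signs; signed composite scores (the mTOR/PI3K/AKT score) mix +1 and
#' -1 terms.
#'
#' @param name score name.
#' @param genes character vector of gene symbols.
#' @param signs numeric vector of +1/-1, one per gene (default all +1).
#' @return list of class \code{"ScoreSpec"}.
#' @export
scoreSpec <- function(name, genes, signs = rep(1, length(genes))) {
    genes <- as.character(genes)
    if (length(signs) != length(genes))
        stop("one sign per gene required")
    if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
    if (anyDuplicated(genes)) stop("duplicate genes in score spec")
    structure(list(name = name, genes = genes, signs = as.numeric(signs)),
              class = "ScoreSpec")
}

#' Packaged pathway score specifications
#'
#' The three gene lists shipped with the package: the 24-gene AMPK
#' loss-of-function set and the 18-gene PPAR set (mean-expression scores),
#' and the six-term signed mTOR/PI3K/AKT composite
#' (AKT + mTOR + GSK3 + S6K + S6 - PTEN).  The mTOR list names pathway
#' members at the protein level; this fixture maps each to one canonical
#' gene symbol (AKT1, MTOR, GSK3B, RPS6KB1, RPS6, PTEN) — an interpretation,
#' since several paralogs exist.
#'
#' @return A \code{\link{scoreSpec}}.
#' @export
ampkScoreSpec <- function() {
    scoreSpec("AMPK24", readGeneList(
        system.file("extdata", "ampk24_genes.txt", package = "pancanSig",
                    mustWork = TRUE)))
}

#' @rdname ampkScoreSpec
#' @export
pparScoreSpec <- function() {
    scoreSpec("PPAR18", readGeneList(
        system.file("extdata", "ppar18_genes.txt", package = "pancanSig",
                    mustWork = TRUE)))
}

#' @rdname ampkScoreSpec
#' @export
mtorScoreSpec <- function() {
    d <- readSignedGeneList(
        system.file("extdata", "mtor_score_signed.tsv", package = "pancanSig",
                    mustWork = TRUE))
    scoreSpec("mTOR", d$gene, d$sign)
}

#' Intersect recurrence and differential-expression evidence
#'
#' Putative loss-of-function genes are those recurrently deleted and
#' recurrently downregulated; putative gain-of-function genes recurrently
#' amplified and upregulated.  Genes qualifying for both calls are excluded
#' from both sets and reported as conflicts with a warning, enforcing mutual
#' exclusivity of the two sets.
#'
#' @param delCalls,ampCalls outputs of \code{\link{recurrentGenes}} for the
#'   deletion and amplification directions.
#' @param downCalls,upCalls rows of \code{\link{recurrentDeGenes}} with the
#'   matching direction (filtered internally if mixed).
#' @return A \linkS4class{GeneSetCall}.
#' @export
callPutativeLofGof <- function(delCalls, ampCalls, downCalls, upCalls) {
    down <- downCalls[downCalls$direction == "down", , drop = FALSE]
    up <- upCalls[upCalls$direction == "up", , drop = FALSE]
    lof <- sort(intersect(delCalls$gene, down$gene))
    gof <- sort(intersect(ampCalls$gene, up$gene))
    conflicts <- intersect(lof, gof)
    if (length(conflicts)) {
        warning("genes qualify for both LoF and GoF, excluded from both: ",
                paste(conflicts, collapse = ", "), call. = FALSE)
        lof <- setdiff(lof, conflicts)
        gof <- setdiff(gof, conflicts)
    }
    keep <- c(lof, gof, conflicts)
    new("GeneSetCall", lofGenes = lof, gofGenes = gof,
        conflicts = sort(conflicts),
        evidence = list(
            recurrence = rbind(
                delCalls[delCalls$gene %in% keep, , drop = FALSE],
                ampCalls[ampCalls$gene %in% keep, , drop = FALSE]),
            de = rbind(down[down$gene %in% keep, , drop = FALSE],
                       up[up$gene %in% keep, , drop = FALSE])))
}

#' Mean-expression pathway score
#'
#' Per-sample arithmetic mean of log2 expression over the genes of an
#' unsigned score spec.  By default only tumor samples are scored; set
#' \code{tumorOnly = FALSE} to score every sample (ordination input).
#' Genes absent from the matrix are tolerated down to a fraction
#' \code{minCoverage} of the spec (default 1: all genes required).
#'
#' @param exprExp an \linkS4class{ExprExperiment}.
#' @param spec an unsigned \code{\link{scoreSpec}}.
#' @param minCoverage minimum fraction of spec genes that must be present.
#' @param tumorOnly score tumor samples only (default TRUE).
#' @return named numeric vector of scores.
#' @export
meanExpressionScore <- function(exprExp, spec, minCoverage = 1,
                                tumorOnly = TRUE) {
    stopifnot(inherits(spec, "ScoreSpec"))
    if (!all(spec$signs == 1))
        stop("mean-expression scores require an unsigned spec; ",
             "use compositeScore() for signed lists")
    v <- SummarizedExperiment::assay(exprExp, "expr")
    if (tumorOnly) v <- v[, tumorFlag(exprExp), drop = FALSE]
    present <- intersect(spec$genes, rownames(v))
    if (!length(present))
        stop("none of the ", length(spec$genes), " '", spec$name,
             "' genes are in the expression matrix")
    if (length(present) / length(spec$genes) < minCoverage)
        stop("only ", length(present), "/", length(spec$genes), " '",
             spec$name, "' genes present; below minCoverage = ", minCoverage)
    if (length(present) < length(spec$genes))
        warning("scoring '", spec$name, "' on ", length(present), "/",
                length(spec$genes), " genes; missing: ",
                paste(setdiff(spec$genes, present), collapse = ", "),
                call. = FALSE)
    colMeans(v[present, , drop = FALSE])
}

#' Signed composite pathway score
#'
#' Per-sample signed sum \eqn{\sum_g sign_g \, x_g} over the spec genes.
#' All genes must be present: a signed sum with a missing term changes
#' meaning, so no coverage relaxation is offered.
#'
#' @inheritParams meanExpressionScore
#' @param spec a signed \code{\link{scoreSpec}}.
#' @return named numeric vector of scores.
#' @export
compositeScore <- function(exprExp, spec, tumorOnly = TRUE) {
    stopifnot(inherits(spec, "ScoreSpec"))
    v <- SummarizedExperiment::assay(exprExp, "expr")
    if (tumorOnly) v <- v[, tumorFlag(exprExp), drop = FALSE]
    missing <- setdiff(spec$genes, rownames(v))
    if (length(missing))
        stop("composite score '", spec$name, "' gene(s) missing from matrix: ",
             paste(missing, collapse = ", "))
    colSums(v[spec$genes, , drop = FALSE] * spec$signs)
}

#' Stratify samples by score quantiles
#'
#' Bins samples by empirical quantile cutoffs (linear-interpolation
#' definition, \code{stats::quantile} type 7).  Samples falling exactly on a
#' cutoff are assigned to the lower bin.  Labels are \code{Q1} (lowest) to
#' \code{Qq}.
#'
#' @param score named numeric score vector.
#' @param q number of quantile bins (default 4).
#' @return data.frame of class \code{"StrataAssignment"} with columns
#'   \code{sample}, \code{label}; attribute \code{"cutoffs"} holds the
#'   internal cutoffs used.
#' @export
stratifyByQuantile <- function(score, q = 4L) {
    if (length(unique(score)) < q)
        stop("need at least ", q, " distinct score values to form ", q,
             " bins")
    cuts <- stats::quantile(score, probs = seq(0, 1, length.out = q + 1),
                            names = FALSE, type = 7)
    bin <- cut(score, breaks = cuts, include.lowest = TRUE, right = TRUE,
               labels = paste0("Q", seq_len(q)))
    out <- data.frame(sample = names(score), label = as.character(bin),
                      stringsAsFactors = FALSE)
    attr(out, "cutoffs") <- cuts[-c(1L, q + 1L)]
    class(out) <- c("StrataAssignment", class(out))
    out
}

#' Extract the extreme quartile samples
#'
#' @param strata a \code{\link{stratifyByQuantile}} assignment.
#' @return list with character vectors \code{low} (Q1) and \code{high}
#'   (highest bin).
#' @export
extremeQuartiles <- function(strata) {
    labs <- unique(strata$label)
    top <- labs[order(as.integer(sub("^Q", "", labs)))][length(labs)]
    list(low = strata$sample[strata$label == "Q1"],
         high = strata$sample[strata$label == top])
}

#' Joint median (quadrant) stratification of two scores
#'
#' Dichotomizes each score at its median (value > median is high, <= median
#' is low) and labels each sample with the quadrant pair
#' \code{low-low}, \code{low-high}, \code{high-low}, \code{high-high},
#' first component from \code{scoreA}.
#'
#' @param scoreA,scoreB named numeric score vectors over the same samples.
#' @return data.frame of class \code{"StrataAssignment"} with columns
#'   \code{sample}, \code{label}; attribute \code{"cutoffs"} holds the two
#'   medians.
#' @export
stratifyByMedianPairs <- function(scoreA, scoreB) {
    common <- intersect(names(scoreA), names(scoreB))
    if (!setequal(names(scoreA), names(scoreB)))
        stop("scores must cover the same samples")
    a <- scoreA[common]; b <- scoreB[common]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L)
        stop("constant score cannot be dichotomized")
    ma <- stats::median(a); mb <- stats::median(b)
    lab <- paste(ifelse(a > ma, "high", "low"),
                 ifelse(b > mb, "high", "low"), sep = "-")
    out <- data.frame(sample = common, label = lab,
                      stringsAsFactors = FALSE)
    attr(out, "cutoffs") <- c(medianA = ma, medianB = mb)
    class(out) <- c("StrataAssignment", class(out))
    out
}
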