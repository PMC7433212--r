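#' Tumor versus non-tumor differential expression per cancer
#'
#' Runs a two-sided Wilcoxon rank-sum test (or Welch t-test) per gene within
#' each cancer type, comparing tumor to non-tumor samples, with
#' Benjamini-Hochberg correction across genes within each cancer.  Cancers
#' with fewer than \code{minGroup} tumors or non-tumors are skipped with a
#' warning (the study design tolerates cohorts that lack normals).
#' \code{log2fc} is the difference of group means on the log2 scale
#' (tumor minus non-tumor); direction is its sign for genes with
#' \code{q <= alpha}, \code{"ns"} otherwise.
#'
#' @param exprExp an \linkS4class{ExprExperiment}.
#' @param alpha FDR significance level (default 0.05).
#' @param test \code{"wilcoxon"} (default) or \code{"welch"}.
#' @param minGroup minimum samples per group (default 3).
#' @return data.frame with columns \code{gene}, \code{cancer},
#'   \code{log2fc}, \code{p}, \code{q}, \code{direction}.
#' @export
deTestPerCancer <- function(exprExp, alpha = 0.05,
                            test = c("wilcoxon", "welch"), minGroup = 3L) {
    test <- match.arg(test)
    stopifnot(is(exprExp, "ExprExperiment"))
    v <- SummarizedExperiment::assay(exprExp, "expr")
    cancer <- cancerOf(exprExp)
    tumor <- tumorFlag(exprExp)
    res <- lapply(sort(unique(cancer)), function(cc) {
        tIdx <- cancer == cc & tumor
        nIdx <- cancer == cc & !tumor
        if (sum(tIdx) < minGroup || sum(nIdx) < minGroup) {
            warning("skipping cancer ", cc, ": ", sum(tIdx), " tumor / ",
                    sum(nIdx), " non-tumor samples (need >= ", minGroup,
                    " each)", call. = FALSE)
            return(NULL)
        }
        twoGroupDe(v[, tIdx, drop = FALSE], v[, nIdx, drop = FALSE],
                   cc, alpha, test)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(gene = character(), cancer = character(),
                          log2fc = numeric(), p = numeric(), q = numeric(),
                          direction = character(), stringsAsFactors = FALSE)
    out
}

# Shared two-group testing core used for tumor/normal and Q4/Q1 contrasts.
twoGroupDe <- function(a, b, label, alpha, test) {
    p <- vapply(seq_len(nrow(a)), function(i) {
        x <- a[i, ]; y <- b[i, ]
        if (length(unique(c(x, y))) == 1L) return(1)
        if (test == "wilcoxon")
            suppressWarnings(stats::wilcox.test(x, y)$p.value)
        else
            stats::t.test(x, y)$p.value
    }, numeric(1))
    q <- bhAdjust(p)
    lfc <- rowMeans(a) - rowMeans(b)
    direction <- ifelse(q <= alpha, ifelse(lfc > 0, "up", "down"), "ns")
    data.frame(gene = rownames(a), cancer = label, log2fc = lfc, p = p,
               q = q, direction = direction,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The FDR correction used pipeline-wide (across genes within a cancer and
#' across terms within a gene-set library).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

#' Cross-cancer recurrence of differential expression
#'
#' A gene is called recurrently up (down) when it is significant with that
#' direction in at least \code{minCancers} cancer types.  A gene may be
#' called in both directions if cancers disagree; the signature module
#' resolves such conflicts.
#'
#' @param de output of \code{\link{deTestPerCancer}}.
#' @param minCancers minimum number of significant cancers; default
#'   \code{ceiling(K / 3)} over the cancers present in \code{de}.
#' @return data.frame with columns \code{gene}, \code{direction},
#'   \code{nCancersSignificant}, \code{cancers} (comma-separated), sorted by
#'   count (decreasing) then gene.
#' @export
recurrentDeGenes <- function(de, minCancers = NULL) {
    K <- length(unique(de$cancer))
    if (is.null(minCancers)) minCancers <- minCancerTypes(K)
    stopifnot(minCancers >= 1)
    sig <- de[de$direction %in% c("up", "down"), , drop = FALSE]
    out <- lapply(c("up", "down"), function(d) {
        sub <- sig[sig$direction == d, , drop = FALSE]
        if (!nrow(sub)) return(NULL)
        byGene <- split(sub$cancer, sub$gene)
        n <- lengths(byGene)
        keep <- n >= minCancers
        if (!any(keep)) return(NULL)
        data.frame(gene = names(byGene)[keep], direction = d,
                   nCancersSignificant = unname(n[keep]),
                   cancers = vapply(byGene[keep], function(x)
                       paste(sort(x), collapse = ","), character(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(data.frame(gene = character(), direction = character(),
                          nCancersSignificant = integer(),
                          cancers = character(), stringsAsFactors = FALSE))
    out[order(-out$nCancersSignificant, out$gene), , drop = FALSE]
}

#' Differential expression between score strata
#'
#' Applies the same test machinery to tumors of one cancer stratified into
#' high- (Q4) and low- (Q1) scoring groups, the contrast feeding
#' over-representation analysis.
#'
#' @param exprExp an \linkS4class{ExprExperiment}.
#' @param strata a \code{\link{stratifyByQuantile}} assignment; only samples
#'   labelled \code{Q1} and \code{Q4} are used, and both strata must contain
#'   at least \code{minGroup} samples present in \code{exprExp}.
#' @param alpha FDR level (default 0.05).
#' @param test,minGroup as in \code{\link{deTestPerCancer}}.
#' @return data.frame as \code{\link{deTestPerCancer}}, with \code{cancer}
#'   column fixed to \code{"Q4_vs_Q1"}.
#' @export
deBetweenStrata <- function(exprExp, strata, alpha = 0.05,
                            test = c("wilcoxon", "welch"), minGroup = 3L) {
    test <- match.arg(test)
    stopifnot(is(exprExp, "ExprExperiment"))
    lab <- strata$label[match(colnames(exprExp), strata$sample)]
    hi <- !is.na(lab) & lab == "Q4"
    lo <- !is.na(lab) & lab == "Q1"
    if (sum(hi) < minGroup || sum(lo) < minGroup)
        stop("each stratum needs >= ", minGroup, " samples (got Q4=",
             sum(hi), ", Q1=", sum(lo), ")")
    v <- SummarizedExperiment::assay(exprExp, "expr")
    twoGroupDe(v[, hi, drop = FALSE], v[, lo, drop = FALSE],
               "Q4_vs_Q1", alpha, test)
}
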