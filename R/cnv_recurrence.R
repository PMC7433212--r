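#' Classify a GISTIC thresholded value
#'
#' Maps the discrete gene-level calls to alteration classes: -2 deep
#' (homozygous) deletion, -1 shallow (heterozygous) deletion, 0 neutral,
#' +1 shallow amplification, +2 deep amplification.
#'
#' @param v integer vector of thresholded values.
#' @param gene,sample optional labels used in error messages.
#' @return character vector of classes.
#' @examples
#' classifyGisticValue(c(-2, -1, 0, 1, 2))
#' @export
classifyGisticValue <- function(v, gene = NULL, sample = NULL) {
    bad <- !is.na(v) & !(v %in% -2:2)
    if (any(bad)) {
        where <- if (!is.null(gene) || !is.null(sample))
            sprintf(" (gene %s, sample %s)",
                    paste(gene[bad], collapse = ","),
                    paste(sample[bad], collapse = ",")) else ""
        stop("invalid GISTIC thresholded value ",
             paste(unique(v[bad]), collapse = ","), where)
    }
    cls <- c("deep_deletion", "shallow_deletion", "neutral",
             "shallow_amplification", "deep_amplification")
    out <- cls[v + 3L]
    out
}

#' Per-gene per-cancer alteration fractions
#'
#' Counts classified copy-number calls within each cancer type and returns
#' the fraction of evaluable samples carrying shallow/deep deletions and
#' amplifications.  \code{fracDel} and \code{fracAmp} combine shallow and
#' deep events.  NA calls are excluded from numerator and denominator, so
#' fractions are over evaluable samples.
#'
#' @param cnvExp a \linkS4class{CnvExperiment}.
#' @return data.frame with one row per (gene, cancer): columns \code{gene},
#'   \code{cancer}, \code{fracShallowDel}, \code{fracDeepDel},
#'   \code{fracShallowAmp}, \code{fracDeepAmp}, \code{fracDel},
#'   \code{fracAmp}, \code{nSamples}.
#' @export
alterationFractions <- function(cnvExp) {
    stopifnot(is(cnvExp, "CnvExperiment"))
    v <- SummarizedExperiment::assay(cnvExp, "cnv")
    cancer <- cancerOf(cnvExp)
    cancers <- sort(unique(cancer))
    if (any(table(cancer) < 1L)) stop("empty cancer group")
    res <- lapply(cancers, function(cc) {
        sub <- v[, cancer == cc, drop = FALSE]
        nEval <- rowSums(!is.na(sub))
        if (any(nEval == 0L))
            stop("gene with no evaluable samples in cancer ", cc)
        data.frame(
            gene = rownames(sub), cancer = cc,
            fracShallowDel = rowSums(sub == -1L, na.rm = TRUE) / nEval,
            fracDeepDel    = rowSums(sub == -2L, na.rm = TRUE) / nEval,
            fracShallowAmp = rowSums(sub == +1L, na.rm = TRUE) / nEval,
            fracDeepAmp    = rowSums(sub == +2L, na.rm = TRUE) / nEval,
            nSamples = nEval,
            stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, res)
    out$fracDel <- out$fracShallowDel + out$fracDeepDel
    out$fracAmp <- out$fracShallowAmp + out$fracDeepAmp
    out
}

#' Cross-cancer recurrence filter for copy-number alterations
#'
#' A gene is called recurrently deleted (amplified) when its combined
#' shallow+deep deletion (amplification) fraction is at least
#' \code{fracThreshold} in at least \code{minCancers} cancer types; both
#' comparisons are inclusive.  The default minimum is one third of the
#' cancer types, rounded up (7 of 21).
#'
#' @param fractions output of \code{\link{alterationFractions}}.
#' @param direction \code{"deletion"} or \code{"amplification"}.
#' @param fracThreshold within-cancer sample fraction cutoff (default 0.20).
#' @param minCancers minimum number of cancer types passing the cutoff;
#'   default \code{ceiling(K / 3)} for K cancer types present.
#' @param combineShallowDeep count shallow and deep events together
#'   (default TRUE); if FALSE only deep events are counted.
#' @return data.frame of calls sorted by \code{nCancersPassing} (decreasing)
#'   then gene: columns \code{gene}, \code{direction},
#'   \code{nCancersPassing}, \code{cancersPassing} (comma-separated).
#' @export
recurrentGenes <- function(fractions,
                           direction = c("deletion", "amplification"),
                           fracThreshold = 0.20,
                           minCancers = NULL,
                           combineShallowDeep = TRUE) {
    direction <- match.arg(direction)
    K <- length(unique(fractions$cancer))
    if (is.null(minCancers)) minCancers <- minCancerTypes(K)
    stopifnot(fracThreshold > 0, fracThreshold <= 1,
              minCancers >= 1, minCancers <= K)
    frac <- if (direction == "deletion") {
        if (combineShallowDeep) fractions$fracDel else fractions$fracDeepDel
    } else {
        if (combineShallowDeep) fractions$fracAmp else fractions$fracDeepAmp
    }
    pass <- fractions[frac >= fracThreshold, c("gene", "cancer")]
    if (!nrow(pass)) {
        return(data.frame(gene = character(), direction = character(),
                          nCancersPassing = integer(),
                          cancersPassing = character(),
                          stringsAsFactors = FALSE))
    }
    byGene <- split(pass$cancer, pass$gene)
    n <- lengths(byGene)
    keep <- n >= minCancers
    out <- data.frame(gene = names(byGene)[keep],
                      direction = direction,
                      nCancersPassing = unname(n[keep]),
                      cancersPassing = vapply(byGene[keep], function(x)
                          paste(sort(x), collapse = ","), character(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$nCancersPassing, out$gene), , drop = FALSE]
}

#' Minimum cancer-type count for the one-third recurrence rule
#'
#' @param K number of cancer types.
#' @return \code{ceiling(K / 3)} as an integer (7 for the 21-cancer design).
#' @export
minCancerTypes <- function(K) as.integer(ceiling(K / 3))
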