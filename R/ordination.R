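#' Pairwise sample distances on a gene set
#'
#' Euclidean distances between samples restricted to the given genes,
#' optionally after per-gene z-scoring across the included samples.
#'
#' @param exprExp an \linkS4class{ExprExperiment}.
#' @param genes gene symbols to use; all must be present.
#' @param standardize z-score each gene across samples first (default FALSE).
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
pairwiseDistances <- function(exprExp, genes, standardize = FALSE) {
    stopifnot(is(exprExp, "ExprExperiment"))
    if (ncol(exprExp) < 2L) stop("need >= 2 samples")
    miss <- setdiff(genes, rownames(exprExp))
    if (length(miss))
        stop("gene(s) absent from matrix: ", paste(miss, collapse = ", "))
    v <- SummarizedExperiment::assay(exprExp, "expr")[genes, , drop = FALSE]
    if (standardize) {
        v <- t(scale(t(v)))
        v[is.nan(v)] <- 0  # constant gene: no contribution
    }
    as.matrix(stats::dist(t(v)))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of \eqn{-d^2/2} followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues, ordered by decreasing eigenvalue and centered by
#' construction.  Negative eigenvalues (non-Euclidean input) are reported,
#' and their axes dropped; if fewer than \code{k} positive eigenvalues
#' exist the embedding is truncated with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of axes requested (default 2).
#' @return list of class \code{"PcoaEmbedding"}: \code{points} (samples x
#'   axes), \code{eigenvalues} (all), \code{varExplained} (fraction of the
#'   positive-eigenvalue total per retained axis).
#' @export
pcoa <- function(d, k = 2L) {
    d <- as.matrix(d)
    stopifnot(k >= 1L, nrow(d) == ncol(d))
    if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
    n <- nrow(d)
    A <- -0.5 * d^2
    J <- diag(n) - matrix(1 / n, n, n)
    B <- J %*% A %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    pos <- e$values > max(e$values[1L], 0) * 1e-9
    nPos <- sum(pos)
    if (nPos < k) {
        warning("only ", nPos, " positive eigenvalues; truncating to ",
                nPos, " axes", call. = FALSE)
        k <- nPos
    }
    pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(e$values[seq_len(k)]), k)
    dimnames(pts) <- list(rownames(d), paste0("axis", seq_len(k)))
    structure(list(points = pts, eigenvalues = e$values,
                   varExplained = e$values[seq_len(k)] /
                       sum(e$values[e$values > 0])),
              class = "PcoaEmbedding")
}

#' Permutational multivariate analysis of variance
#'
#' Distance-based one-factor PERMANOVA: total sum of squares is
#' \eqn{\sum_{i<j} d_{ij}^2 / n}, within-group sums analogous within each
#' group, and the pseudo-F is
#' \eqn{(SS_B/(g-1)) / (SS_W/(n-g))}.  Significance comes from label
#' permutations: \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}.  With
#' \code{exhaustive = TRUE} all distinct label arrangements are enumerated
#' instead and \eqn{p} is the exact fraction (observed arrangement
#' included) with \eqn{F^\pi \ge F}.
#'
#' @param d symmetric distance matrix.
#' @param labels group labels, >= 2 groups with >= 2 samples each.
#' @param nPerm number of random permutations (default 999).
#' @param seed RNG seed for the permutations (required: reproducibility
#'   over convention).
#' @param exhaustive enumerate all distinct label arrangements (feasible
#'   for small n only).
#' @return list of class \code{"PermanovaResult"}: \code{pseudoF},
#'   \code{R2}, \code{p}, \code{nPerm}, \code{seed}, \code{exhaustive}.
#' @export
permanova <- function(d, labels, nPerm = 999L, seed, exhaustive = FALSE) {
    d <- as.matrix(d)
    labels <- as.character(labels)
    stopifnot(nrow(d) == length(labels))
    tab <- table(labels)
    if (length(tab) < 2L || any(tab < 2L))
        stop("need >= 2 groups with >= 2 samples each")
    Fobs <- permanovaF(d, labels)
    if (exhaustive) {
        perms <- distinctArrangements(labels)
        Fall <- vapply(perms, function(lb) permanovaF(d, lb)$F, numeric(1))
        p <- mean(Fall >= Fobs$F - 1e-12)
        nUsed <- length(perms)
    } else {
        if (missing(seed)) stop("seed is required for random permutations")
        set.seed(seed)
        Fperm <- vapply(seq_len(nPerm), function(i)
            permanovaF(d, sample(labels))$F, numeric(1))
        p <- (1 + sum(Fperm >= Fobs$F - 1e-12)) / (1 + nPerm)
        nUsed <- nPerm
    }
    structure(list(pseudoF = Fobs$F, R2 = Fobs$R2, p = p, nPerm = nUsed,
                   seed = if (exhaustive) NA_integer_ else seed,
                   exhaustive = exhaustive),
              class = "PermanovaResult")
}

# Anderson partitioning of distance-based sums of squares.
permanovaF <- function(d, labels) {
    n <- nrow(d)
    g <- length(unique(labels))
    d2 <- d^2
    ssT <- sum(d2[upper.tri(d2)]) / n
    ssW <- 0
    for (lv in unique(labels)) {
        idx <- labels == lv
        sub <- d2[idx, idx, drop = FALSE]
        ssW <- ssW + sum(sub[upper.tri(sub)]) / sum(idx)
    }
    ssB <- ssT - ssW
    list(F = (ssB / (g - 1)) / (ssW / (n - g)), R2 = ssB / ssT)
}

# All distinct assignments of the multiset of labels to positions.
distinctArrangements <- function(labels) {
    uniq <- unique(labels)
    rec <- function(remaining, counts) {
        if (!length(remaining)) return(list(character(0)))
        out <- list()
        for (u in uniq) {
            if (counts[[u]] > 0L) {
                c2 <- counts; c2[[u]] <- c2[[u]] - 1L
                for (tail in rec(remaining[-1L], c2))
                    out[[length(out) + 1L]] <- c(u, tail)
            }
        }
        out
    }
    counts <- as.list(table(labels))
    rec(seq_along(labels), counts)
}

#' @export
print.PermanovaResult <- function(x, ...) {
    cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%s, %d permutations)\n",
                x$pseudoF, x$R2, x$p,
                if (x$exhaustive) "exhaustive" else "sampled", x$nPerm))
    invisible(x)
}
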