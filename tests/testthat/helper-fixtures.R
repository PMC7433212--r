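# Shared in-code fixtures for the test suite.

# Small labelled expression matrix: G genes x (per-cancer tumors + normals).
makeExprFixture <- function(nGenes = 10, cancers = c("C01", "C02"),
                            tumors = 6, normals = 4, seed = 1) {
    set.seed(seed)
    ids <- unlist(lapply(cancers, function(cc)
        c(sprintf("%s_T%d", cc, seq_len(tumors)),
          sprintf("%s_N%d", cc, seq_len(normals)))))
    cancer <- rep(cancers, each = tumors + normals)
    tumor <- rep(c(rep(TRUE, tumors), rep(FALSE, normals)),
                 length(cancers))
    v <- matrix(rnorm(nGenes * length(ids), 8, 1), nGenes, length(ids),
                dimnames = list(sprintf("G%04d", seq_len(nGenes)), ids))
    ExprExperiment(v, cancer = cancer, tumor = tumor)
}

# CNV fixture from an explicit matrix.
makeCnvFixture <- function(values, cancer) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("G%04d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
    CnvExperiment(values, cancer = cancer)
}

# A small cohort spec used across module tests.
smallCohortSpec <- function(seed = 1, ...) {
    args <- list(n_cancers = 5L, tumors_per_cancer = 20L,
                 normals_per_cancer = 6L, n_genes = 60L,
                 planted_lof = sprintf("G%04d", 1:3),
                 planted_gof = sprintf("G%04d", 4:5),
                 n_cancers_affected = 3L, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(cohortSpec, args)
}

# Independent step-up BH implementation (oracle for bhAdjust).
stepUpBh <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    q
}

# Independent Mann-Whitney AUC with ties counted one half.
mannWhitneyAuc <- function(markerCases, markerControls) {
    gt <- outer(markerCases, markerControls, ">")
    eq <- outer(markerCases, markerControls, "==")
    (sum(gt) + 0.5 * sum(eq)) / (length(markerCases) * length(markerControls))
}

# Independent PERMANOVA pseudo-F / R2 from first principles.
bruteForcePermanovaF <- function(d, labels) {
    n <- nrow(d)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + d[i, j]^2
    ssT <- tot / n
    ssW <- 0
    for (lv in unique(labels)) {
        idx <- which(labels == lv)
        s <- 0
        if (length(idx) > 1)
            for (a in seq_along(idx)[-length(idx)])
                for (b in (a + 1):length(idx))
                    s <- s + d[idx[a], idx[b]]^2
        ssW <- ssW + s / length(idx)
    }
    g <- length(unique(labels))
    list(F = ((ssT - ssW) / (g - 1)) / (ssW / (n - g)),
         R2 = (ssT - ssW) / ssT)
}
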