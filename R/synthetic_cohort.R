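#' Specify a synthetic multi-cancer cohort
#'
#' Defines the study conditions a generated cohort emulates: a pan-cancer
#' design with \code{n_cancers} cancer types, per-cancer tumor and non-tumor
#' expression samples, a set of planted recurrently deleted (LoF) and
#' amplified (GoF) genes whose copy-number calls are correlated with additive
#' log2 expression shifts in tumors of the affected cancers, and overall
#' survival drawn from an exponential proportional-hazards model whose
#' log-hazard is linear in the mean expression of the planted LoF set.
#'
#' Defaults describe a cohort of 21 cancer types with 40 tumors and 10
#' non-tumors each over 300 genes, 10 planted LoF genes deleted with
#' probability 0.5 in 10 of the 21 cancers with a -2 log2 expression shift,
#' a mirrored 5-gene GoF set, residual noise SD 0.7 and a 2 percent
#' background alteration rate.
#'
#' @param n_cancers number of cancer types K.
#' @param tumors_per_cancer,normals_per_cancer samples per cancer type.
#' @param n_genes number of genes G (ids \code{G0001} ...).
#' @param planted_lof,planted_gof character vectors of planted gene ids
#'   (must be disjoint subsets of the gene universe).
#' @param p_del,p_amp per-tumor alteration probability of a planted gene in
#'   an affected cancer.
#' @param delta_down,delta_up additive log2 expression shift applied to
#'   tumors of affected cancers (negative for LoF, positive for GoF).
#' @param n_cancers_affected how many of the K cancers carry each planted
#'   alteration.
#' @param background_rate per-cell probability of a non-recurrent noise call.
#' @param deep_fraction fraction of altered calls that are deep (+/-2)
#'   rather than shallow (+/-1).
#' @param expr_sd residual expression noise SD (log2 units).
#' @param beta true log-hazard coefficient per unit of planted-LoF-set mean
#'   score (centered at the cohort mean).
#' @param baseline_hazard exponential event rate at the mean score,
#'   reference stage.
#' @param censor_rate target fraction of censored patients (independent
#'   uniform censoring; 0 disables censoring).
#' @param stage_levels,stage_hr TNM-like stage labels and their hazard
#'   multipliers (first level is the reference).
#' @param seed RNG seed; identical spec + seed gives a byte-identical cohort.
#' @return A list of class \code{"CohortSpec"}.
#' @examples
#' spec <- cohortSpec(n_cancers = 3, tumors_per_cancer = 10,
#'                    normals_per_cancer = 4, n_genes = 50,
#'                    planted_lof = c("G0001", "G0002"), seed = 7)
#' @export
cohortSpec <- function(n_cancers = 21L,
                       tumors_per_cancer = 40L,
                       normals_per_cancer = 10L,
                       n_genes = 300L,
                       planted_lof = sprintf("G%04d", 1:10),
                       planted_gof = sprintf("G%04d", 11:15),
                       p_del = 0.5, p_amp = 0.5,
                       delta_down = -2, delta_up = 2,
                       n_cancers_affected = 10L,
                       background_rate = 0.02,
                       deep_fraction = 0.3,
                       expr_sd = 0.7,
                       beta = log(2),
                       baseline_hazard = 0.1,
                       censor_rate = 0.3,
                       stage_levels = c("I", "II", "III", "IV"),
                       stage_hr = c(1, 1.2, 1.5, 2),
                       seed = 1L) {
    spec <- list(n_cancers = as.integer(n_cancers),
                 tumors_per_cancer = as.integer(tumors_per_cancer),
                 normals_per_cancer = as.integer(normals_per_cancer),
                 n_genes = as.integer(n_genes),
                 planted_lof = as.character(planted_lof),
                 planted_gof = as.character(planted_gof),
                 p_del = p_del, p_amp = p_amp,
                 delta_down = delta_down, delta_up = delta_up,
                 n_cancers_affected = as.integer(n_cancers_affected),
                 background_rate = background_rate,
                 deep_fraction = deep_fraction,
                 expr_sd = expr_sd, beta = beta,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 stage_levels = as.character(stage_levels),
                 stage_hr = as.numeric(stage_hr),
                 seed = as.integer(seed))
    class(spec) <- "CohortSpec"
    validateCohortSpec(spec)
    spec
}

validateCohortSpec <- function(spec) {
    with(spec, {
        if (n_cancers < 1L || n_genes < 1L || tumors_per_cancer < 1L)
            stop("degenerate cohort spec: need >= 1 cancer, gene and tumor per cancer")
        probs <- c(p_del = p_del, p_amp = p_amp,
                   background_rate = background_rate,
                   deep_fraction = deep_fraction, censor_rate = censor_rate)
        bad <- probs < 0 | probs > 1
        if (any(bad))
            stop("probabilities outside [0,1]: ",
                 paste(names(probs)[bad], collapse = ", "))
        if (length(intersect(planted_lof, planted_gof)))
            stop("planted LoF and GoF sets must be disjoint")
        universe <- sprintf("G%04d", seq_len(n_genes))
        if (!all(c(planted_lof, planted_gof) %in% universe))
            stop("planted genes must lie within the G0001..G", n_genes,
                 " universe")
        if (n_cancers_affected > n_cancers)
            stop("n_cancers_affected exceeds the number of cancers")
        if (delta_down > 0 || delta_up < 0)
            stop("delta_down must be <= 0 and delta_up >= 0")
        if (length(stage_hr) != length(stage_levels) || any(stage_hr <= 0))
            stop("stage_hr must be positive, one per stage level")
        if (expr_sd < 0 || baseline_hazard <= 0 || normals_per_cancer < 0)
            stop("expr_sd >= 0, baseline_hazard > 0, normals_per_cancer >= 0 required")
    })
    invisible(spec)
}

# Derived sub-stream seeds keep the three draw blocks (copy number,
# expression, clinical/survival) independent of each other's sizes.
subSeed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)

#' Generate a synthetic multi-cancer cohort
#'
#' Draws thresholded copy-number calls, log2 expression and clinical survival
#' per the \code{\link{cohortSpec}} conditions.  For each planted gene a set
#' of \code{n_cancers_affected} cancers is chosen; within their tumors the
#' gene is altered with probability \code{p_del}/\code{p_amp} (deep with
#' probability \code{deep_fraction}, shallow otherwise) and its expression is
#' shifted by \code{delta_down}/\code{delta_up}.  All other cells receive
#' independent background noise calls at \code{background_rate}.  Survival
#' times are exponential with log-hazard
#' \code{beta * (score - mean(score)) + log(stage multiplier)}, where score is
#' the mean expression of the planted LoF genes over tumor samples, censored
#' by an independent uniform time calibrated to \code{censor_rate}.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' sc <- generateCohort(cohortSpec(n_cancers = 3, tumors_per_cancer = 8,
#'                                 normals_per_cancer = 3, n_genes = 40,
#'                                 planted_lof = "G0001",
#'                                 planted_gof = character(0),
#'                                 n_cancers_affected = 2, seed = 1))
#' sc
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    validateCohortSpec(spec)
    K <- spec$n_cancers
    G <- spec$n_genes
    genes <- sprintf("G%04d", seq_len(G))
    cancers <- sprintf("C%02d", seq_len(K))
    tumorIds <- as.vector(vapply(cancers, function(cc)
        sprintf("%s_T%03d", cc, seq_len(spec$tumors_per_cancer)),
        character(spec$tumors_per_cancer)))
    tumorCancer <- rep(cancers, each = spec$tumors_per_cancer)
    nT <- length(tumorIds)
    if (spec$normals_per_cancer > 0L) {
        normalIds <- as.vector(vapply(cancers, function(cc)
            sprintf("%s_N%03d", cc, seq_len(spec$normals_per_cancer)),
            character(spec$normals_per_cancer)))
        normalCancer <- rep(cancers, each = spec$normals_per_cancer)
    } else {
        normalIds <- character(0); normalCancer <- character(0)
    }

    ## --- stream 1: alteration layout + copy number -------------------------
    set.seed(subSeed(spec$seed, 1L))
    planted <- c(spec$planted_lof, spec$planted_gof)
    affected <- lapply(planted, function(g)
        sort(sample(cancers, spec$n_cancers_affected)))
    names(affected) <- planted

    cnvMat <- matrix(0L, G, nT, dimnames = list(genes, tumorIds))
    if (spec$background_rate > 0) {
        hit <- matrix(runif(G * nT) < spec$background_rate, G, nT)
        n <- sum(hit)
        if (n) {
            sgn <- sample(c(-1L, 1L), n, replace = TRUE)
            mag <- 1L + (runif(n) < spec$deep_fraction)
            cnvMat[hit] <- sgn * mag
        }
    }
    plantCalls <- function(gene, prob, sign) {
        inAff <- tumorCancer %in% affected[[gene]]
        alt <- inAff & runif(nT) < prob
        mag <- 1L + (runif(nT) < spec$deep_fraction)
        cnvMat[gene, alt] <<- sign * mag[alt]
    }
    for (g in spec$planted_lof) plantCalls(g, spec$p_del, -1L)
    for (g in spec$planted_gof) plantCalls(g, spec$p_amp, +1L)

    ## --- stream 2: expression ---------------------------------------------
    set.seed(subSeed(spec$seed, 2L))
    allIds <- c(tumorIds, normalIds)
    allCancer <- c(tumorCancer, normalCancer)
    isTumor <- c(rep(TRUE, nT), rep(FALSE, length(normalIds)))
    baseline <- runif(G, 4, 12)
    exprMat <- baseline +
        matrix(rnorm(G * length(allIds), 0, spec$expr_sd), G, length(allIds))
    dimnames(exprMat) <- list(genes, allIds)
    for (g in spec$planted_lof) {
        sel <- isTumor & allCancer %in% affected[[g]]
        exprMat[g, sel] <- exprMat[g, sel] + spec$delta_down
    }
    for (g in spec$planted_gof) {
        sel <- isTumor & allCancer %in% affected[[g]]
        exprMat[g, sel] <- exprMat[g, sel] + spec$delta_up
    }

    ## --- stream 3: clinical / survival ------------------------------------
    set.seed(subSeed(spec$seed, 3L))
    if (length(spec$planted_lof)) {
        score <- colMeans(exprMat[spec$planted_lof, tumorIds, drop = FALSE])
    } else score <- setNames(numeric(nT), tumorIds)
    stage <- sample(spec$stage_levels, nT, replace = TRUE)
    stageHr <- spec$stage_hr[match(stage, spec$stage_levels)]
    rate <- spec$baseline_hazard *
        exp(spec$beta * (score - mean(score))) * stageHr
    tEvent <- stats::rexp(nT, rate)
    if (spec$censor_rate > 0) {
        cMax <- calibrateCensoring(rate, spec$censor_rate)
        cTime <- runif(nT, 0, cMax)
        time <- pmin(tEvent, cTime)
        event <- as.integer(tEvent <= cTime)
    } else {
        cMax <- Inf
        time <- tEvent
        event <- rep(1L, nT)
    }
    clin <- data.frame(sample = tumorIds, cancer = tumorCancer,
                       time = time, event = event, stage = stage,
                       stringsAsFactors = FALSE)

    new("SyntheticCohort",
        cnv = CnvExperiment(cnvMat, cancer = tumorCancer),
        expr = ExprExperiment(exprMat, cancer = allCancer, tumor = isTumor),
        clinical = clin,
        truth = list(planted_lof = spec$planted_lof,
                     planted_gof = spec$planted_gof,
                     affected_cancers = affected,
                     beta = spec$beta, score = score,
                     censor_max = cMax, spec = spec))
}

# Upper censoring bound c such that P(C < T) hits the target rate, with
# C ~ U(0, c) and T_i ~ Exp(rate_i):  P(C < T) = mean_i (1 - exp(-r_i c))/(r_i c).
calibrateCensoring <- function(rate, target) {
    f <- function(cc) mean((1 - exp(-rate * cc)) / (rate * cc)) - target
    lo <- 1e-8 / mean(rate); hi <- 1e8 / mean(rate)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
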