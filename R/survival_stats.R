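#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function per group over the distinct observed
#' times.  Patients censored exactly at an event time are counted at risk
#' for that time.
#'
#' @param time positive follow-up times, one unit throughout.
#' @param event 0/1 event indicator (1 = death).
#' @param group optional group labels; NULL treats everyone as one group.
#' @return data.frame with columns \code{group}, \code{time}, \code{nRisk},
#'   \code{nEvent}, \code{nCensor}, \code{surv} (right-continuous step
#'   values), one row per distinct observed time per group.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' @export
kmEstimate <- function(time, event, group = NULL) {
    checkSurvival(time, event)
    if (is.null(group)) group <- rep("all", length(time))
    stopifnot(length(group) == length(time))
    res <- lapply(split(seq_along(time), group), function(idx) {
        tt <- time[idx]; ee <- event[idx]
        ut <- sort(unique(tt))
        nRisk <- vapply(ut, function(u) sum(tt >= u), integer(1))
        nEvent <- vapply(ut, function(u) sum(tt == u & ee == 1L), integer(1))
        nCensor <- vapply(ut, function(u) sum(tt == u & ee == 0L), integer(1))
        surv <- cumprod(1 - nEvent / nRisk)
        data.frame(time = ut, nRisk = nRisk, nEvent = nEvent,
                   nCensor = nCensor, surv = surv, row.names = NULL)
    })
    out <- do.call(rbind, Map(function(g, d) cbind(group = g, d),
                              names(res), res))
    rownames(out) <- NULL
    out
}

#' Log-rank (Mantel-Haenszel) test
#'
#' Compares event distributions across two or more groups by summing
#' hypergeometric observed-minus-expected event counts and their
#' (co)variances over the distinct event times; the statistic is referred
#' to a chi-square distribution with groups - 1 degrees of freedom.
#'
#' @inheritParams kmEstimate
#' @param group group labels (>= 2 groups).
#' @return list of class \code{"LogrankResult"}: \code{chisq}, \code{df},
#'   \code{p}, and a per-group table \code{groups} with observed and
#'   expected event counts.
#' @export
logrankTest <- function(time, event, group) {
    checkSurvival(time, event)
    group <- as.character(group)
    stopifnot(length(group) == length(time))
    gl <- sort(unique(group))
    if (length(gl) < 2L) stop("log-rank test needs >= 2 groups")
    if (sum(event) < 1L) stop("log-rank test needs >= 1 event")
    G <- length(gl)
    eventTimes <- sort(unique(time[event == 1L]))
    O <- E <- setNames(numeric(G), gl)
    V <- matrix(0, G, G, dimnames = list(gl, gl))
    for (u in eventTimes) {
        atRisk <- time >= u
        n <- sum(atRisk)
        d <- sum(time == u & event == 1L)
        nj <- vapply(gl, function(g) sum(atRisk & group == g), numeric(1))
        dj <- vapply(gl, function(g)
            sum(time == u & event == 1L & group == g), numeric(1))
        O <- O + dj
        E <- E + d * nj / n
        if (n > 1) {
            f <- d * (n - d) / (n - 1)
            V <- V + f * (diag(nj / n, G) - tcrossprod(nj / n))
        }
    }
    keep <- seq_len(G - 1L)
    omE <- (O - E)[keep]
    Vs <- V[keep, keep, drop = FALSE]
    chisq <- tryCatch(drop(t(omE) %*% solve(Vs, omE)),
                      error = function(e) {
                          drop(t(omE) %*% MASS_ginv(Vs) %*% omE)
                      })
    df <- G - 1L
    structure(list(chisq = chisq, df = df,
                   p = stats::pchisq(chisq, df, lower.tail = FALSE),
                   groups = data.frame(group = gl, observed = as.numeric(O),
                                       expected = as.numeric(E),
                                       row.names = NULL)),
              class = "LogrankResult")
}

# Moore-Penrose inverse via SVD; used when the log-rank variance matrix is
# singular (e.g. a group with no one at risk at any event time).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
    s <- svd(X)
    pos <- s$d > max(tol * s$d[1L], 0)
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with the Efron
#' approximation for tied event times.  Wald confidence intervals are
#' \eqn{\exp(\beta \pm z_{0.975} \cdot SE)}.  Zero-variance or collinear
#' covariates are rejected; non-convergence and monotone-likelihood
#' (separation-like) fits are flagged, never returned silently.
#'
#' @inheritParams kmEstimate
#' @param covariates numeric matrix or data.frame of covariates (factors are
#'   expanded to treatment-coded dummies).
#' @param maxIter,tol Newton-Raphson iteration cap and convergence tolerance
#'   on the log-likelihood change.
#' @return list of class \code{"CoxFit"}: \code{coefficients} (data.frame
#'   with \code{term}, \code{coef}, \code{hr}, \code{se}, \code{ciLower},
#'   \code{ciUpper}, \code{waldP}), \code{loglik} (null and final),
#'   \code{converged}, \code{monotone}, \code{iterations}, \code{n},
#'   \code{nEvents}.
#' @export
coxFit <- function(time, event, covariates, maxIter = 25L, tol = 1e-9) {
    checkSurvival(time, event)
    if (sum(event) < 1L) stop("Cox fit needs >= 1 event")
    X <- buildDesign(covariates)
    stopifnot(nrow(X) == length(time))
    v <- apply(X, 2L, stats::var)
    if (any(v == 0))
        stop("degenerate covariate(s) with zero variance: ",
             paste(colnames(X)[v == 0], collapse = ", "))
    if (qr(X)$rank < ncol(X))
        stop("collinear covariates in Cox design")

    beta <- rep(0, ncol(X))
    ll0 <- coxPartialLoglik(beta, time, event, X)$loglik
    llPrev <- ll0
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        d <- coxPartialLoglik(beta, time, event, X, derivatives = TRUE)
        step <- solve(d$info, d$score)
        # halve the step until the likelihood does not decrease
        for (h in 0:5) {
            cand <- beta + step / 2^h
            llNew <- coxPartialLoglik(cand, time, event, X)$loglik
            if (is.finite(llNew) && llNew >= d$loglik - 1e-12) break
        }
        beta <- cand
        if (abs(llNew - llPrev) < tol * (abs(llPrev) + 1e-8)) {
            converged <- TRUE
            llPrev <- llNew
            break
        }
        llPrev <- llNew
    }
    monotone <- any(abs(beta) > 15)
    if (!converged)
        warning("Cox fit did not converge in ", maxIter, " iterations",
                call. = FALSE)
    if (monotone)
        warning("monotone partial likelihood suspected (|coef| > 15); ",
                "estimates unreliable", call. = FALSE)
    d <- coxPartialLoglik(beta, time, event, X, derivatives = TRUE)
    se <- sqrt(diag(solve(d$info)))
    z <- stats::qnorm(0.975)
    coefs <- data.frame(
        term = colnames(X), coef = beta, hr = exp(beta), se = se,
        ciLower = exp(beta - z * se), ciUpper = exp(beta + z * se),
        waldP = 2 * stats::pnorm(-abs(beta / se)), row.names = NULL)
    structure(list(coefficients = coefs, loglik = c(null = ll0,
                                                    final = llPrev),
                   converged = converged, monotone = monotone,
                   iterations = iter, n = length(time),
                   nEvents = sum(event)),
              class = "CoxFit")
}

buildDesign <- function(covariates) {
    if (is.matrix(covariates)) {
        X <- covariates
        if (is.null(colnames(X)))
            colnames(X) <- paste0("x", seq_len(ncol(X)))
        storage.mode(X) <- "double"
        return(X)
    }
    if (is.numeric(covariates))
        return(matrix(as.double(covariates), ncol = 1L,
                      dimnames = list(NULL, "x")))
    stopifnot(is.data.frame(covariates))
    stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
}

#' Efron partial log-likelihood and derivatives
#'
#' The explicitly coded partial likelihood behind \code{\link{coxFit}},
#' exposed so it can be maximized or audited independently of the
#' Newton-Raphson path.
#'
#' @inheritParams kmEstimate
#' @param beta coefficient vector.
#' @param X design matrix.
#' @param derivatives also return score vector and information matrix.
#' @return list with \code{loglik} and, if requested, \code{score} and
#'   \code{info} (observed information, i.e. negative Hessian).
#' @export
coxPartialLoglik <- function(beta, time, event, X, derivatives = FALSE) {
    p <- ncol(X)
    eta <- drop(X %*% beta)
    w <- exp(eta)
    eventTimes <- sort(unique(time[event == 1L]))
    ll <- 0
    score <- numeric(p)
    info <- matrix(0, p, p)
    for (u in eventTimes) {
        R <- time >= u
        D <- time == u & event == 1L
        d <- sum(D)
        s0R <- sum(w[R]);  s0D <- sum(w[D])
        s1R <- colSums(X[R, , drop = FALSE] * w[R])
        s1D <- colSums(X[D, , drop = FALSE] * w[D])
        ll <- ll + sum(eta[D])
        if (derivatives) {
            score <- score + colSums(X[D, , drop = FALSE])
            s2R <- crossprod(X[R, , drop = FALSE] * sqrt(w[R]))
            s2D <- crossprod(X[D, , drop = FALSE] * sqrt(w[D]))
        }
        for (l in seq_len(d) - 1L) {
            a <- l / d
            denom <- s0R - a * s0D
            ll <- ll - log(denom)
            if (derivatives) {
                zl <- (s1R - a * s1D) / denom
                score <- score - zl
                info <- info + (s2R - a * s2D) / denom - tcrossprod(zl)
            }
        }
    }
    if (derivatives) list(loglik = ll, score = score, info = info)
    else list(loglik = ll)
}

#' Time-dependent ROC curve and AUC at a fixed horizon
#'
#' Cumulative-case / dynamic-control discrimination of a continuous marker
#' for events occurring by \code{horizon}, with inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution: cases (event by the horizon) are weighted by
#' \eqn{1/\hat G(T_i^-)}, controls (followed beyond the horizon) by
#' \eqn{1/\hat G(horizon)}.  The curve follows the higher-marker =
#' higher-risk convention; AUC is the trapezoid area over the
#' marker-threshold sweep.  With no censoring before the horizon this
#' reduces exactly to the Mann-Whitney AUC of marker versus binary
#' by-horizon status.
#'
#' @inheritParams kmEstimate
#' @param marker named or plain numeric risk marker, one value per patient.
#' @param horizon prediction horizon, in the time unit of \code{time}.
#' @return list of class \code{"TdRocResult"}: \code{horizon}, \code{auc},
#'   \code{orientation} ("higher_risk" when AUC >= 0.5, else "lower_risk" —
#'   never silently flipped), \code{curve} (data.frame threshold,
#'   sensitivity, specificity), \code{nCases}, \code{nControls}.
#' @export
tdRocAuc <- function(marker, time, event, horizon) {
    checkSurvival(time, event)
    stopifnot(length(marker) == length(time), is.finite(horizon))
    if (horizon <= min(time) || horizon >= max(time))
        stop("horizon must lie strictly within the observed time range")
    cases <- time <= horizon & event == 1L
    controls <- time > horizon
    if (!any(cases)) stop("no events before the horizon")
    if (!any(controls)) stop("no patients followed beyond the horizon")

    G <- censorKmStep(time, event)
    wCase <- 1 / G(pmax(time[cases] - 1e-12, 0))
    wCtrl <- rep(1 / G(horizon), sum(controls))
    if (any(!is.finite(c(wCase, wCtrl))))
        stop("censoring survival reaches zero before the horizon; ",
             "weights undefined")

    mc <- marker[cases]; mk <- marker[controls]
    thr <- sort(unique(marker))
    sens <- vapply(thr, function(cc) sum(wCase[mc > cc]) / sum(wCase),
                   numeric(1))
    spec <- vapply(thr, function(cc) sum(wCtrl[mk <= cc]) / sum(wCtrl),
                   numeric(1))
    fpr <- c(1, 1 - spec, 0)
    tpr <- c(1, sens, 0)
    auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
               (tpr[-length(tpr)] + tpr[-1L]) / 2)
    structure(list(horizon = horizon, auc = auc,
                   orientation = if (auc >= 0.5) "higher_risk"
                                 else "lower_risk",
                   curve = data.frame(threshold = thr, sensitivity = sens,
                                      specificity = spec),
                   nCases = sum(cases), nControls = sum(controls)),
              class = "TdRocResult")
}

# Step function of the censoring-distribution KM estimate G(t)
# (right-continuous; event indicator flipped).
censorKmStep <- function(time, event) {
    km <- kmEstimate(time, 1L - event)
    drop0 <- km$nEvent > 0
    if (!any(drop0)) return(function(t) rep(1, length(t)))
    stats::stepfun(km$time[drop0], c(1, km$surv[drop0]), right = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.  The p-value uses the
#' t-approximation with n - 2 degrees of freedom; for n <= 9 an exact
#' two-sided permutation p over all n! orderings is computed instead.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list of class \code{"CorrelationResult"}: \code{rho}, \code{p},
#'   \code{n}.
#' @export
spearmanCorr <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 3L) stop("need n >= 3 pairs")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("Spearman correlation undefined for a constant vector")
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= 9L) {
        perms <- allPermutations(n)
        rhoPerm <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
        p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    } else {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), n - 2)
    }
    structure(list(rho = rho, p = min(p, 1), n = n),
              class = "CorrelationResult")
}

allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- allPermutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, sub + (sub >= k))
    }))
}

checkSurvival <- function(time, event) {
    stopifnot(length(time) == length(event))
    if (anyNA(time) || anyNA(event)) stop("missing survival times or events")
    if (any(time <= 0)) stop("survival times must be positive")
    if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
    invisible(TRUE)
}

#' @export
print.CoxFit <- function(x, ...) {
    cat(sprintf("Cox proportional-hazards fit (Efron ties): n = %d, events = %d\n",
                x$n, x$nEvents))
    print(x$coefficients, digits = 4)
    cat(sprintf("loglik: null %.3f -> final %.3f; converged: %s\n",
                x$loglik["null"], x$loglik["final"], x$converged))
    invisible(x)
}

#' @export
print.LogrankResult <- function(x, ...) {
    cat(sprintf("Log-rank test: chisq = %.4f, df = %d, p = %.4g\n",
                x$chisq, x$df, x$p))
    print(x$groups, digits = 4)
    invisible(x)
}
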