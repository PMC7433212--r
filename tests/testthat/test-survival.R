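test_that("product-limit estimate matches hand computation", {
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
    expect_true(all(diff(km$surv) <= 0))

    # all censored: survival stays at 1
    km2 <- kmEstimate(c(1, 2, 3, 4), c(0, 0, 0, 0))
    expect_true(all(km2$surv == 1))

    # mixed 6-patient example, worked by hand:
    # t=1 (d=1,n=6) S=5/6; t=2 censored; t=3 (d=1,n=4) S=5/8;
    # t=4 (d=1,n=3; one censored at 4 still at risk) S=5/12; t=5 (d=1,n=1) S=0
    km3 <- kmEstimate(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 0, 1))
    expect_equal(km3$surv[km3$time == 1], 5 / 6)
    expect_equal(km3$surv[km3$time == 3], 5 / 8)
    expect_equal(km3$surv[km3$time == 4], 5 / 12)
    expect_equal(km3$surv[km3$time == 5], 0)
})

test_that("KM with no censoring equals the empirical survival function", {
    set.seed(71)
    tt <- rexp(40)
    km <- kmEstimate(tt, rep(1, 40))
    expect_equal(km$surv, vapply(km$time, function(u) mean(tt > u),
                                 numeric(1)))
})

test_that("KM agrees with the survival package on censored data", {
    set.seed(72)
    tt <- round(rexp(60, 0.3), 1) + 0.1
    ev <- rbinom(60, 1, 0.7)
    km <- kmEstimate(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    expect_equal(km$surv[km$nEvent > 0],
                 summary(sf, times = km$time[km$nEvent > 0])$surv,
                 tolerance = 1e-12)
})

test_that("log-rank statistic is zero for two identical groups", {
    tt <- c(1, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 1)
    lr <- logrankTest(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
    expect_equal(lr$chisq, 0, tolerance = 1e-12)
    expect_equal(lr$p, 1)
    expect_equal(sum(lr$groups$observed - lr$groups$expected), 0,
                 tolerance = 1e-12)
})

test_that("log-rank matches a hand-computed O-E/variance table", {
    # 8 patients, two groups; independent tally over event times
    tt <- c(1, 2, 3, 4, 2, 3, 5, 6)
    ev <- c(1, 1, 0, 1, 1, 1, 1, 0)
    gr <- rep(c("a", "b"), each = 4)
    lr <- logrankTest(tt, ev, gr)
    o <- e <- v <- 0
    for (u in sort(unique(tt[ev == 1]))) {
        atRisk <- tt >= u
        n <- sum(atRisk); n1 <- sum(atRisk & gr == "a")
        d <- sum(tt == u & ev == 1)
        d1 <- sum(tt == u & ev == 1 & gr == "a")
        o <- o + d1
        e <- e + d * n1 / n
        if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    expect_equal(lr$chisq, (o - e)^2 / v, tolerance = 1e-12)
    expect_equal(lr$groups$observed[lr$groups$group == "a"], o)
    expect_equal(lr$groups$expected[lr$groups$group == "a"], e)
    # and agrees with survival::survdiff
    sd <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank errors on degenerate input", {
    expect_error(logrankTest(1:4, c(1, 1, 0, 1), rep("a", 4)), ">= 2 groups")
    expect_error(logrankTest(1:4, rep(0, 4), rep(c("a", "b"), 2)),
                 ">= 1 event")
})

test_that("Cox coefficient maximizes the partial likelihood (grid oracle)", {
    # 10 patients, binary covariate, no ties
    tt <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.4, 8.8, 9.1, 10.5)
    ev <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
    x <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0)
    fit <- coxFit(tt, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
    # independent likelihood (Breslow = Efron without ties), grid search
    pl <- function(b) {
        ll <- 0
        for (i in which(ev == 1))
            ll <- ll + b * x[i] - log(sum(exp(b * x[tt >= tt[i]])))
        ll
    }
    grid <- seq(-4, 4, by = 1e-4)
    bHat <- grid[which.max(vapply(grid, pl, numeric(1)))]
    expect_equal(fit$coefficients$coef, bHat, tolerance = 1e-4)
    expect_true(fit$converged)
    expect_true(fit$coefficients$ciLower < fit$coefficients$hr &&
                fit$coefficients$hr < fit$coefficients$ciUpper)
})

test_that("Cox with Efron ties agrees with survival::coxph", {
    set.seed(81)
    n <- 120
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    tt <- ceiling(rexp(n, 0.2 * exp(0.6 * x1 - 0.4 * x2)))  # many ties
    ev <- rbinom(n, 1, 0.8)
    fit <- coxFit(tt, ev, cbind(x1 = x1, x2 = x2))
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2,
                           ties = "efron")
    expect_equal(fit$coefficients$coef, unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik[["final"]], ref$loglik[2], tolerance = 1e-8)
})

test_that("Cox rejects degenerate and collinear designs", {
    tt <- 1:10; ev <- rep(1, 10)
    expect_error(coxFit(tt, ev, matrix(1, 10, 1)), "zero variance")
    x <- rnorm(10)
    expect_error(coxFit(tt, ev, cbind(a = x, b = 2 * x)), "collinear")
})

test_that("Cox coefficients are invariant to time rescaling", {
    set.seed(82)
    n <- 80
    x <- rnorm(n)
    tt <- rexp(n, 0.1 * exp(0.5 * x)); ev <- rbinom(n, 1, 0.8)
    f1 <- coxFit(tt, ev, matrix(x, ncol = 1))
    f2 <- coxFit(tt * 365.25, ev, matrix(x, ncol = 1))
    expect_equal(f1$coefficients$coef, f2$coefficients$coef,
                 tolerance = 1e-7)
})

test_that("log-rank direction agrees with the Cox hazard ratio", {
    set.seed(83)
    n <- 200
    grp <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.2 * exp(log(2.5) * grp))
    ev <- rep(1, n)
    lr <- logrankTest(tt, ev, grp)
    fit <- coxFit(tt, ev, matrix(grp, ncol = 1))
    excessDeaths <- with(lr$groups, observed - expected)[
        lr$groups$group == "1"]
    expect_true((fit$coefficients$hr > 1) == (excessDeaths > 0))
})

test_that("td-ROC reduces to the Mann-Whitney AUC without censoring", {
    set.seed(91)
    n <- 150
    marker <- rnorm(n)
    tt <- rexp(n, 0.15 * exp(0.8 * marker))
    ev <- rep(1L, n)
    horizon <- median(tt)
    roc <- tdRocAuc(marker, tt, ev, horizon)
    byH <- tt <= horizon
    expect_equal(roc$auc, mannWhitneyAuc(marker[byH], marker[!byH]),
                 tolerance = 1e-10)
    expect_equal(roc$orientation, "higher_risk")
    # ... and with tied marker values
    marker2 <- round(marker, 1)
    roc2 <- tdRocAuc(marker2, tt, ev, horizon)
    expect_equal(roc2$auc, mannWhitneyAuc(marker2[byH], marker2[!byH]),
                 tolerance = 1e-10)
})

test_that("a perfectly separating marker gives AUC 1", {
    tt <- c(1, 2, 3, 10, 11, 12)
    ev <- rep(1L, 6)
    marker <- c(9, 8, 7, 1, 2, 3)
    expect_equal(tdRocAuc(marker, tt, ev, 5)$auc, 1)
    # protective orientation is reported, not flipped
    expect_equal(tdRocAuc(-marker, tt, ev, 5)$auc, 0)
    expect_equal(tdRocAuc(-marker, tt, ev, 5)$orientation, "lower_risk")
})

test_that("td-ROC validates its preconditions", {
    tt <- c(1, 2, 8, 9); ev <- c(0, 0, 1, 1)
    expect_error(tdRocAuc(rnorm(4), tt, ev, 20), "within the observed")
    expect_error(tdRocAuc(rnorm(4), tt, ev, 5), "no events before")
})

test_that("Spearman rho hits the sign bounds and handles ties", {
    x <- 1:10
    expect_equal(spearmanCorr(x, x^3)$rho, 1)
    expect_equal(spearmanCorr(x, -exp(x / 2))$rho, -1)
    # tied data against the brute-force mid-rank Pearson formula
    xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
    yt <- c(2, 1, 3, 3, 5, 4, 6, 5, 7, 9, 8, 10)
    res <- spearmanCorr(xt, yt)
    rx <- rank(xt); ry <- rank(yt)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(res$rho, oracle, tolerance = 1e-12)
    expect_equal(res$rho, unname(suppressWarnings(
        cor.test(xt, yt, method = "spearman")$estimate)),
        tolerance = 1e-12)
    expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
})

test_that("exact permutation p for small n matches cor.test", {
    set.seed(92)
    x <- rnorm(7); y <- rnorm(7)
    res <- spearmanCorr(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    # large-n t approximation stays in [0, 1] and tracks cor.test
    x2 <- rnorm(60); y2 <- x2 + rnorm(60)
    res2 <- spearmanCorr(x2, y2)
    ref2 <- cor.test(x2, y2, method = "spearman", exact = FALSE)
    expect_equal(res2$p, ref2$p.value, tolerance = 1e-6)
})
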