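test_that("packaged pathway lists have the printed sizes and members", {
    ampk <- ampkScoreSpec()
    expect_length(ampk$genes, 24)
    expect_true(all(c("PRKAA2", "FBP1", "FOXO3", "PFKFB1") %in% ampk$genes))
    expect_true(all(ampk$signs == 1))
    expect_length(pparScoreSpec()$genes, 18)
    mtor <- mtorScoreSpec()
    expect_length(mtor$genes, 6)
    expect_equal(mtor$signs[mtor$genes == "PTEN"], -1)
    expect_equal(sum(mtor$signs), 4)
})

test_that("LoF/GoF calls are the recurrence-DE intersections", {
    del <- data.frame(gene = c("A", "B", "C"), direction = "deletion",
                      nCancersPassing = 8, cancersPassing = "x")
    amp <- data.frame(gene = c("D", "E"), direction = "amplification",
                      nCancersPassing = 8, cancersPassing = "x")
    down <- data.frame(gene = c("A", "B", "Z"), direction = "down",
                       nCancersSignificant = 7, cancers = "x")
    up <- data.frame(gene = c("D", "Q"), direction = "up",
                     nCancersSignificant = 7, cancers = "x")
    call <- callPutativeLofGof(del, amp, down, up)
    expect_setequal(lofGenes(call), c("A", "B"))   # deleted and down
    expect_setequal(gofGenes(call), "D")           # amplified and up
    expect_length(conflictGenes(call), 0)
    # recurrently deleted but not DE -> in neither set
    expect_false("C" %in% c(lofGenes(call), gofGenes(call)))
})

test_that("genes qualifying both ways are excluded and reported", {
    del <- data.frame(gene = "X", direction = "deletion",
                      nCancersPassing = 8, cancersPassing = "x")
    amp <- data.frame(gene = "X", direction = "amplification",
                      nCancersPassing = 8, cancersPassing = "x")
    down <- data.frame(gene = "X", direction = "down",
                       nCancersSignificant = 7, cancers = "x")
    up <- data.frame(gene = "X", direction = "up",
                     nCancersSignificant = 7, cancers = "x")
    expect_warning(call <- callPutativeLofGof(del, amp, down, up),
                   "both LoF and GoF")
    expect_length(lofGenes(call), 0)
    expect_length(gofGenes(call), 0)
    expect_equal(conflictGenes(call), "X")
})

test_that("mean score equals the arithmetic mean over spec genes", {
    v <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("s1", "s2")))
    e <- ExprExperiment(v, cancer = c("C01", "C01"), tumor = c(TRUE, TRUE))
    sp <- scoreSpec("test", c("A", "B", "C"))
    expect_equal(unname(meanExpressionScore(e, sp)), c(3, 4))
    # one-gene spec is the gene itself
    expect_equal(unname(meanExpressionScore(e, scoreSpec("one", "B"))),
                 c(3, 4))
    # gene-order invariance
    expect_equal(meanExpressionScore(e, scoreSpec("r", c("C", "A", "B"))),
                 meanExpressionScore(e, sp))
})

test_that("mean score matches a brute-force mean on random data", {
    set.seed(51)
    e <- makeExprFixture(nGenes = 30, cancers = "C01", tumors = 12,
                         normals = 0)
    genes <- sprintf("G%04d", sample(30, 9))
    sc <- meanExpressionScore(e, scoreSpec("rand", genes))
    v <- SummarizedExperiment::assay(e, "expr")
    for (s in names(sc)) {
        acc <- 0
        for (g in genes) acc <- acc + v[g, s]
        expect_equal(unname(sc[s]), acc / length(genes))
    }
    # linearity: shifting expression by c shifts the score by c
    e2 <- ExprExperiment(v + 1.5, cancer = cancerOf(e),
                         tumor = tumorFlag(e))
    expect_equal(meanExpressionScore(e2, scoreSpec("rand", genes)),
                 sc + 1.5)
})

test_that("composite score is the signed sum with PTEN-style negation", {
    genes <- c("AKT1", "MTOR", "GSK3B", "RPS6KB1", "RPS6", "PTEN")
    v <- matrix(1, 6, 2, dimnames = list(genes, c("s1", "s2")))
    e <- ExprExperiment(v, cancer = c("C01", "C01"), tumor = c(TRUE, TRUE))
    sp <- mtorScoreSpec()
    expect_equal(unname(compositeScore(e, sp)), c(4, 4))
    v2 <- v; v2["PTEN", "s1"] <- 2
    e2 <- ExprExperiment(v2, cancer = c("C01", "C01"),
                         tumor = c(TRUE, TRUE))
    expect_equal(unname(compositeScore(e2, sp)), c(3, 4))
    # missing gene errors by name
    e3 <- ExprExperiment(v[-6, , drop = FALSE], cancer = c("C01", "C01"),
                         tumor = c(TRUE, TRUE))
    expect_error(compositeScore(e3, sp), "PTEN")
})

test_that("composite score matches a brute-force signed sum", {
    set.seed(52)
    genes <- c("AKT1", "MTOR", "GSK3B", "RPS6KB1", "RPS6", "PTEN")
    v <- matrix(rnorm(6 * 8, 8, 2), 6, 8,
                dimnames = list(genes, sprintf("s%d", 1:8)))
    e <- ExprExperiment(v, cancer = rep("C01", 8), tumor = rep(TRUE, 8))
    sp <- mtorScoreSpec()
    sc <- compositeScore(e, sp)
    for (s in colnames(v)) {
        acc <- 0
        for (i in seq_along(sp$genes))
            acc <- acc + sp$signs[i] * v[sp$genes[i], s]
        expect_equal(unname(sc[s]), acc)
    }
})

test_that("quartile stratification bins by interpolated cutoffs, ties down", {
    sc <- setNames(as.numeric(1:8), sprintf("s%d", 1:8))
    st <- stratifyByQuantile(sc, 4)
    expect_setequal(st$sample[st$label == "Q1"], c("s1", "s2"))
    expect_setequal(st$sample[st$label == "Q4"], c("s7", "s8"))
    # values exactly on the median cutoff (4) go to the lower bin (Q2)
    sc2 <- setNames(c(1, 2, 3, 4, 4, 5, 6, 7), sprintf("t%d", 1:8))
    st2 <- stratifyByQuantile(sc2, 4)
    expect_equal(unname(attr(st2, "cutoffs")[2]), 4)
    expect_equal(st2$label[sc2[st2$sample] == 4], c("Q2", "Q2"))
    expect_error(stratifyByQuantile(setNames(rep(1, 5), 1:5), 4),
                 "distinct")
})

test_that("quartile bin sizes differ by at most one for distinct values", {
    set.seed(61)
    for (n in c(8, 13, 40, 101)) {
        sc <- setNames(rnorm(n), sprintf("s%d", 1:n))
        tab <- table(stratifyByQuantile(sc, 4)$label)
        expect_lte(max(tab) - min(tab), 1)
        expect_equal(sum(tab), n)
    }
})

test_that("stratification is invariant to monotone score transforms", {
    set.seed(62)
    sc <- setNames(rnorm(23), sprintf("s%d", 1:23))
    a <- stratifyByQuantile(sc, 4)
    b <- stratifyByQuantile(exp(sc) + 2, 4)
    expect_equal(a$label, b$label)
})

test_that("median-pair quadrants dichotomize both scores", {
    a <- setNames(c(1, 1, 3, 3), sprintf("s%d", 1:4))
    b <- setNames(c(1, 3, 1, 3), sprintf("s%d", 1:4))
    st <- stratifyByMedianPairs(a, b)
    expect_setequal(st$label, c("low-low", "low-high", "high-low",
                                "high-high"))
    # perfect dependence occupies only the diagonal quadrants
    st2 <- stratifyByMedianPairs(a, a)
    expect_setequal(unique(st2$label), c("low-low", "high-high"))
    expect_error(stratifyByMedianPairs(setNames(rep(1, 4), names(a)), b),
                 "constant")
})

test_that("quadrant counts match brute-force double dichotomization", {
    set.seed(63)
    n <- 57
    a <- setNames(rnorm(n), sprintf("s%d", 1:n))
    b <- setNames(rnorm(n), sprintf("s%d", 1:n))
    st <- stratifyByMedianPairs(a, b)
    ma <- median(a); mb <- median(b)
    want <- paste(ifelse(a > ma, "high", "low"),
                  ifelse(b > mb, "high", "low"), sep = "-")
    expect_equal(st$label[match(names(a), st$sample)], unname(want))
})

test_that("planted LoF and GoF sets are recovered end to end", {
    hits <- 0
    for (seed in 1:5) {
        sc <- generateCohort(smallCohortSpec(seed = seed))
        fr <- alterationFractions(cnv(sc))
        del <- recurrentGenes(fr, "deletion", minCancers = 2)
        amp <- recurrentGenes(fr, "amplification", minCancers = 2)
        de <- suppressWarnings(deTestPerCancer(expr(sc)))
        rde <- recurrentDeGenes(de, 2)
        call <- callPutativeLofGof(
            del, amp, rde[rde$direction == "down", ],
            rde[rde$direction == "up", ])
        truth <- cohortTruth(sc)
        ok <- setequal(lofGenes(call), truth$planted_lof) &&
            setequal(gofGenes(call), truth$planted_gof) &&
            length(conflictGenes(call)) == 0
        hits <- hits + ok
    }
    expect_gte(hits, 4)
})
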