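test_that("normalization fixes identical and proportional libraries", {
    su <- smallScreenSetup(seed = 7)
    nS <- length(taSites(su$ta))
    set.seed(4)
    base <- rpois(nS, 20)
    a <- manualCounts(su$ta, base)
    # identical libraries: factors (1, 1), output equals input
    nrm <- normalizeLibraries(a, a)
    expect_equal(unname(nrm$scaleFactors), c(1, 1))
    expect_equal(nrm$ref@counts, a@counts)
    # test = 2 x ref sitewise: factors (4/3, 2/3) equalize the totals
    b <- manualCounts(su$ta, 2 * base)
    nrm <- normalizeLibraries(a, b)
    expect_equal(unname(nrm$scaleFactors), c(4 / 3, 2 / 3))
    expect_equal(sum(nrm$ref@counts), sum(nrm$test@counts))
    # zero-read library is an error
    z <- manualCounts(su$ta, numeric(nS))
    expect_error(normalizeLibraries(a, z), "zero mapped reads")
})

test_that("winsorization bounds a jackpot site's influence (10-site toy)", {
    # ref has a jackpot holding >90% of its reads; test is flat.
    # Hand calculation with winsorFraction = 0.1:
    #   ref nonzero counts (1 x9, 100): type-7 quantile at 0.9 is
    #     1 + 0.1 * (100 - 1) = 10.9, winsorized total 9 + 10.9 = 19.9
    #   test total 10 (threshold 1, unchanged)
    #   harmonic target 2/(1/19.9 + 1/10) = 398/29.9
    #   factors: ref (398/29.9)/19.9 = 20/29.9, test (398/29.9)/10 = 39.8/29.9
    ta <- new("TASiteIndex", sites = as.integer(seq(10, 100, by = 10)),
              geneId = rep(".", 10), circular = FALSE,
              genomeLength = 200L)
    ref <- manualCounts(ta, c(100, rep(1, 9)))
    test <- manualCounts(ta, rep(1, 10))
    nrm <- normalizeLibraries(ref, test, winsorFraction = 0.1)
    expect_equal(unname(nrm$scaleFactors), c(20 / 29.9, 39.8 / 29.9))
    # without winsorization the jackpot would inflate the ref factor's
    # denominator from 19.9 to 109
    nrm0 <- normalizeLibraries(ref, test, winsorFraction = 0)
    expect_lt(nrm0$scaleFactors[["ref"]], nrm$scaleFactors[["ref"]])
})

test_that("fold reduction is pseudocounted ratio of totals", {
    # a top-hit scale: 216.7 vs 9.0 gives (216.7+1)/(9+1) = 21.77
    expect_equal(geneFoldReduction(216.7, 9), 21.77)
    expect_equal(geneFoldReduction(50, 50), 1)
    expect_equal(geneFoldReduction(0, 0), 1)
    expect_equal(geneFoldReduction(99, 0), 100)
})

test_that("Mann-Whitney U and exact p match the worked examples", {
    # all y above all x: U = 9; y is stochastically larger
    r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "less")
    expect_equal(r$U, 9)
    expect_equal(r$p, 1)
    expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "greater")$p, 1 / 20)
    # mirrored: U = 0, one-sided exact p = 1/20
    r <- mannWhitneyU(c(4, 5, 6), c(1, 2, 3), "less")
    expect_equal(r$U, 0)
    expect_equal(r$p, 1 / 20)
    # full tie: U = n*m/2, two-sided p = 1
    r <- mannWhitneyU(c(5, 5), c(5, 5), "two_sided")
    expect_equal(r$U, 2)
    expect_equal(r$p, 1)
    expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("U + U' = n*m and exact p agrees with wilcox.test without ties", {
    set.seed(8)
    for (k in 1:200) {
        n <- sample(1:8, 1); m <- sample(1:8, 1)
        x <- sample(0:30, n, TRUE); y <- sample(0:30, m, TRUE)
        u1 <- mannWhitneyU(x, y)$U
        u2 <- mannWhitneyU(y, x)$U
        expect_equal(u1 + u2, n * m)
    }
    for (k in 1:100) {
        n <- sample(2:6, 1); m <- sample(2:6, 1)
        # disjoint supports guarantee no ties, so wilcox.test stays exact
        x <- sample(seq(2, 1000, 2), n); y <- sample(seq(1, 999, 2), m)
        ours <- mannWhitneyU(x, y, "less")
        ref <- suppressWarnings(
            stats::wilcox.test(y, x, alternative = "less", exact = TRUE))
        expect_equal(ours$U, unname(ref$statistic))
        expect_equal(ours$p, ref$p.value)
    }
})

test_that("normal approximation is close to exact near the cutover", {
    set.seed(15)
    for (k in 1:50) {
        x <- rpois(7, 8); y <- rpois(7, 8)
        pe <- mannWhitneyU(x, y, "less", exactLimit = 14)$p
        pa <- mannWhitneyU(x, y, "less", exactLimit = 0)$p
        expect_lt(abs(pe - pa), 0.05)
    }
})

test_that("lowering test counts never helps a gene look represented", {
    set.seed(12)
    for (k in 1:100) {
        nS <- sample(3:12, 1)
        x <- rpois(nS, 20)
        y <- rpois(nS, 20)
        drop <- sample(0:3, nS, TRUE)
        y2 <- pmax(y - drop, 0)
        expect_gte(geneFoldReduction(sum(x), sum(y2)),
                   geneFoldReduction(sum(x), sum(y)))
        p1 <- mannWhitneyU(x, y, "less")$p
        p2 <- mannWhitneyU(x, y2, "less")$p
        expect_lte(p2, p1 + 1e-12)
    }
})

test_that("screen results carry consistent per-gene statistics", {
    su <- smallScreenSetup(seed = 7)
    nS <- length(taSites(su$ta))
    set.seed(5)
    ref <- manualCounts(su$ta, rpois(nS, 30), "WT")
    test <- manualCounts(su$ta, rpois(nS, 30), "mutant")
    # silence one gene in the test library: it must rank first
    gid <- S4Vectors::mcols(genomeGenes(su$genome))$gene_id
    hit <- siteGenes(su$ta) == gid[4]
    test@counts[hit] <- 0
    test@nMapped <- sum(test@counts)
    res <- analyzeScreen(ref, test, su$genome, su$ta)
    expect_identical(res$gene_id[1], gid[4])
    expect_lt(res$q[1], 0.05)
    # U bounds and BH monotonicity after the step-up
    expect_true(all(res$U >= 0 & res$U <= res$n_sites^2))
    expect_true(all(res$q >= res$p - 1e-12))
    byP <- res[order(res$p), ]
    expect_true(all(diff(byP$q) >= -1e-12))
    # a gene absent from both libraries is a clean null row
    ref0 <- ref; ref0@counts[hit] <- 0; ref0@nMapped <- sum(ref0@counts)
    res0 <- analyzeScreen(ref0, test, su$genome, su$ta)
    row <- res0[res0$gene_id == gid[4], ]
    expect_equal(row$fold_reduction, 1)
    expect_equal(row$p, 1)
    # disjoint TA indices are rejected
    ta2 <- new("TASiteIndex", sites = taSites(su$ta) + 1L,
               geneId = siteGenes(su$ta), circular = TRUE,
               genomeLength = su$ta@genomeLength + 1L)
    bad <- manualCounts(ta2, rpois(nS, 30))
    expect_error(analyzeScreen(ref, bad, su$genome, su$ta), "disjoint")
})

test_that("planted hit with deep coverage lands in the top decile", {
    su <- smallScreenSetup(len = 40000, nGenes = 25, seed = 17,
                           nConditional = 1, conditionalRatio = 100)
    fm <- su$fitness
    planted <- plantedGenes(fm)
    expect_length(planted, 1L)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    runBg <- function(bg, s1) {
        t0 <- buildLibrary(su$ta, fm, bg, 50000, seed = s1)
        t30 <- applySelection(t0, fm, su$ta, 50000, seed = s1 + 1)
        sim <- simulateReads(t30, su$genome, su$ta, 300000, seed = s1 + 2)
        mapReads(sim$reads, idx, bg, "T30")
    }
    res <- analyzeScreen(runBg("WT", 100), runBg("mutant", 200),
                         su$genome, su$ta)
    r <- which(res$gene_id == planted)
    expect_lte(r, ceiling(nrow(res) / 10))
    expect_lt(res$q[r], 0.05)
})

test_that("recovery report equals a hand tabulation on a toy screen", {
    su <- smallScreenSetup(len = 30000, nGenes = 20, seed = 23,
                           nConditional = 4)
    fm <- su$fitness
    gid <- fm@geneId
    planted <- plantedGenes(fm)
    # fabricate a results table: 3 of 4 planted called, plus 1 neutral call
    neutral <- setdiff(gid, planted)
    q <- stats::setNames(rep(0.5, 20), gid)
    q[planted[1:3]] <- 0.001
    q[neutral[1]] <- 0.01
    res <- data.frame(gene_id = gid, name = gid, n_sites = 10,
                      total_ref = 100, total_test = 50,
                      fold_reduction = 2 - q[gid], U = 50,
                      p = q[gid], q = q[gid])
    res <- res[order(-res$fold_reduction), ]
    rep <- recoveryReport(res, fm, alpha = 0.05)
    expect_identical(rep$summary$n_planted, 4L)
    expect_identical(rep$summary$true_positives, 3L)
    expect_identical(rep$summary$false_positives, 1L)
    expect_identical(rep$summary$false_negatives, 1L)
    expect_equal(rep$summary$recall, 0.75)
    expect_identical(sum(rep$table$called), 4L)
})

test_that("results TSV and volcano table are written coherently", {
    d <- withr::local_tempdir()
    su <- smallScreenSetup(seed = 7)
    nS <- length(taSites(su$ta))
    set.seed(6)
    ref <- manualCounts(su$ta, rpois(nS, 25), "WT")
    test <- manualCounts(su$ta, rpois(nS, 25), "mutant")
    res <- analyzeScreen(ref, test, su$genome, su$ta)
    p1 <- file.path(d, "res.tsv"); p2 <- file.path(d, "vol.tsv")
    writeScreenResults(res, p1, volcanoPath = p2, header = "seed=7")
    back <- utils::read.table(p1, header = TRUE, sep = "\t",
                              comment.char = "#")
    expect_identical(nrow(back), nrow(res))
    vol <- utils::read.table(p2, header = TRUE, sep = "\t")
    expect_equal(vol$log2_fold_reduction, log2(res$fold_reduction))
    expect_equal(vol$neg_log10_p, -log10(res$p))
})
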