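test_that("tag index is collision-free on a random genome at length 16", {
    su <- smallScreenSetup(seed = 7)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    expect_length(idx@ambiguous, 0L)
    expect_false(anyDuplicated(idx@tags) > 0)
    # circular genome: every site usable, two candidate tags each
    expect_identical(length(idx@tags), 2L * length(taSites(su$ta)))
})

test_that("a constructed 16-mer repeat makes its tag ambiguous", {
    tag <- "ACGCGGCCGGCCAGGC"  # 16 bp, contains no TA
    set.seed(1)
    filler <- function(n) paste(sample(c("A", "C", "G"), n, TRUE),
                                collapse = "")
    seqStr <- paste0(filler(400), tag, "TA", filler(400), tag, "TA",
                     filler(400))
    g <- toyGenome(seqStr, circular = TRUE)
    ta <- findTASites(g)
    idx <- buildTagIndex(g, ta, 16)
    expect_true(tag %in% idx@ambiguous)
    expect_false(tag %in% idx@tags)
})

test_that("short tags collide by pigeonhole, matching brute-force counts", {
    su <- smallScreenSetup(len = 12000, nGenes = 6, seed = 9)
    idx <- buildTagIndex(su$genome, su$ta, 10)
    # independent brute-force enumeration of candidate (tag, site) pairs
    seqStr <- as.character(genomeSequence(su$genome))
    big <- paste0(seqStr, seqStr)
    L <- nchar(seqStr)
    p <- taSites(su$ta)
    rc <- function(s) chartr("ACGT", "TGCA",
                             vapply(strsplit(s, ""), function(v)
                                 paste(rev(v), collapse = ""), ""))
    cand <- unique(data.frame(
        tag = c(substring(big, p - 10 + L, p - 1 + L),
                rc(substring(big, p + 2, p + 11))),
        site = c(p, p)))
    tb <- table(cand$tag)
    expAmb <- sort(names(tb)[tb > 1])
    expect_gt(length(expAmb), 0L)
    expect_identical(sort(idx@ambiguous), expAmb)
    expect_identical(sort(idx@tags), sort(names(tb)[tb == 1]))
})

test_that("error-free mapping reproduces the simulator truth exactly", {
    su <- smallScreenSetup(seed = 7)
    lib <- buildLibrary(su$ta, su$fitness, "WT", 20000, seed = 1)
    t30 <- applySelection(lib, su$fitness, su$ta, 20000, seed = 2)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    sim <- simulateReads(t30, su$genome, su$ta, depth = 50000, seed = 3)
    sc <- mapReads(sim$reads, idx, "WT", "T30")
    truthHist <- as.numeric(table(factor(sim$truth$site,
                                         levels = taSites(su$ta))))
    expect_identical(sc@counts, truthHist)
    acc <- readAccounting(sc)
    expect_identical(acc$n_total, 50000)
    expect_identical(acc$n_unmapped + acc$n_ambiguous, 0)
})

test_that("unmappable and ambiguous reads are accounted, never assigned", {
    su <- smallScreenSetup(seed = 7)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    reads <- c(strrep("N", 16), "ACGT", idx@tags[1])
    sc <- mapReads(reads, idx)
    acc <- readAccounting(sc)
    expect_identical(acc$n_mapped, 1)
    expect_identical(acc$n_unmapped, 2)  # all-N read and too-short read
    expect_identical(acc$n_total, 3)
    expect_identical(sum(sc@counts), 1)
})

test_that("read accounting conserves on random FASTQ-like input", {
    su <- smallScreenSetup(seed = 7)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    set.seed(10)
    for (k in 1:10) {
        n <- sample(50:200, 1)
        reads <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T", "N"), sample(10:30, 1),
                         TRUE), collapse = ""), "")
        reads <- c(reads, sample(idx@tags, 20))
        acc <- readAccounting(mapReads(reads, idx))
        expect_equal(acc$n_total, length(reads))
        expect_identical(acc$n_mapped, sum(mapReads(reads, idx)@counts))
    }
})

test_that("malformed FASTQ reports the offending record", {
    d <- withr::local_tempdir()
    fq <- file.path(d, "bad.fq")
    writeLines(c("@r1", "ACGT", "+", "IIII",
                 "r2-missing-at", "ACGT", "+", "IIII"), fq)
    su <- smallScreenSetup(seed = 7)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    expect_error(mapReads(fq, idx), "record 2")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2"), fq)
    expect_error(mapReads(fq, idx), "multiple of 4")
})

test_that("FASTQ round trip through file matches in-memory mapping", {
    d <- withr::local_tempdir()
    su <- smallScreenSetup(seed = 7)
    lib <- buildLibrary(su$ta, su$fitness, "WT", 10000, seed = 1)
    t30 <- applySelection(lib, su$fitness, su$ta, 10000, seed = 2)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    fq <- file.path(d, "lib.fq")
    sim <- simulateReads(t30, su$genome, su$ta, depth = 5000, seed = 3,
                         fastqPath = fq)
    scMem <- mapReads(sim$reads, idx)
    scFile <- mapReads(fq, idx)
    expect_identical(scFile@counts, scMem@counts)
})

test_that("exact matching maps ~0.99^16 of reads at 1% error", {
    su <- smallScreenSetup(seed = 7)
    lib <- buildLibrary(su$ta, su$fitness, "WT", 20000, seed = 1)
    t30 <- applySelection(lib, su$fitness, su$ta, 20000, seed = 2)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    D <- 10000L
    sim <- simulateReads(t30, su$genome, su$ta, depth = D,
                         errorRate = 0.01, seed = 5)
    acc <- readAccounting(mapReads(sim$reads, idx))
    p <- 0.99^16
    expect_lt(abs(acc$n_mapped / D - p), 5 * sqrt(p * (1 - p) / D))
})

test_that("WIG round trips losslessly and deterministically", {
    d <- withr::local_tempdir()
    su <- smallScreenSetup(seed = 7)
    lib <- buildLibrary(su$ta, su$fitness, "WT", 10000, seed = 1)
    t30 <- applySelection(lib, su$fitness, su$ta, 10000, seed = 2)
    idx <- buildTagIndex(su$genome, su$ta, 16)
    sim <- simulateReads(t30, su$genome, su$ta, depth = 20000, seed = 3)
    sc <- mapReads(sim$reads, idx, "WT", "T30")
    w1 <- file.path(d, "a.wig"); w2 <- file.path(d, "b.wig")
    writeWig(sc, w1)
    sc2 <- readWig(w1, su$ta)
    expect_identical(sc2@counts, sc@counts)
    expect_identical(sc2@background, "WT")
    expect_identical(sc2@timepoint, "T30")
    expect_identical(readAccounting(sc2), readAccounting(sc))
    # byte-identical across repeated runs of the same seed
    sim2 <- simulateReads(t30, su$genome, su$ta, depth = 20000, seed = 3)
    writeWig(mapReads(sim2$reads, idx, "WT", "T30"), w2)
    expect_identical(readLines(w1), readLines(w2))
})

test_that("empty library yields a header-only WIG; bad positions error", {
    d <- withr::local_tempdir()
    su <- smallScreenSetup(seed = 7)
    empty <- manualCounts(su$ta, numeric(length(taSites(su$ta))))
    w <- file.path(d, "empty.wig")
    writeWig(empty, w)
    lines <- readLines(w)
    expect_length(lines, 2L)  # metadata comment + variableStep declaration
    expect_identical(readWig(w, su$ta)@counts, empty@counts)
    # a position absent from the TA index is rejected by line
    bad <- file.path(d, "bad.wig")
    nonSite <- setdiff(seq_len(20000), taSites(su$ta))[1]
    writeLines(c("variableStep chrom=toy span=1",
                 paste(nonSite, 5)), bad)
    expect_error(readWig(bad, su$ta), "line 2.*not a TA site")
})
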