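# Shared in-code fixtures: everything is generated at test time.

# A toy genome from an explicit sequence (no annotation unless given).
toyGenome <- function(sequence, circular = FALSE, genes = NULL, id = "toy") {
    if (is.null(genes)) genes <- GenomicRanges::GRanges()
    TnGenome(id, sequence, circular = circular, genes = genes)
}

# A small synthetic genome + TA index, sized for fast unit tests.
smallScreenSetup <- function(len = 20000, nGenes = 12, seed = 7,
                             circular = TRUE, ...) {
    g <- generateGenome(len, nGenes, c(600L, 1200L), seed = seed,
                        circular = circular)
    ta <- findTASites(g)
    fm <- fitnessModel(g, seed = seed + 1L, ...)
    list(genome = g, ta = ta, fitness = fm)
}

# Independent quadratic-scan oracle for TA sites (1-based T coordinate).
naiveTAScan <- function(sequence, circular) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    L <- length(chars)
    sites <- integer(0)
    for (i in seq_len(L)) {
        nxt <- if (i < L) i + 1L else if (circular) 1L else NA_integer_
        if (!is.na(nxt) && chars[i] == "T" && chars[nxt] == "A")
            sites <- c(sites, i)
    }
    sites
}

# Independent pair-counting Mann-Whitney U (statistic for sample y).
bruteForceU <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y)
        u <- u + (xi < yj) + 0.5 * (xi == yj)
    u
}

# Independent exact p by full enumeration of all choose(n+m, m) splits of
# the combined multiset, with pair counting per split (no ranks).
enumeratedP <- function(x, y, alternative) {
    comb <- c(x, y)
    N <- length(comb)
    m <- length(y)
    sets <- utils::combn(N, m)
    uObs <- bruteForceU(x, y)
    uAll <- apply(sets, 2L, function(j)
        bruteForceU(comb[-j], comb[j]))
    eps <- 1e-9
    pl <- mean(uAll <= uObs + eps)
    pg <- mean(uAll >= uObs - eps)
    switch(alternative,
           less = pl, greater = pg,
           two_sided = min(1, 2 * min(pl, pg)))
}

# Build a SiteCounts by hand over a TA index.
manualCounts <- function(ta, counts, background = "bg", timepoint = "T30",
                         seqname = "toy") {
    new("SiteCounts", background = background, timepoint = timepoint,
        seqname = seqname, sites = taSites(ta), counts = as.numeric(counts),
        nMapped = sum(counts), nUnmapped = 0, nAmbiguous = 0)
}
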