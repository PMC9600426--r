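# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else suppressWarnings(rm(".Random.seed", envir = genv))
    }, add = TRUE)
    set.seed(as.integer(seed))
    force(expr)
}

# Vectorized reverse complement of plain character DNA strings.
revComp <- function(x) {
    if (!length(x)) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Map each TA site to a per-site fitness parameter ("w" or "s") for one
# background: gene sites take the gene's value, intergenic sites the default
# (w = 1, s = background baseline).
siteFitness <- function(ta, fitness, background, what = c("w", "s")) {
    what <- match.arg(what)
    if (!background %in% fitness@backgrounds)
        stop("background '", background, "' unknown to the fitness model")
    vals <- slot(fitness, what)[, background]
    names(vals) <- fitness@geneId
    default <- if (what == "w") 1 else fitness@baselineS[[background]]
    out <- rep(default, length(ta@sites))
    hit <- ta@geneId != "."
    idx <- match(ta@geneId[hit], fitness@geneId)
    if (anyNA(idx))
        stop("TA index names genes absent from the fitness model")
    out[hit] <- vals[idx]
    out
}
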