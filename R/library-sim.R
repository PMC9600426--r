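#' Simulate transposon library construction (T0)
#'
#' Each of \code{nTransformants} transformants receives an insertion at a TA
#' site drawn uniformly over the genome's TA index, then survives outgrowth
#' and colony formation with probability \code{w} of the containing gene
#' (intergenic insertions always survive). Survivors form the frozen T0
#' library pool.
#'
#' @param ta a [TASiteIndex-class].
#' @param fitness a [FitnessModel-class] defining \code{w} per gene.
#' @param background background label, must be known to \code{fitness}.
#' @param nTransformants number of transformants (the study pooled
#'   approximately 750,000; desk-scale default 50,000).
#' @param seed integer RNG seed.
#'
#' @return An [InsertionLibrary-class] at timepoint \code{"T0"};
#'   \code{totalClones} is the number of surviving transformants.
#' @examples
#' g <- generateGenome(50000, 30, seed = 7)
#' ta <- findTASites(g)
#' fm <- fitnessModel(g, nConditional = 3, seed = 1)
#' lib <- buildLibrary(ta, fm, "WT", 5000, seed = 2)
#' lib
#' @export
buildLibrary <- function(ta, fitness, background, nTransformants = 50000L,
                         seed = 1L) {
    stopifnot(is(ta, "TASiteIndex"), is(fitness, "FitnessModel"))
    nTransformants <- as.integer(nTransformants)
    if (nTransformants < 1L) stop("'nTransformants' must be >= 1")
    nS <- length(ta@sites)
    if (nS == 0L) stop("TA index is empty")
    w <- siteFitness(ta, fitness, background, "w")
    withSeed(seed, {
        hits <- as.vector(stats::rmultinom(1L, nTransformants, rep(1, nS)))
        surv <- stats::rbinom(nS, hits, w)
        new("InsertionLibrary", background = background, timepoint = "T0",
            sites = ta@sites, abundance = as.integer(surv),
            totalClones = as.integer(sum(surv)))
    })
}

#' Simulate sporulation, heat-kill selection and germination pooling (T30)
#'
#' Two-stage sampling: (1) each clone independently survives sporulation,
#' the 80 degC / 20 min heat kill and germination with probability \code{s}
#' of its gene (binomial thinning per site); (2) a fixed number of colonies
#' is pooled from the germinated survivors (multinomial resampling with
#' probabilities proportional to the thinned counts - the pooling
#' bottleneck).
#'
#' @param lib an [InsertionLibrary-class] at timepoint \code{"T0"}.
#' @param fitness a [FitnessModel-class] defining \code{s} per gene.
#' @param ta the [TASiteIndex-class] the library was built on (for per-site
#'   gene lookup).
#' @param nColoniesPooled number of germinated colonies pooled (the study
#'   pooled approximately 750,000; desk-scale default 50,000).
#' @param seed integer RNG seed.
#'
#' @return An [InsertionLibrary-class] at timepoint \code{"T30"} with
#'   \code{totalClones == nColoniesPooled}.
#' @export
applySelection <- function(lib, fitness, ta, nColoniesPooled = 50000L,
                           seed = 1L) {
    stopifnot(is(lib, "InsertionLibrary"), is(fitness, "FitnessModel"),
              is(ta, "TASiteIndex"))
    if (lib@timepoint != "T0")
        stop("selection must be applied to a T0 library")
    if (!identical(lib@sites, ta@sites))
        stop("library and TA index disagree on sites")
    nColoniesPooled <- as.integer(nColoniesPooled)
    s <- siteFitness(ta, fitness, lib@background, "s")
    withSeed(seed, {
        thinned <- stats::rbinom(length(lib@abundance), lib@abundance, s)
        if (sum(thinned) == 0L)
            stop("selection extinguished library: no clones survived ",
                 "sporulation selection (s parameters too harsh for the ",
                 "library size)")
        pooled <- as.vector(stats::rmultinom(1L, nColoniesPooled, thinned))
        new("InsertionLibrary", background = lib@background,
            timepoint = "T30", sites = lib@sites,
            abundance = as.integer(pooled),
            totalClones = as.integer(sum(pooled)))
    })
}
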