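#' Build a per-gene fitness model (the planted truth)
#'
#' Assigns every gene of the genome a role and the corresponding vegetative
#' (\code{w}) and sporulation (\code{s}) survival probabilities per genetic
#' background:
#' \itemize{
#'   \item \code{neutral}: \code{w = 1}, \code{s = baselineS} in every
#'     background.
#'   \item \code{essential_vegetative}: \code{w = 0} everywhere - insertion
#'     clones never form colonies, so these genes are empty in every library.
#'   \item \code{sporulation_factor} (the planted conditional essentials):
#'     \code{w = 1}; \code{s = baselineS} in the reference background but
#'     \code{baselineS / conditionalRatio} in \code{conditionalBackground},
#'     emulating genes whose disruption blocks spore formation only in a
#'     sensitized mutant.
#' }
#' Roles are assigned to randomly chosen genes under \code{seed}.
#'
#' @param genes a [GenomicRanges::GRanges] with a \code{gene_id} column, or a
#'   [TnGenome-class].
#' @param backgrounds background labels; the first is the reference.
#' @param baselineS baseline probability that a clone carrying a neutral (or
#'   intergenic) insertion yields a heat-resistant, germinable spore.
#' @param nEssential number of essential_vegetative genes to plant.
#' @param nConditional number of sporulation_factor genes to plant.
#' @param conditionalRatio fold reduction of \code{s} for planted genes in
#'   the sensitized background (>= 1).
#' @param conditionalBackground which background carries the defect; default
#'   the second label.
#' @param seed integer RNG seed for the role assignment.
#'
#' @return A [FitnessModel-class].
#' @examples
#' g <- generateGenome(50000, 30, seed = 7)
#' fm <- fitnessModel(g, nConditional = 3, seed = 1)
#' table(fitnessRoles(fm))
#' @export
fitnessModel <- function(genes, backgrounds = c("WT", "mutant"),
                         baselineS = 0.5, nEssential = 0L,
                         nConditional = 0L, conditionalRatio = 20,
                         conditionalBackground = backgrounds[2],
                         seed = 1L) {
    if (is(genes, "TnGenome")) genes <- genes@genes
    geneId <- S4Vectors::mcols(genes)$gene_id
    ng <- length(geneId)
    if (nEssential + nConditional > ng)
        stop("more planted genes than genes in the annotation")
    if (conditionalRatio < 1)
        stop("'conditionalRatio' must be >= 1")
    if (!conditionalBackground %in% backgrounds)
        stop("'conditionalBackground' must be one of 'backgrounds'")
    role <- rep("neutral", ng)
    withSeed(seed, {
        planted <- sample(ng, nEssential + nConditional)
        if (nEssential > 0L) role[planted[seq_len(nEssential)]] <-
            "essential_vegetative"
        if (nConditional > 0L) role[planted[nEssential + seq_len(nConditional)]] <-
            "sporulation_factor"
    })
    nb <- length(backgrounds)
    w <- matrix(1, ng, nb, dimnames = list(geneId, backgrounds))
    s <- matrix(baselineS, ng, nb, dimnames = list(geneId, backgrounds))
    w[role == "essential_vegetative", ] <- 0
    s[role == "sporulation_factor", conditionalBackground] <-
        baselineS / conditionalRatio
    bs <- rep(baselineS, nb)
    names(bs) <- backgrounds
    new("FitnessModel", backgrounds = backgrounds, geneId = geneId,
        role = role, w = w, s = s, baselineS = bs)
}

#' Accessors for FitnessModel
#'
#' @param fitness a [FitnessModel-class].
#' @param background a background label.
#'
#' @return \code{fitnessRoles}: named character vector of gene roles.
#'   \code{sporulationSurvival} / \code{vegetativeSurvival}: named numeric
#'   vector of per-gene \code{s} / \code{w} for the background.
#'   \code{plantedGenes}: gene ids of the planted sporulation factors.
#' @export
fitnessRoles <- function(fitness) {
    stats::setNames(fitness@role, fitness@geneId)
}

#' @rdname fitnessRoles
#' @export
sporulationSurvival <- function(fitness, background) {
    if (!background %in% fitness@backgrounds)
        stop("background '", background, "' unknown to the fitness model")
    stats::setNames(fitness@s[, background], fitness@geneId)
}

#' @rdname fitnessRoles
#' @export
vegetativeSurvival <- function(fitness, background) {
    if (!background %in% fitness@backgrounds)
        stop("background '", background, "' unknown to the fitness model")
    stats::setNames(fitness@w[, background], fitness@geneId)
}

#' @rdname fitnessRoles
#' @export
plantedGenes <- function(fitness) {
    fitness@geneId[fitness@role == "sporulation_factor"]
}

#' Override fitness parameters for selected genes
#'
#' @param fitness a [FitnessModel-class].
#' @param geneId gene ids to modify.
#' @param background background whose parameters change (default: all).
#' @param w,s replacement probabilities (scalar or one per gene); \code{NULL}
#'   leaves the parameter untouched.
#' @param role optional replacement role label for the genes.
#'
#' @return The modified [FitnessModel-class].
#' @export
setFitness <- function(fitness, geneId, background = NULL, w = NULL,
                       s = NULL, role = NULL) {
    idx <- match(geneId, fitness@geneId)
    if (anyNA(idx)) stop("unknown gene id(s): ",
                         paste(geneId[is.na(idx)], collapse = ", "))
    cols <- if (is.null(background)) fitness@backgrounds else background
    if (!all(cols %in% fitness@backgrounds))
        stop("unknown background")
    if (!is.null(w)) fitness@w[idx, cols] <- w
    if (!is.null(s)) fitness@s[idx, cols] <- s
    if (!is.null(role)) fitness@role[idx] <- role
    validObject(fitness)
    fitness
}
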