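# Accessors and show methods for the S4 containers.

#' Accessors for TnGenome and TASiteIndex
#'
#' @param x a [TnGenome-class] or [TASiteIndex-class].
#' @return \code{genomeSequence}: the [Biostrings::DNAString];
#'   \code{genomeGenes}: the gene [GenomicRanges::GRanges];
#'   \code{taSites}: integer TA-site coordinates;
#'   \code{siteGenes}: per-site gene ids (\code{"."} = intergenic).
#' @export
genomeSequence <- function(x) x@sequence

#' @rdname genomeSequence
#' @export
genomeGenes <- function(x) x@genes

#' @rdname genomeSequence
#' @export
taSites <- function(x) x@sites

#' @rdname genomeSequence
#' @export
siteGenes <- function(x) x@geneId

#' Accessors for InsertionLibrary and SiteCounts
#'
#' @param x an [InsertionLibrary-class] or [SiteCounts-class].
#' @return \code{libraryAbundance} / \code{siteReadCounts}: named numeric
#'   vector of per-site values (names = TA-site coordinates);
#'   \code{totalClones}: integer.
#' @export
libraryAbundance <- function(x) stats::setNames(x@abundance, x@sites)

#' @rdname libraryAbundance
#' @export
totalClones <- function(x) x@totalClones

#' @rdname libraryAbundance
#' @export
siteReadCounts <- function(x) stats::setNames(x@counts, x@sites)

setMethod("show", "TnGenome", function(object) {
    cat("TnGenome '", object@id, "': ", length(object@sequence), " bp, ",
        if (object@circular) "circular" else "linear", ", ",
        length(object@genes), " genes\n", sep = "")
})

setMethod("show", "TASiteIndex", function(object) {
    cat("TASiteIndex: ", length(object@sites), " TA sites on ",
        object@genomeLength, " bp (",
        sum(object@geneId != "."), " genic)\n", sep = "")
})

setMethod("show", "FitnessModel", function(object) {
    cat("FitnessModel: ", length(object@geneId), " genes x ",
        length(object@backgrounds), " backgrounds (",
        paste(object@backgrounds, collapse = ", "), ")\n", sep = "")
    print(table(role = object@role))
})

setMethod("show", "InsertionLibrary", function(object) {
    cat("InsertionLibrary [", object@background, ", ", object@timepoint,
        "]: ", object@totalClones, " clones over ",
        sum(object@abundance > 0), "/", length(object@sites),
        " occupied TA sites\n", sep = "")
})

setMethod("show", "SiteCounts", function(object) {
    cat("SiteCounts [", object@background, ", ", object@timepoint, "]: ",
        format(object@nMapped), " mapped reads over ",
        sum(object@counts > 0), "/", length(object@sites),
        " TA sites (unmapped ", format(object@nUnmapped),
        ", ambiguous ", format(object@nAmbiguous), ")\n", sep = "")
})

setMethod("show", "TagIndex", function(object) {
    cat("TagIndex: ", length(object@tags), " tags of length ",
        object@tagLength, " over ", length(object@sites), " TA sites (",
        length(object@ambiguous), " ambiguous)\n", sep = "")
})
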