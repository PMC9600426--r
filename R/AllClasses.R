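#' @import methods
#' @importFrom S4Vectors mcols
NULL

#' Annotated (synthetic or real) genome for a Tn-seq screen
#'
#' Holds a single chromosome sequence together with its gene annotation.
#' Synthetic genomes are produced by [generateGenome()]; real genomes can be
#' assembled from a FASTA file ([readGenomeFasta()]) and a GFF3 annotation
#' ([readGFF3()]).
#'
#' @slot id single seqname, e.g. \code{"synthetic_genome"}.
#' @slot sequence a [Biostrings::DNAString] over \{A,C,G,T\}.
#' @slot circular logical; if \code{TRUE}, coordinate arithmetic (TA-site
#'   detection, junction tags) wraps modulo the genome length.
#' @slot genes a [GenomicRanges::GRanges] with metadata columns
#'   \code{gene_id} and \code{name}; 1-based inclusive coordinates.
#'
#' @exportClass TnGenome
setClass("TnGenome",
    representation(
        id = "character",
        sequence = "DNAString",
        circular = "logical",
        genes = "GRanges"
    )
)

setValidity("TnGenome", function(object) {
    msg <- character()
    if (length(object@id) != 1L)
        msg <- c(msg, "'id' must be a single string")
    if (length(object@sequence) < 1L)
        msg <- c(msg, "genome sequence must be non-empty")
    freqs <- Biostrings::alphabetFrequency(object@sequence)
    if (sum(freqs[c("A", "C", "G", "T")]) != length(object@sequence))
        msg <- c(msg, "genome alphabet must be strictly {A,C,G,T}")
    if (length(object@genes) > 0L) {
        mc <- S4Vectors::mcols(object@genes)
        if (!all(c("gene_id", "name") %in% colnames(mc)))
            msg <- c(msg, "genes must carry 'gene_id' and 'name' columns")
        if (any(BiocGenerics::end(object@genes) > length(object@sequence)))
            msg <- c(msg, "gene coordinates exceed genome length")
    }
    if (length(msg)) msg else TRUE
})

#' Index of TA dinucleotide insertion sites
#'
#' Each site is identified by the 1-based coordinate of the T of a TA
#' dinucleotide; overlapping occurrences (TATA) are distinct sites. A site
#' belongs to the gene whose body \code{[start, end]} contains its T
#' coordinate; intergenic sites carry gene id \code{"."}.
#'
#' @slot sites strictly increasing integer coordinates of the T of each TA.
#' @slot geneId character vector parallel to \code{sites}; \code{"."} for
#'   intergenic sites.
#' @slot circular logical, inherited from the genome.
#' @slot genomeLength integer genome length, for wraparound arithmetic.
#'
#' @exportClass TASiteIndex
setClass("TASiteIndex",
    representation(
        sites = "integer",
        geneId = "character",
        circular = "logical",
        genomeLength = "integer"
    )
)

setValidity("TASiteIndex", function(object) {
    msg <- character()
    if (length(object@sites) != length(object@geneId))
        msg <- c(msg, "'sites' and 'geneId' must have equal length")
    if (is.unsorted(object@sites, strictly = TRUE))
        msg <- c(msg, "'sites' must be strictly increasing")
    if (length(object@sites) &&
        (min(object@sites) < 1L || max(object@sites) > object@genomeLength))
        msg <- c(msg, "sites out of genome bounds")
    if (length(msg)) msg else TRUE
})

#' Planted per-gene fitness truth for the selection simulator
#'
#' For every gene and genetic background the model stores a vegetative
#' survival probability \code{w} (probability that an insertion clone in the
#' gene forms a colony during library construction) and a sporulation
#' survival probability \code{s} (probability the clone yields a
#' heat-resistant, germinable spore). Intergenic insertions default to
#' \code{w = 1} and the background baseline \code{s}.
#'
#' @slot backgrounds background labels, e.g. \code{c("WT", "mutant")}.
#' @slot geneId gene identifiers (rows of \code{w} and \code{s}).
#' @slot role one of \code{"neutral"}, \code{"essential_vegetative"},
#'   \code{"sporulation_factor"} per gene.
#' @slot w,s numeric matrices, genes x backgrounds, values in [0, 1].
#' @slot baselineS named numeric; baseline sporulation survival per
#'   background (applies to neutral genes and intergenic sites).
#'
#' @exportClass FitnessModel
setClass("FitnessModel",
    representation(
        backgrounds = "character",
        geneId = "character",
        role = "character",
        w = "matrix",
        s = "matrix",
        baselineS = "numeric"
    )
)

setValidity("FitnessModel", function(object) {
    msg <- character()
    ng <- length(object@geneId)
    if (!identical(dim(object@w), c(ng, length(object@backgrounds))) ||
        !identical(dim(object@s), c(ng, length(object@backgrounds))))
        msg <- c(msg, "'w' and 's' must be genes x backgrounds matrices")
    if (any(object@w < 0 | object@w > 1) || any(object@s < 0 | object@s > 1))
        msg <- c(msg, "'w' and 's' must lie in [0, 1]")
    if (length(object@role) != ng)
        msg <- c(msg, "'role' must have one entry per gene")
    if (!all(object@role %in%
             c("neutral", "essential_vegetative", "sporulation_factor")))
        msg <- c(msg, "unknown role label")
    if (ng && any(object@w[object@role == "essential_vegetative", ] != 0))
        msg <- c(msg, "essential_vegetative genes must have w = 0")
    if (!all(object@backgrounds %in% names(object@baselineS)))
        msg <- c(msg, "'baselineS' must be named by background")
    if (length(msg)) msg else TRUE
})

#' Clone abundance per TA site at one timepoint in one background
#'
#' @slot background background label.
#' @slot timepoint \code{"T0"} (post library construction) or \code{"T30"}
#'   (post sporulation selection and germination pooling).
#' @slot sites TA-site coordinates (the full TA index of the genome).
#' @slot abundance non-negative integer clone counts parallel to
#'   \code{sites}.
#' @slot totalClones integer, equals \code{sum(abundance)}.
#'
#' @exportClass InsertionLibrary
setClass("InsertionLibrary",
    representation(
        background = "character",
        timepoint = "character",
        sites = "integer",
        abundance = "integer",
        totalClones = "integer"
    )
)

setValidity("InsertionLibrary", function(object) {
    msg <- character()
    if (!object@timepoint %in% c("T0", "T30"))
        msg <- c(msg, "'timepoint' must be 'T0' or 'T30'")
    if (length(object@abundance) != length(object@sites))
        msg <- c(msg, "'abundance' must be parallel to 'sites'")
    if (any(object@abundance < 0L))
        msg <- c(msg, "'abundance' must be non-negative")
    if (object@totalClones != sum(object@abundance))
        msg <- c(msg, "'totalClones' must equal sum(abundance)")
    if (length(msg)) msg else TRUE
})

#' Per-TA-site mapped read counts for one sequenced library
#'
#' The Tn-seq profile of a library: every TA site of the genome with its
#' mapped read count (zeros included), plus read accounting. The accounting
#' invariant \code{nMapped + nUnmapped + nAmbiguous = reads processed} is
#' established by [mapReads()]. After [normalizeLibraries()] the counts are
#' rescaled and \code{nMapped} is updated to the (non-integer) scaled total.
#'
#' @slot background,timepoint library metadata.
#' @slot seqname seqname used in WIG output.
#' @slot sites TA-site coordinates.
#' @slot counts numeric read counts parallel to \code{sites}.
#' @slot nMapped,nUnmapped,nAmbiguous read accounting.
#'
#' @exportClass SiteCounts
setClass("SiteCounts",
    representation(
        background = "character",
        timepoint = "character",
        seqname = "character",
        sites = "integer",
        counts = "numeric",
        nMapped = "numeric",
        nUnmapped = "numeric",
        nAmbiguous = "numeric"
    )
)

setValidity("SiteCounts", function(object) {
    msg <- character()
    if (length(object@counts) != length(object@sites))
        msg <- c(msg, "'counts' must be parallel to 'sites'")
    if (any(object@counts < 0))
        msg <- c(msg, "'counts' must be non-negative")
    if (abs(object@nMapped - sum(object@counts)) > 1e-6 * max(1, object@nMapped))
        msg <- c(msg, "'nMapped' must equal sum(counts)")
    if (length(msg)) msg else TRUE
})

#' Exact-match junction-tag index
#'
#' Maps every unambiguous fixed-length junction tag (left flank of the TA,
#' plus the reverse complement of the right flank) to its unique TA site.
#' Tags occurring at more than one site are held in \code{ambiguous} and are
#' never assigned.
#'
#' @slot tagLength tag length in bases.
#' @slot tags unambiguous tag sequences.
#' @slot tagSite TA-site coordinate per tag.
#' @slot ambiguous tag sequences occurring at more than one site.
#' @slot sites the full TA-site vector of the genome (for zero restoration).
#' @slot seqname genome id.
#'
#' @exportClass TagIndex
setClass("TagIndex",
    representation(
        tagLength = "integer",
        tags = "character",
        tagSite = "integer",
        ambiguous = "character",
        sites = "integer",
        seqname = "character"
    )
)

setValidity("TagIndex", function(object) {
    msg <- character()
    if (length(object@tags) != length(object@tagSite))
        msg <- c(msg, "'tags' and 'tagSite' must have equal length")
    if (anyDuplicated(object@tags))
        msg <- c(msg, "'tags' must be unique")
    if (length(intersect(object@tags, object@ambiguous)))
        msg <- c(msg, "ambiguous tags must not appear in the map")
    if (length(msg)) msg else TRUE
})
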