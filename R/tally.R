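#' Build the exact-match junction-tag index
#'
#' For every TA site with both flanks fully inside the (possibly circular)
#' genome, two candidate tags are generated: the left flank and the reverse
#' complement of the right flank. Tags that occur at more than one site are
#' moved to the ambiguous set and are never assigned by [mapReads()]. A tag
#' whose two orientations coincide at the same site (palindromic flanks)
#' remains assignable.
#'
#' @param genome a [TnGenome-class].
#' @param ta a [TASiteIndex-class].
#' @param tagLength tag length in bases (>= 10; default 16, MmeI-style).
#'
#' @return A [TagIndex-class].
#' @export
buildTagIndex <- function(genome, ta, tagLength = 16L) {
    stopifnot(is(genome, "TnGenome"), is(ta, "TASiteIndex"))
    tg <- siteTags(genome, ta, tagLength)
    use <- tg$usable
    cand <- data.frame(
        tag = c(tg$left[use], tg$rightRC[use]),
        site = c(ta@sites[use], ta@sites[use]),
        stringsAsFactors = FALSE)
    # collapse duplicate (tag, site) pairs, then flag tags at >1 site
    cand <- unique(cand)
    dup <- unique(cand$tag[duplicated(cand$tag)])
    keep <- !(cand$tag %in% dup)
    new("TagIndex", tagLength = as.integer(tagLength),
        tags = cand$tag[keep], tagSite = cand$site[keep],
        ambiguous = dup, sites = ta@sites, seqname = genome@id)
}

# Strict 4-line-record FASTQ reader; reports the record number on malformed
# input. Returns the read sequences.
readFastqSeqs <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("FASTQ parse error: line count ", length(lines),
             " is not a multiple of 4")
    n <- length(lines) %/% 4L
    if (n == 0L) return(character(0))
    hdr <- lines[seq(1L, by = 4L, length.out = n)]
    plus <- lines[seq(3L, by = 4L, length.out = n)]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad))
        stop("FASTQ parse error at record ", bad[1],
             ": header does not start with '@'")
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad))
        stop("FASTQ parse error at record ", bad[1],
             ": separator line does not start with '+'")
    lines[seq(2L, by = 4L, length.out = n)]
}

#' Map junction-tag reads to TA sites
#'
#' Exact string match of each read's first \code{tagLength} bases against
#' the tag index (reads longer than the tag are truncated from the 5' end).
#' Hits increment the site count; reads matching an ambiguous tag increment
#' \code{nAmbiguous}; everything else increments \code{nUnmapped}. The
#' accounting invariant \code{nMapped + nUnmapped + nAmbiguous = total reads}
#' always holds.
#'
#' @param reads a FASTQ file path or a character vector of read sequences.
#' @param index a [TagIndex-class].
#' @param background,timepoint metadata attached to the result.
#'
#' @return A [SiteCounts-class] over all TA sites of the index (zero counts
#'   included).
#' @export
mapReads <- function(reads, index, background = NA_character_,
                     timepoint = NA_character_) {
    stopifnot(is(index, "TagIndex"))
    if (length(reads) == 1L && file.exists(reads))
        reads <- readFastqSeqs(reads)
    short <- nchar(reads) < index@tagLength
    tags <- substr(reads, 1L, index@tagLength)
    hit <- match(tags, index@tags)
    hit[short] <- NA_integer_
    isAmb <- !short & is.na(hit) & tags %in% index@ambiguous
    nAmb <- sum(isAmb)
    nMapped <- sum(!is.na(hit))
    nUnmapped <- length(reads) - nMapped - nAmb
    counts <- numeric(length(index@sites))
    if (nMapped > 0L) {
        tb <- tabulate(match(index@tagSite[hit[!is.na(hit)]], index@sites),
                       nbins = length(index@sites))
        counts <- as.numeric(tb)
    }
    new("SiteCounts", background = background, timepoint = timepoint,
        seqname = index@seqname, sites = index@sites, counts = counts,
        nMapped = as.numeric(nMapped), nUnmapped = as.numeric(nUnmapped),
        nAmbiguous = as.numeric(nAmb))
}

#' Write / read a per-site count track as variableStep WIG
#'
#' One \code{variableStep} declaration (span 1) followed by one line per
#' nonzero TA site. Library metadata and read accounting travel in comment
#' lines, so the round trip is lossless; zero-count sites are restored from
#' the TA index on read. Reading a position absent from the TA index is an
#' error naming the offending line.
#'
#' @param counts a [SiteCounts-class].
#' @param path file path.
#' @param ta a [TASiteIndex-class] used to restore zero-count sites.
#'
#' @return \code{readWig} returns a [SiteCounts-class]; \code{writeWig}
#'   returns \code{path} invisibly.
#' @export
writeWig <- function(counts, path) {
    stopifnot(is(counts, "SiteCounts"))
    nz <- counts@counts != 0
    lines <- c(
        sprintf("#SporeTnSeq background=%s timepoint=%s mapped=%s unmapped=%s ambiguous=%s",
                counts@background, counts@timepoint,
                format(counts@nMapped, scientific = FALSE),
                format(counts@nUnmapped, scientific = FALSE),
                format(counts@nAmbiguous, scientific = FALSE)),
        sprintf("variableStep chrom=%s span=1", counts@seqname))
    if (any(nz))
        lines <- c(lines, paste(counts@sites[nz],
                                format(counts@counts[nz],
                                       scientific = FALSE, trim = TRUE)))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeWig
#' @export
readWig <- function(path, ta) {
    stopifnot(is(ta, "TASiteIndex"))
    lines <- readLines(path)
    background <- timepoint <- NA_character_
    nUnmapped <- nAmbiguous <- 0
    meta <- grep("^#SporeTnSeq", lines, value = TRUE)
    if (length(meta)) {
        getField <- function(key) {
            m <- regmatches(meta[1],
                            regexec(paste0(key, "=([^ ]+)"), meta[1]))[[1]]
            if (length(m) < 2L) NA_character_ else m[2]
        }
        background <- getField("background")
        timepoint <- getField("timepoint")
        nUnmapped <- as.numeric(getField("unmapped"))
        nAmbiguous <- as.numeric(getField("ambiguous"))
    }
    decl <- grep("^variableStep", lines)
    if (length(decl) != 1L)
        stop("WIG parse error: expected exactly one variableStep ",
             "declaration")
    seqname <- sub(".*chrom=([^ ]+).*", "\\1", lines[decl])
    dataIdx <- setdiff(seq_along(lines),
                       c(grep("^#", lines), decl, which(!nzchar(lines))))
    counts <- numeric(length(ta@sites))
    for (i in dataIdx) {
        f <- strsplit(lines[i], "[ \t]+")[[1]]
        if (length(f) != 2L)
            stop("WIG parse error at line ", i, ": expected 'position value'")
        pos <- suppressWarnings(as.integer(f[1]))
        val <- suppressWarnings(as.numeric(f[2]))
        if (is.na(pos) || is.na(val))
            stop("WIG parse error at line ", i, ": non-numeric fields")
        j <- match(pos, ta@sites)
        if (is.na(j))
            stop("WIG parse error at line ", i, ": position ", pos,
                 " is not a TA site")
        counts[j] <- val
    }
    new("SiteCounts", background = background, timepoint = timepoint,
        seqname = seqname, sites = ta@sites, counts = counts,
        nMapped = sum(counts), nUnmapped = nUnmapped,
        nAmbiguous = nAmbiguous)
}

#' Read-accounting summary of a mapped library
#'
#' @param counts a [SiteCounts-class].
#' @return A named list with \code{n_mapped}, \code{n_unmapped},
#'   \code{n_ambiguous} and \code{n_total}.
#' @export
readAccounting <- function(counts) {
    list(n_mapped = counts@nMapped, n_unmapped = counts@nUnmapped,
         n_ambiguous = counts@nAmbiguous,
         n_total = counts@nMapped + counts@nUnmapped + counts@nAmbiguous)
}
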