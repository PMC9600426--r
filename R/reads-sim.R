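# Junction-tag extraction shared by the read simulator and the tag index.
# For each TA site p: the left tag is the tagLength bases ending at p - 1;
# the right tag is the tagLength bases starting at p + 2, reverse
# complemented (reads off the right transposon end come out antisense).
# On a circular genome both flanks wrap; on a linear genome sites whose
# flanks run off an end are flagged unusable.
siteTags <- function(genome, ta, tagLength) {
    tagLength <- as.integer(tagLength)
    if (tagLength < 10L) stop("'tagLength' must be >= 10")
    L <- length(genome@sequence)
    p <- ta@sites
    str <- as.character(genome@sequence)
    if (genome@circular) {
        big <- paste0(str, str)
        left <- substring(big, p - tagLength + L, p - 1L + L)
        right <- substring(big, p + 2L, p + tagLength + 1L)
        usable <- rep(TRUE, length(p))
    } else {
        usable <- (p - tagLength >= 1L) & (p + tagLength + 1L <= L)
        left <- right <- rep(NA_character_, length(p))
        left[usable] <- substring(str, p[usable] - tagLength,
                                  p[usable] - 1L)
        right[usable] <- substring(str, p[usable] + 2L,
                                   p[usable] + tagLength + 1L)
    }
    rightRC <- right
    rightRC[usable] <- revComp(right[usable])
    list(left = left, rightRC = rightRC, usable = usable)
}

# Apply i.i.d. per-base substitution errors to fixed-length tags.
mutateTags <- function(tags, tagLength, errorRate) {
    nerr <- stats::rbinom(length(tags), tagLength, errorRate)
    idx <- which(nerr > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
        pos <- sample.int(tagLength, nerr[i])
        cur <- strsplit(tags[i], "", fixed = TRUE)[[1]]
        for (pp in pos)
            cur[pp] <- sample(setdiff(bases, cur[pp]), 1L)
        tags[i] <- paste(cur, collapse = "")
    }
    tags
}

#' Simulate MmeI junction-tag sequencing of a library
#'
#' Draws \code{depth} reads multinomially from the library's clone
#' abundances. Each read is the fixed-length genomic tag flanking the
#' insertion's TA site, emitted from the left or right transposon-chromosome
#' junction with equal probability; right-junction tags are emitted reverse
#' complemented (sequencing runs off the transposon end). Substitution
#' errors are applied at \code{errorRate} per base. A truth table records
#' the originating site of every read for downstream oracles.
#'
#' On a linear genome, sites whose tag would run off an end are skipped with
#' a warning (their clones emit no reads).
#'
#' @param lib an [InsertionLibrary-class] (typically T30).
#' @param genome the [TnGenome-class] the library was built on.
#' @param ta the [TASiteIndex-class] of the genome.
#' @param depth number of reads to draw.
#' @param tagLength junction-tag length in bases (default 16, MmeI-style).
#' @param errorRate per-base substitution probability (default 0).
#' @param seed integer RNG seed.
#' @param fastqPath optional path; if given, reads are written as a 4-line
#'   FASTQ with constant Phred+33 quality \code{"I"}.
#' @param truthPath optional path for the truth table TSV
#'   (\code{read_id}, \code{site}, \code{junction_side}).
#'
#' @return Invisibly, a list with \code{reads} (character vector of read
#'   sequences), \code{ids}, and \code{truth} (data.frame with
#'   \code{read_id}, \code{site}, \code{junction_side}).
#' @export
simulateReads <- function(lib, genome, ta, depth, tagLength = 16L,
                          errorRate = 0, seed = 1L, fastqPath = NULL,
                          truthPath = NULL) {
    stopifnot(is(lib, "InsertionLibrary"), is(genome, "TnGenome"),
              is(ta, "TASiteIndex"))
    depth <- as.integer(depth)
    if (depth < 1L) stop("'depth' must be >= 1")
    tags <- siteTags(genome, ta, tagLength)
    ab <- as.numeric(lib@abundance)
    if (!all(tags$usable)) {
        nskip <- sum(!tags$usable & ab > 0)
        if (nskip > 0L)
            warning(nskip, " site(s) skipped: tag runs off the linear ",
                    "genome end")
        ab[!tags$usable] <- 0
    }
    if (sum(ab) == 0) stop("library has no sequenceable clones")
    withSeed(seed, {
        siteReads <- as.vector(stats::rmultinom(1L, depth, ab))
        nLeft <- stats::rbinom(length(siteReads), siteReads, 0.5)
        nRight <- siteReads - nLeft
        reads <- c(rep(tags$left, nLeft), rep(tags$rightRC, nRight))
        site <- c(rep(ta@sites, nLeft), rep(ta@sites, nRight))
        side <- rep(c("left", "right"), c(sum(nLeft), sum(nRight)))
        ord <- sample.int(depth)
        reads <- reads[ord]; site <- site[ord]; side <- side[ord]
        if (errorRate > 0)
            reads <- mutateTags(reads, as.integer(tagLength), errorRate)
        ids <- sprintf("read_%07d", seq_len(depth))
        truth <- data.frame(read_id = ids, site = site,
                            junction_side = side,
                            stringsAsFactors = FALSE)
        if (!is.null(fastqPath))
            writeFastq(ids, reads, fastqPath,
                       qual = strrep("I", tagLength))
        if (!is.null(truthPath))
            utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        invisible(list(reads = reads, ids = ids, truth = truth))
    })
}

#' Write reads as a 4-line-record FASTQ
#'
#' @param ids read identifiers (without the \code{@} prefix).
#' @param reads read sequences.
#' @param path output path.
#' @param qual quality string, recycled per read (Phred+33).
#'
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(ids, reads, path, qual = strrep("I", 16L)) {
    stopifnot(length(ids) == length(reads))
    n <- length(reads)
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    lines[seq(2L, by = 4L, length.out = n)] <- reads
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- qual
    writeLines(lines, path)
    invisible(path)
}
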