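#' Construct a TnGenome from its parts
#'
#' @param id seqname of the (single) chromosome.
#' @param sequence a [Biostrings::DNAString], character string, or anything
#'   coercible to a DNAString; normalized to uppercase.
#' @param circular logical; whether coordinates wrap at the origin.
#' @param genes a [GenomicRanges::GRanges] with \code{gene_id} and
#'   \code{name} metadata columns (may be empty).
#'
#' @return A [TnGenome-class] object.
#' @export
TnGenome <- function(id, sequence, circular = TRUE,
                     genes = GenomicRanges::GRanges()) {
    seq <- Biostrings::DNAString(toupper(as.character(sequence)))
    if (length(genes) > 0L) {
        mc <- S4Vectors::mcols(genes)
        if (is.null(mc$name)) mc$name <- mc$gene_id
        S4Vectors::mcols(genes) <- mc
    }
    new("TnGenome", id = id, sequence = seq, circular = circular,
        genes = genes)
}

#' Generate a synthetic annotated genome
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content and packs
#' non-overlapping genes onto it with intergenic gaps of at least
#' \code{minGap} bases. Every gene is guaranteed to contain at least one TA
#' dinucleotide (enforced by resampling the rare offending gene body). Genes
#' never span the origin.
#'
#' @param length genome length in bases (>= 1,000).
#' @param nGenes number of genes to place.
#' @param geneLengthRange length-2 integer vector; gene lengths are drawn
#'   uniformly from this range (default 600-1500 bp, bacterial-like).
#' @param gcContent target GC fraction in [0.2, 0.8].
#' @param seed integer RNG seed; the output is deterministic given the seed.
#' @param circular logical, default \code{TRUE} (bacterial chromosome).
#' @param id seqname for the chromosome.
#' @param minGap minimum intergenic gap in bases.
#'
#' @return A [TnGenome-class] with \code{nGenes} annotated genes.
#' @examples
#' g <- generateGenome(50000, 30, seed = 7)
#' g
#' @export
generateGenome <- function(length, nGenes, geneLengthRange = c(600L, 1500L),
                           gcContent = 0.43, seed = 1L, circular = TRUE,
                           id = "synthetic_genome", minGap = 50L) {
    length <- as.integer(length)
    nGenes <- as.integer(nGenes)
    if (length < 1000L)
        stop("configuration error: genome length must be >= 1,000 bases")
    if (gcContent < 0.2 || gcContent > 0.8)
        stop("configuration error: gcContent must lie in [0.2, 0.8]")
    meanLen <- mean(geneLengthRange)
    if (nGenes * (meanLen + minGap) > 0.9 * length)
        stop("configuration error: infeasible packing - nGenes x (mean gene ",
             "length + minimum gap) exceeds 0.9 x genome length")
    withSeed(seed, {
        lens <- sample(seq.int(geneLengthRange[1], geneLengthRange[2]),
                       nGenes, replace = TRUE)
        slack <- length - sum(lens) - (nGenes + 1L) * minGap
        if (slack < 0L)
            stop("configuration error: infeasible packing - sampled gene ",
                 "lengths plus minimum gaps exceed the genome length")
        extra <- as.vector(stats::rmultinom(1L, slack,
                                            rep(1, nGenes + 1L)))
        starts <- integer(nGenes)
        pos <- 0L
        for (i in seq_len(nGenes)) {
            pos <- pos + minGap + extra[i]
            starts[i] <- pos + 1L
            pos <- pos + lens[i]
        }
        probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
                   G = gcContent / 2, T = (1 - gcContent) / 2)
        bases <- sample(names(probs), length, replace = TRUE, prob = probs)
        # enforce >= 1 TA per gene by resampling offending gene bodies
        hasTA <- function(v) any(v[-length(v)] == "T" & v[-1] == "A")
        for (i in seq_len(nGenes)) {
            span <- starts[i]:(starts[i] + lens[i] - 1L)
            while (!hasTA(bases[span]))
                bases[span] <- sample(names(probs), lens[i],
                                      replace = TRUE, prob = probs)
        }
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        geneId <- sprintf("gene_%04d", seq_len(nGenes))
        genes <- GenomicRanges::GRanges(
            seqnames = id,
            ranges = IRanges::IRanges(start = starts, width = lens),
            strand = strand,
            gene_id = geneId,
            name = geneId
        )
        TnGenome(id, paste(bases, collapse = ""), circular = circular,
                 genes = genes)
    })
}

#' Index all TA dinucleotide sites of a genome
#'
#' A coordinate \code{p} is a TA site iff \code{sequence[p] == "T"} and
#' \code{sequence[p + 1] == "A"}, with the successor position taken modulo
#' the genome length when the genome is circular. Overlapping occurrences
#' (TATA) yield distinct sites. Each site is assigned to the gene whose body
#' contains its T coordinate, or \code{"."} if intergenic.
#'
#' @param genome a [TnGenome-class].
#'
#' @return A [TASiteIndex-class].
#' @examples
#' g <- generateGenome(50000, 30, seed = 7)
#' ta <- findTASites(g)
#' ta
#' @export
findTASites <- function(genome) {
    stopifnot(is(genome, "TnGenome"))
    L <- length(genome@sequence)
    sites <- BiocGenerics::start(
        Biostrings::matchPattern("TA", genome@sequence))
    if (genome@circular && L >= 2L) {
        lastBase <- as.character(Biostrings::subseq(genome@sequence, L, L))
        firstBase <- as.character(Biostrings::subseq(genome@sequence, 1L, 1L))
        if (lastBase == "T" && firstBase == "A")
            sites <- c(sites, L)
    }
    sites <- as.integer(sort(unique(sites)))
    geneId <- rep(".", length(sites))
    if (length(genome@genes) > 0L && length(sites) > 0L) {
        hits <- IRanges::findOverlaps(
            IRanges::IRanges(start = sites, width = 1L),
            IRanges::ranges(genome@genes), select = "first")
        ok <- !is.na(hits)
        geneId[ok] <- S4Vectors::mcols(genome@genes)$gene_id[hits[ok]]
    }
    new("TASiteIndex", sites = sites, geneId = geneId,
        circular = genome@circular, genomeLength = L)
}

#' Write / read a genome FASTA
#'
#' Plain single-record FASTA via Biostrings. Lowercase bases on input are
#' accepted and normalized to uppercase; bases outside \{A,C,G,T\} are
#' rejected (synthetic-mode contract).
#'
#' @param genome a [TnGenome-class].
#' @param path file path.
#' @param circular logical flag attached to the genome on read.
#' @param genes annotation attached on read (default empty).
#'
#' @return \code{readGenomeFasta} returns a [TnGenome-class];
#'   \code{writeGenomeFasta} returns \code{path} invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    dss <- Biostrings::DNAStringSet(genome@sequence)
    names(dss) <- genome@id
    Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
    invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path, circular = TRUE,
                            genes = GenomicRanges::GRanges()) {
    dss <- Biostrings::readDNAStringSet(path)
    if (length(dss) != 1L)
        stop("expected a single-record FASTA, found ", length(dss),
             " records")
    TnGenome(names(dss)[1], as.character(dss[[1]]), circular = circular,
             genes = genes)
}

#' Write / read the gene annotation as GFF3
#'
#' Feature type \code{"gene"}, 1-based inclusive coordinates, attributes
#' \code{ID} and \code{Name}. The reader is strict and reports the offending
#' line number on malformed input (wrong column count, non-numeric or
#' inverted coordinates).
#'
#' @param genome a [TnGenome-class] (its \code{genes} are written).
#' @param path file path.
#'
#' @return \code{readGFF3} returns a [GenomicRanges::GRanges];
#'   \code{writeGFF3} returns \code{path} invisibly.
#' @export
writeGFF3 <- function(genome, path) {
    g <- genome@genes
    mc <- S4Vectors::mcols(g)
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome@id,
                       length(genome@sequence)))
    if (length(g) > 0L) {
        lines <- c(lines, sprintf(
            "%s\tSporeTnSeq\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            as.character(GenomicRanges::seqnames(g)),
            BiocGenerics::start(g), BiocGenerics::end(g),
            as.character(BiocGenerics::strand(g)),
            mc$gene_id, mc$name))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGFF3
#' @export
readGFF3 <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineNo <- which(keep)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    parseAttr <- function(attr, key) {
        m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]*)"),
                                      attr))[[1]]
        if (length(m) < 2L) NA_character_ else m[2]
    }
    n <- length(rows)
    seqid <- ch <- id <- nm <- strand <- character(n)
    start <- end <- integer(n)
    for (i in seq_len(n)) {
        f <- rows[[i]]
        if (length(f) != 9L)
            stop("GFF3 parse error at line ", lineNo[i],
                 ": expected 9 tab-separated fields, found ", length(f))
        st <- suppressWarnings(as.integer(f[4]))
        en <- suppressWarnings(as.integer(f[5]))
        if (is.na(st) || is.na(en))
            stop("GFF3 parse error at line ", lineNo[i],
                 ": non-numeric coordinates")
        if (en < st)
            stop("GFF3 parse error at line ", lineNo[i],
                 ": end < start")
        if (!f[7] %in% c("+", "-", "."))
            stop("GFF3 parse error at line ", lineNo[i],
                 ": invalid strand '", f[7], "'")
        seqid[i] <- f[1]; start[i] <- st; end[i] <- en; strand[i] <- f[7]
        id[i] <- parseAttr(f[9], "ID")
        nm[i] <- parseAttr(f[9], "Name")
        if (is.na(id[i]))
            stop("GFF3 parse error at line ", lineNo[i],
                 ": missing ID attribute")
    }
    nm[is.na(nm)] <- id[is.na(nm)]
    strand[strand == "."] <- "*"
    GenomicRanges::GRanges(
        seqnames = seqid,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand, gene_id = id, name = nm)
}

#' Write / read the TA-site list as TSV
#'
#' Two columns: \code{site} (1-based coordinate of the T) and \code{gene_id}
#' (\code{"."} for intergenic sites).
#'
#' @param ta a [TASiteIndex-class].
#' @param path file path.
#' @param circular,genomeLength index metadata restored on read.
#'
#' @return \code{readTASites} returns a [TASiteIndex-class];
#'   \code{writeTASites} returns \code{path} invisibly.
#' @export
writeTASites <- function(ta, path) {
    utils::write.table(
        data.frame(site = ta@sites, gene_id = ta@geneId),
        file = path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTASites
#' @export
readTASites <- function(path, circular = TRUE, genomeLength = NA_integer_) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("integer", "character"))
    if (is.na(genomeLength)) genomeLength <- max(df$site, 0L) + 1L
    new("TASiteIndex", sites = df$site, geneId = df$gene_id,
        circular = circular, genomeLength = as.integer(genomeLength))
}
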