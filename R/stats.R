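#' Normalize two libraries by winsorized total scaling
#'
#' Sequencing depth differs between libraries, so raw per-site counts are
#' not comparable. Each library's total is computed after winsorizing its
#' top \code{winsorFraction} of nonzero sites to the winsor threshold (the
#' \code{1 - winsorFraction} quantile of nonzero counts), which bounds the
#' influence of jackpot sites on the scale factor. Both libraries are then
#' rescaled to a common target - the harmonic mean of the two winsorized
#' totals - so the two scale factors average to 1.
#'
#' @param ref,test [SiteCounts-class] objects on the same TA index.
#' @param winsorFraction fraction of nonzero sites winsorized per library
#'   (default 0.001).
#'
#' @return A list with elements \code{ref} and \code{test} (rescaled
#'   [SiteCounts-class] objects) and \code{scaleFactors} (named numeric,
#'   \code{c(ref = , test = )}).
#' @export
normalizeLibraries <- function(ref, test, winsorFraction = 0.001) {
    stopifnot(is(ref, "SiteCounts"), is(test, "SiteCounts"))
    if (!identical(ref@sites, test@sites))
        stop("libraries are on disjoint TA indices")
    winsTotal <- function(counts) {
        nz <- counts[counts > 0]
        if (length(nz) == 0L) return(0)
        thr <- stats::quantile(nz, 1 - winsorFraction, names = FALSE,
                               type = 7)
        sum(pmin(counts, thr))
    }
    tRef <- winsTotal(ref@counts)
    tTest <- winsTotal(test@counts)
    if (tRef == 0 || tTest == 0)
        stop("cannot normalize a library with zero mapped reads")
    target <- 2 / (1 / tRef + 1 / tTest)
    f <- c(ref = target / tRef, test = target / tTest)
    scale <- function(x, fac) {
        x@counts <- x@counts * fac
        x@nMapped <- sum(x@counts)
        x
    }
    list(ref = scale(ref, f["ref"]), test = scale(test, f["test"]),
         scaleFactors = f)
}

#' Per-gene fold reduction of insertions
#'
#' The screen's headline effect size: the ratio of a gene's (normalized)
#' insertion-read total in the reference library to that in the test
#' library, with a pseudocount on both totals so genes emptied by selection
#' yield a finite, bounded ratio.
#'
#' @param totalRef,totalTest per-gene normalized read totals (vectorized).
#' @param pseudocount added to both totals (default 1).
#'
#' @return \code{(totalRef + pseudocount) / (totalTest + pseudocount)}.
#' @examples
#' geneFoldReduction(216.7, 9)  # 21.77
#' @export
geneFoldReduction <- function(totalRef, totalTest, pseudocount = 1) {
    (totalRef + pseudocount) / (totalTest + pseudocount)
}

#' Mann-Whitney U test for per-gene underrepresentation
#'
#' Compares the per-TA-site counts of the test library (\code{y}) against
#' the reference library (\code{x}) within one gene. The statistic is the
#' standard U for sample \code{y}:
#' \deqn{U = \#\{(i,j): x_i < y_j\} + \tfrac12 \#\{(i,j): x_i = y_j\},}
#' so \code{alternative = "less"} (small U) tests whether \code{y} is
#' stochastically smaller than \code{x} - underrepresentation of insertions
#' in the test background.
#'
#' When \code{length(x) + length(y) <= exactLimit} the p-value is exact,
#' computed by enumerating all \code{choose(n + m, m)} assignments of the
#' observed (multi)set of counts to the two samples; ties are therefore
#' handled exactly. Otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used; a fully tied gene (zero
#' variance) yields p = 1.
#'
#' @param x reference-library counts (length >= 1).
#' @param y test-library counts (length >= 1).
#' @param alternative \code{"less"} (default; y stochastically smaller),
#'   \code{"greater"}, or \code{"two_sided"}.
#' @param exactLimit maximum \code{n + m} for exact enumeration (default 14).
#'
#' @return A list with elements \code{U} and \code{p}.
#' @examples
#' mannWhitneyU(c(4, 5, 6), c(1, 2, 3))  # U = 0, exact p = 1/20
#' @export
mannWhitneyU <- function(x, y,
                         alternative = c("less", "greater", "two_sided"),
                         exactLimit = 14L) {
    alternative <- match.arg(alternative)
    if (length(x) < 1L || length(y) < 1L)
        stop("'x' and 'y' must be non-empty")
    n <- length(x)
    m <- length(y)
    N <- n + m
    comb <- c(x, y)
    r <- rank(comb)
    U <- sum(r[n + seq_len(m)]) - m * (m + 1) / 2
    eps <- 1e-9
    if (N <= exactLimit) {
        sets <- utils::combn(N, m)
        Uall <- colSums(matrix(r[sets], nrow = m)) - m * (m + 1) / 2
        pl <- mean(Uall <= U + eps)
        pg <- mean(Uall >= U - eps)
    } else {
        mu <- n * m / 2
        tie <- table(comb)
        sigma2 <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
        if (sigma2 <= 0) {
            pl <- pg <- 1
        } else {
            sd <- sqrt(sigma2)
            pl <- stats::pnorm((U + 0.5 - mu) / sd)
            pg <- stats::pnorm((U - 0.5 - mu) / sd, lower.tail = FALSE)
        }
    }
    p <- switch(alternative,
                less = pl,
                greater = pg,
                two_sided = min(1, 2 * min(pl, pg)))
    list(U = U, p = p)
}

#' Run the per-gene underrepresentation screen
#'
#' Normalizes the two libraries ([normalizeLibraries()]), then for every
#' gene with at least one TA site builds the paired per-site count vectors
#' over all TA sites in the gene body (zero-count sites included - absence
#' of insertions is the signal), computes the fold reduction of insertions
#' ([geneFoldReduction()]), the Mann-Whitney U statistic and one-sided
#' p-value for underrepresentation in the test library ([mannWhitneyU()]
#' with \code{alternative = "less"}), and finally Benjamini-Hochberg q
#' values across all tested genes. Genes without TA sites are skipped with a
#' warning.
#'
#' @param ref reference-background (e.g. wild-type) [SiteCounts-class].
#' @param test sensitized-background [SiteCounts-class].
#' @param genes gene annotation: a [GenomicRanges::GRanges] with
#'   \code{gene_id}/\code{name} columns, or a [TnGenome-class].
#' @param ta the shared [TASiteIndex-class].
#' @param winsorFraction passed to [normalizeLibraries()].
#' @param pseudocount passed to [geneFoldReduction()].
#' @param trimFraction fraction of the gene body excluded at each end before
#'   collecting TA sites (default 0: no edge trimming).
#' @param exactLimit passed to [mannWhitneyU()].
#'
#' @return A \code{data.frame} with one row per tested gene - columns
#'   \code{gene_id}, \code{name}, \code{n_sites}, \code{total_ref},
#'   \code{total_test}, \code{fold_reduction}, \code{U}, \code{p}, \code{q} -
#'   sorted by decreasing fold reduction (ties broken by increasing p).
#' @export
analyzeScreen <- function(ref, test, genes, ta, winsorFraction = 0.001,
                          pseudocount = 1, trimFraction = 0,
                          exactLimit = 14L) {
    if (is(genes, "TnGenome")) genes <- genes@genes
    stopifnot(is(ta, "TASiteIndex"))
    norm <- normalizeLibraries(ref, test, winsorFraction)
    refC <- norm$ref@counts
    testC <- norm$test@counts
    mc <- S4Vectors::mcols(genes)
    gid <- mc$gene_id
    gname <- if (is.null(mc$name)) gid else mc$name
    gstart <- BiocGenerics::start(genes)
    gend <- BiocGenerics::end(genes)
    siteIdx <- split(seq_along(ta@sites), ta@geneId)
    res <- vector("list", length(gid))
    skipped <- character(0)
    for (i in seq_along(gid)) {
        idx <- siteIdx[[gid[i]]]
        if (trimFraction > 0 && length(idx)) {
            len <- gend[i] - gstart[i] + 1L
            lo <- gstart[i] + trimFraction * len
            hi <- gend[i] - trimFraction * len
            idx <- idx[ta@sites[idx] >= lo & ta@sites[idx] <= hi]
        }
        if (is.null(idx) || length(idx) == 0L) {
            skipped <- c(skipped, gid[i])
            next
        }
        xr <- refC[idx]
        yt <- testC[idx]
        mw <- mannWhitneyU(xr, yt, "less", exactLimit = exactLimit)
        res[[i]] <- data.frame(
            gene_id = gid[i], name = gname[i], n_sites = length(idx),
            total_ref = sum(xr), total_test = sum(yt),
            fold_reduction = geneFoldReduction(sum(xr), sum(yt),
                                               pseudocount),
            U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
    if (length(skipped))
        warning("skipped ", length(skipped),
                " gene(s) without TA sites: ",
                paste(utils::head(skipped, 5L), collapse = ", "))
    out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0L)
        stop("no gene could be tested")
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(-out$fold_reduction, out$p, out$gene_id), ]
    rownames(out) <- NULL
    out
}

#' Write screen results and a volcano-style table as TSV
#'
#' @param results output of [analyzeScreen()].
#' @param path results TSV path.
#' @param volcanoPath optional path for the volcano table
#'   (\code{gene_id}, \code{log2_fold_reduction}, \code{neg_log10_p}).
#' @param header optional character vector written as leading \code{#}
#'   comment lines (e.g. a config/seed record).
#'
#' @return \code{path}, invisibly.
#' @export
writeScreenResults <- function(results, path, volcanoPath = NULL,
                               header = NULL) {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    if (!is.null(header))
        writeLines(paste0("# ", header), con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(volcanoPath)) {
        floorP <- pmax(results$p, .Machine$double.xmin)
        vol <- data.frame(gene_id = results$gene_id,
                          log2_fold_reduction = log2(results$fold_reduction),
                          neg_log10_p = -log10(floorP))
        utils::write.table(vol, volcanoPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Score screen results against the planted truth
#'
#' Classifies every tested gene against the fitness model that generated the
#' data: a gene is \emph{planted} if its role is \code{sporulation_factor},
#' and \emph{called} if its BH q value falls below \code{alpha}.
#'
#' @param results output of [analyzeScreen()].
#' @param fitness the [FitnessModel-class] used in the simulation.
#' @param alpha q-value threshold for calling a hit (default 0.05).
#'
#' @return A list with \code{table} (per-gene data.frame: \code{gene_id},
#'   \code{role}, \code{planted}, \code{called}, \code{rank} by fold
#'   reduction, \code{fold_reduction}, \code{q}) and \code{summary} (named
#'   list: planted/called counts, true/false positives, false negatives,
#'   recall, and the fold-reduction ranks of the planted genes).
#' @export
recoveryReport <- function(results, fitness, alpha = 0.05) {
    roles <- fitnessRoles(fitness)
    role <- unname(roles[match(results$gene_id, names(roles))])
    role[is.na(role)] <- "neutral"
    planted <- role == "sporulation_factor"
    called <- results$q < alpha
    tab <- data.frame(
        gene_id = results$gene_id, role = role, planted = planted,
        called = called, rank = seq_len(nrow(results)),
        fold_reduction = results$fold_reduction, q = results$q,
        stringsAsFactors = FALSE)
    summary <- list(
        n_genes = nrow(tab),
        n_planted = sum(planted),
        n_called = sum(called),
        true_positives = sum(planted & called),
        false_positives = sum(!planted & called),
        false_negatives = sum(planted & !called),
        recall = if (any(planted)) sum(planted & called) / sum(planted)
                 else NA_real_,
        planted_ranks = tab$rank[planted])
    list(table = tab, summary = summary)
}
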