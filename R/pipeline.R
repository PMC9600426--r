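#' Sporulation efficiency from heat-resistant CFU
#'
#' Heat-resistant (80 degC, 20 min) CFU of a strain expressed as a
#' percentage of the reference (wild-type) heat-resistant CFU.
#'
#' @param strainCfu heat-resistant CFU of the strain.
#' @param referenceCfu heat-resistant CFU of the reference strain (> 0).
#'
#' @return \code{100 * strainCfu / referenceCfu}, a percentage.
#' @examples
#' sporulationEfficiency(4e5, 1e8)  # 0.4
#' @export
sporulationEfficiency <- function(strainCfu, referenceCfu) {
    if (any(referenceCfu <= 0))
        stop("'referenceCfu' must be > 0")
    100 * strainCfu / referenceCfu
}

#' Fold reduction between two sporulation efficiencies
#'
#' @param efficiencyA,efficiencyB efficiencies in percent;
#'   \code{efficiencyB > 0}.
#'
#' @return \code{efficiencyA / efficiencyB}.
#' @examples
#' efficiencyFoldReduction(8, 0.4)      # 20
#' efficiencyFoldReduction(1, 0.001)    # 1000
#' @export
efficiencyFoldReduction <- function(efficiencyA, efficiencyB) {
    if (any(efficiencyB <= 0))
        stop("'efficiencyB' must be > 0")
    efficiencyA / efficiencyB
}

.configDefaults <- list(
    genomeLength = 300000L,
    nGenes = 200L,
    geneLengthRange = c(600L, 1500L),
    gcContent = 0.43,
    circular = TRUE,
    backgrounds = c("WT", "mutant"),
    baselineS = 0.5,
    nEssential = 10L,
    nConditional = 10L,
    conditionalRatio = 20,
    nTransformants = 50000L,
    nColoniesPooled = 50000L,
    depth = 2000000L,
    tagLength = 16L,
    errorRate = 0,
    winsorFraction = 0.001,
    pseudocount = 1,
    trimFraction = 0,
    alpha = 0.05,
    seed = 1L
)

#' Assemble and validate a pipeline configuration
#'
#' Returns the full parameter set of the simulation-and-analysis pipeline,
#' with any supplied values overriding the desk-scale defaults (50,000
#' transformants, 50,000 pooled colonies, 2,000,000 reads per library;
#' sized down from the study's ~750,000-clone scale, which the screen
#' statistics do not require). Unknown keys are rejected before any compute.
#'
#' @param ... named overrides of the default configuration.
#'
#' @return A named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
    over <- list(...)
    if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
        stop("configuration error: all overrides must be named")
    unknown <- setdiff(names(over), names(.configDefaults))
    if (length(unknown))
        stop("configuration error: unknown key(s): ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(.configDefaults, over)
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a \code{RunConfig} list from [runConfig()].
#' @param path file path.
#'
#' @return \code{readRunConfig} returns a validated \code{RunConfig};
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(runConfig, vals)
}

#' Run the full screen pipeline
#'
#' Executes genome generation, fitness planting, library construction in
#' both backgrounds, sporulation selection, junction-tag read simulation,
#' tag mapping, the per-gene underrepresentation screen and the recovery
#' report, writing every artifact (FASTA, GFF3, TA-site TSV, FASTQ, WIG,
#' results/volcano TSV, recovery JSON) plus a JSON manifest from which the
#' run can be repeated exactly. All stage seeds are derived from
#' \code{config$seed} by fixed offsets, so two runs with the same config are
#' byte-identical.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @param outDir output directory (created if missing).
#' @param writeFastqFiles logical; FASTQ files are large, set \code{FALSE}
#'   to skip writing them while keeping the read simulation itself.
#'
#' @return Invisibly, a list with the screen \code{results} data.frame, the
#'   \code{recovery} report, the \code{fitness} truth and the paths of all
#'   written artifacts.
#' @export
runPipeline <- function(config = runConfig(), outDir,
                        writeFastqFiles = TRUE) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(outDir, f)
    seed <- config$seed
    stage <- function(msg) message("[SporeTnSeq] ", msg)

    stage("generating genome")
    genome <- generateGenome(config$genomeLength, config$nGenes,
                             config$geneLengthRange, config$gcContent,
                             seed = seed, circular = config$circular)
    writeGenomeFasta(genome, pth("genome.fasta"))
    writeGFF3(genome, pth("genes.gff3"))
    ta <- findTASites(genome)
    writeTASites(ta, pth("ta_sites.tsv"))

    stage("planting fitness model")
    fitness <- fitnessModel(genome, backgrounds = config$backgrounds,
                            baselineS = config$baselineS,
                            nEssential = config$nEssential,
                            nConditional = config$nConditional,
                            conditionalRatio = config$conditionalRatio,
                            seed = seed + 1L)

    stage("building tag index")
    index <- buildTagIndex(genome, ta, config$tagLength)

    countsList <- list()
    paths <- list(genome = pth("genome.fasta"), gff3 = pth("genes.gff3"),
                  taSites = pth("ta_sites.tsv"))
    for (k in seq_along(config$backgrounds)) {
        bg <- config$backgrounds[k]
        stage(paste0("background ", bg, ": library construction"))
        t0 <- buildLibrary(ta, fitness, bg, config$nTransformants,
                           seed = seed + 10L * k)
        stage(paste0("background ", bg, ": selection and pooling"))
        t30 <- applySelection(t0, fitness, ta, config$nColoniesPooled,
                              seed = seed + 10L * k + 1L)
        stage(paste0("background ", bg, ": sequencing ", config$depth,
                     " reads"))
        fq <- if (writeFastqFiles) pth(paste0(bg, "_T30.fastq")) else NULL
        sim <- simulateReads(t30, genome, ta, config$depth,
                             tagLength = config$tagLength,
                             errorRate = config$errorRate,
                             seed = seed + 10L * k + 2L,
                             fastqPath = fq)
        stage(paste0("background ", bg, ": mapping reads"))
        sc <- mapReads(sim$reads, index, background = bg,
                       timepoint = "T30")
        acc <- readAccounting(sc)
        stage(sprintf("background %s: mapped=%d unmapped=%d ambiguous=%d",
                      bg, acc$n_mapped, acc$n_unmapped, acc$n_ambiguous))
        writeWig(sc, pth(paste0(bg, "_T30.wig")))
        countsList[[bg]] <- sc
        paths[[paste0("wig_", bg)]] <- pth(paste0(bg, "_T30.wig"))
        if (writeFastqFiles) paths[[paste0("fastq_", bg)]] <- fq
    }

    stage("screen statistics")
    results <- analyzeScreen(countsList[[config$backgrounds[1]]],
                             countsList[[config$backgrounds[2]]],
                             genome, ta,
                             winsorFraction = config$winsorFraction,
                             pseudocount = config$pseudocount,
                             trimFraction = config$trimFraction)
    writeScreenResults(
        results, pth("results.tsv"), volcanoPath = pth("volcano.tsv"),
        header = c(paste0("SporeTnSeq screen results"),
                   paste0("seed=", seed),
                   paste0("config: ",
                          paste(names(unclass(config)),
                                vapply(unclass(config), function(v)
                                    paste(v, collapse = ","), ""),
                                sep = "=", collapse = " "))))
    recovery <- recoveryReport(results, fitness, alpha = config$alpha)
    jsonlite::write_json(recovery$summary, pth("recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$results <- pth("results.tsv")
    paths$volcano <- pth("volcano.tsv")
    paths$recovery <- pth("recovery.json")

    writeRunConfig(config, pth("config.yaml"))
    manifest <- list(
        package = "SporeTnSeq",
        version = as.character(utils::packageVersion("SporeTnSeq")),
        seed = seed,
        config = unclass(config),
        outputs = unlist(paths))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$manifest <- pth("manifest.json")
    paths$config <- pth("config.yaml")

    invisible(list(results = results, recovery = recovery,
                   fitness = fitness, genome = genome, ta = ta,
                   counts = countsList, paths = paths))
}
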