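#' Assemble a run configuration
#'
#' A flat list mirroring the YAML config accepted by [runEndToEnd()] and the
#' companion command-line script. Fields not supplied fall back to the
#' defaults shown.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param simParams a [SimParams-class] (simulate mode).
#' @param plantHgt number of recent whole-array transfers to plant between
#'   well-separated lineages after the forward simulation (simulate mode).
#' @param minPlantDistance minimum tree distance between planted
#'   donor/recipient pairs (substitutions/site).
#' @param genomeDir directory of genome FASTA files (real mode; headers
#'   `species|locus|index`).
#' @param treeFile optional newick tree (real mode).
#' @param metadataFile optional TSV `genome_id<TAB>label` (real mode).
#' @param orthology `"known"` (simulate mode only) or `"rbh"`.
#' @param idThreshold,separationThreshold transfer-flag thresholds
#'   (percent).
#' @param alpha model-selection significance level.
#' @param minSep,assignRadius variant-catalog thresholds.
#' @param fragLen ANI fragment length (bp).
#' @param genusName label used in the summary outputs.
#' @return a validated configuration list of class `stasisRunConfig`.
#' @export
runConfig <- function(mode = c("simulate", "real"), simParams = NULL,
                      plantHgt = 0L, minPlantDistance = 0.12,
                      genomeDir = NULL, treeFile = NULL, metadataFile = NULL,
                      orthology = c("known", "rbh"),
                      idThreshold = 99.9, separationThreshold = 95,
                      alpha = 0.05, minSep = 2L, assignRadius = 1L,
                      fragLen = 1000L, genusName = "SimGenus") {
  mode <- match.arg(mode)
  orthology <- match.arg(orthology)
  if (idThreshold < 0 || idThreshold > 100 ||
      separationThreshold < 0 || separationThreshold > 100)
    stop("thresholds must lie in [0, 100]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (mode == "simulate") {
    if (is.null(simParams)) simParams <- simParams()
    methods::validObject(simParams)
  } else {
    if (is.null(genomeDir)) stop("real mode requires genomeDir")
    if (!dir.exists(genomeDir))
      stop("genome directory not found: ", genomeDir)
    for (f in c(treeFile, metadataFile))
      if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
    if (orthology == "known")
      stop("real mode requires orthology = 'rbh' (or a precomputed table)")
  }
  structure(list(mode = mode, simParams = simParams,
                 plantHgt = as.integer(plantHgt),
                 minPlantDistance = minPlantDistance,
                 genomeDir = genomeDir, treeFile = treeFile,
                 metadataFile = metadataFile, orthology = orthology,
                 idThreshold = idThreshold,
                 separationThreshold = separationThreshold, alpha = alpha,
                 minSep = as.integer(minSep),
                 assignRadius = as.integer(assignRadius),
                 fragLen = as.integer(fragLen), genusName = genusName),
            class = "stasisRunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [runConfig()], with
#'   simulator parameters nested under `sim_params`.
#' @return a `stasisRunConfig` list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sp <- NULL
  if (!is.null(y$sim_params)) sp <- do.call(simParams, y$sim_params)
  args <- y[setdiff(names(y), "sim_params")]
  do.call(runConfig, c(args, list(simParams = sp)))
}

#' Run the full analysis end to end
#'
#' Simulate mode: draws the species tree and genus, optionally plants
#' recent whole-array transfers, writes the fixtures, then runs the
#' genome-divergence, transfer-scan, rate-model and variant stages and
#' writes all report tables plus a run manifest. Real mode ingests FASTA
#' genomes instead of simulating. Identical config + seed give
#' byte-identical output.
#'
#' @param config a `stasisRunConfig` (see [runConfig()]) or path to a YAML
#'   config.
#' @param outDir output directory.
#' @param seed master integer seed governing every stochastic draw.
#' @return invisibly, a list with the main in-memory results
#'   (`sim`, `pairs`, `summary`, `fits`, `catalog`, `profiles`, `files`).
#' @export
runEndToEnd <- function(config, outDir, seed = 1L) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "stasisRunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  if (config$mode == "simulate") {
    p <- config$simParams
    tree <- simulateTree(p@nSpecies, p@birthRate, p@treeDepth, seed = seed)
    sim <- simulateGenus(tree, p, seed = seed + 1L)
    if (config$plantHgt > 0L) {
      set.seed(seed + 2L)
      dm <- ape::cophenetic.phylo(tree)
      cand <- which(dm > config$minPlantDistance & upper.tri(dm),
                    arr.ind = TRUE)
      if (nrow(cand) < config$plantHgt)
        stop("not enough well-separated pairs to plant ", config$plantHgt,
             " transfers")
      pick <- cand[sample.int(nrow(cand), config$plantHgt), , drop = FALSE]
      sim <- plantHgtEvents(sim, rownames(dm)[pick[, 1L]],
                            colnames(dm)[pick[, 2L]])
    }
    fixDir <- file.path(outDir, "fixtures")
    writeFixture(sim, fixDir)
    tree <- sim@tree
    genomes <- sim@genomes
    metadata <- NULL
  } else {
    fas <- sort(list.files(config$genomeDir, pattern = "\\.fasta$",
                           full.names = TRUE))
    if (length(fas) == 0L)
      stop("no .fasta files in ", config$genomeDir)
    genomes <- lapply(fas, readGenomeFasta)
    names(genomes) <- vapply(genomes, speciesId, character(1))
    tree <- if (!is.null(config$treeFile))
      readNewickTree(config$treeFile) else NULL
    metadata <- if (!is.null(config$metadataFile)) {
      md <- readTsv(config$metadataFile)
      stats::setNames(as.character(md[[2L]]), md[[1L]])
    } else NULL
    sim <- NULL
  }

  ani <- aniMatrix(genomes, fragLen = config$fragLen)
  sco <- if (config$orthology == "known") scoTableFromSimulation(genomes)
         else findScoRbh(lapply(genomes, markerGenes))
  ml <- concatMlDistance(sco)

  pairs <- buildPairTable(genomes, ani, ml)
  det <- detectHgtPairs(pairs, config$idThreshold,
                        config$separationThreshold)
  pairs <- det$pairs
  summary <- summarizeGenus(config$genusName, genomes, pairs, sco)

  ok <- stats::complete.cases(pairs[, c("ml_distance", "rrna_divergence")])
  linFit <- fitLinearOrigin(pairs$ml_distance[ok], pairs$rrna_divergence[ok])
  quadFit <- fitQuadraticOrigin(pairs$ml_distance[ok],
                                pairs$rrna_divergence[ok])
  chosen <- selectModel(linFit, quadFit, config$alpha)
  fits <- data.frame(
    model = c(linFit@model, quadFit@model),
    coef1 = c(linFit@coefficients[[1L]], quadFit@coefficients[[1L]]),
    coef2 = c(NA_real_, quadFit@coefficients[[2L]]),
    rss = c(linFit@rss, quadFit@rss), n = c(linFit@n, quadFit@n),
    f_statistic = chosen@fStatistic, p_value = chosen@pValue,
    selected = c(chosen@model == linFit@model,
                 chosen@model == quadFit@model),
    stringsAsFactors = FALSE)

  catalog <- buildCatalog(genomes, minSep = config$minSep,
                          assignRadius = config$assignRadius)
  profiles <- assignProfiles(genomes, catalog)
  labs <- variantLabels(catalog)
  spectrum <- if (length(labs) >= 2L)
    mixtureSpectrum(profiles, labs[1:2]) else NULL
  randomness <- if (!is.null(tree) && length(labs) >= 2L)
    phyloRandomnessTest(tree, profiles, nPerm = 999L, seed = seed + 3L)
    else NULL
  enrichment <- if (!is.null(metadata))
    labelEnrichment(profiles, metadata, labs[1L]) else NULL

  files <- c(
    pairs = file.path(outDir, "pairs.tsv"),
    flagged = file.path(outDir, "flagged_pairs.tsv"),
    summary = file.path(outDir, "genus_summary.tsv"),
    fits = file.path(outDir, "fits.tsv"),
    catalog = file.path(outDir, "catalog.fasta"),
    catalog_diffs = file.path(outDir, "catalog_diffs.tsv"),
    profiles = file.path(outDir, "profiles.tsv"),
    report = file.path(outDir, "report.json"),
    manifest = file.path(outDir, "manifest.yaml"))
  writeTsv(pairs, files[["pairs"]])
  writeTsv(det$flagged, files[["flagged"]])
  writeTsv(summary, files[["summary"]])
  writeTsv(fits, files[["fits"]])
  writeFastaSequences(variantSequences(catalog), files[["catalog"]])
  writeTsv(cbind(variant = rownames(catalog@diffMatrix),
                 as.data.frame(catalog@diffMatrix)),
           files[["catalog_diffs"]])
  writeTsv(profiles, files[["profiles"]])
  if (!is.null(spectrum)) {
    files["spectrum"] <- file.path(outDir, "spectrum.tsv")
    writeTsv(spectrum, files[["spectrum"]])
  }

  report <- list(
    genus = config$genusName,
    n_species = length(genomes),
    n_hgt_pairs = det$n,
    selected_model = chosen@model,
    model_p_value = chosen@pValue,
    n_variants = length(labs),
    phylo_randomness_p = if (is.null(randomness)) NULL else randomness$p,
    enrichment_p = if (is.null(enrichment)) NULL else enrichment$p)
  jsonlite::write_json(report, files[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    package = "stasis16S",
    version = as.character(utils::packageVersion("stasis16S")),
    seed = seed,
    mode = config$mode,
    thresholds = list(id = config$idThreshold,
                      separation = config$separationThreshold,
                      alpha = config$alpha, min_sep = config$minSep,
                      assign_radius = config$assignRadius),
    sim_params = if (config$mode == "simulate") {
      p <- config$simParams
      list(n_species = p@nSpecies, tree_depth = p@treeDepth,
           n_genes = p@nGenes, gene_len = p@geneLen, rrna_len = p@rrnaLen,
           rrna_copy_number = p@rrnaCopyNumber,
           rrna_rate_factor = p@rrnaRateFactor,
           conversion_rate = p@conversionRate, hgt_rate = p@hgtRate,
           plant_hgt = config$plantHgt)
    } else NULL)
  yaml::write_yaml(manifest, files[["manifest"]])

  invisible(list(sim = sim, pairs = pairs, flagged = det$flagged,
                 summary = summary, fits = fits, selected = chosen,
                 catalog = catalog, profiles = profiles,
                 spectrum = spectrum, randomness = randomness,
                 enrichment = enrichment, files = files))
}
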