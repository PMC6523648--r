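## Pipeline driver: simulate -> curate -> classify -> mask -> landscape ->
## overlap -> ervscan, with a manifest for reproducibility.

#' Demo pipeline configuration
#'
#' A small self-contained configuration (simulated genome, three ERV
#' families and one CR1 family) exercising every pipeline stage in well
#' under a minute.
#'
#' @param seed integer seed.
#' @param outDir output directory.
#' @return a config list for [runPipeline()].
#' @export
demoConfig <- function(seed = 1, outDir = tempfile("tecur_demo_")) {
  fams <- list(
    familySpec("ERV_A", "ERV", ltrLength = 250, internalLength = 1500,
               tsdLength = 4, copyNumber = 18, divergence = 0.03,
               soloLtrProb = 0.3),
    familySpec("ERV_B", "ERV", ltrLength = 300, internalLength = 1800,
               tsdLength = 6, copyNumber = 15, divergence = 0.05,
               soloLtrProb = 0.4),
    familySpec("ERV_C", "ERV", ltrLength = 200, internalLength = 1200,
               tsdLength = 5, copyNumber = 12, divergence = 0.08,
               soloLtrProb = 0.5),
    familySpec("CR1_A", "CR1", totalLength = 3000, copyNumber = 25,
               divergence = 0.06, cr1TruncationMean = 700))
  list(seed = as.integer(seed), outDir = outDir,
       simulate = list(genomeLength = 6e5, gcContent = 0.42, families = fams),
       stages = c("simulate", "curate", "classify", "mask", "landscape",
                  "ervscan"),
       speciesCode = "Ucy")
}

## md5 of an R object via its canonical JSON serialization
objectDigest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

#' Run the annotation pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic genome +
#' seed library), `curate`, `classify`, `mask`, `landscape` (landscape +
#' summary tables), `overlap` (requires a reference library to define the
#' baseline masking), `ervscan` (pseudo full-length ERV coverage and copy
#' structure for the first curated LTR family with curatable LTR/internal
#' parts). Every output file is recorded in `manifest.json` with its md5;
#' the manifest also carries the parameter digest, so identical inputs and
#' seed give a byte-identical manifest hash. Any stage failure aborts with
#' the stage name.
#'
#' @param config a config list (see [demoConfig()]) or path to a YAML/JSON
#'   file with the same structure.
#' @return list: `manifest` (named md5 map + parameter digest),
#'   `manifestHash`, `outputs` (per-stage R objects).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$outDir), !is.null(config$seed))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "curate", "classify", "mask",
                                 "landscape")
  files <- character(0)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genome <- NULL; seeds <- NULL; sim <- NULL
  if ("simulate" %in% stages) {
    sim <- stage("simulate", {
      sc <- config$simulate
      cfg <- simConfig(genomeLength = sc$genomeLength %||% 1e6,
                       gcContent = sc$gcContent %||% 0.42,
                       seed = config$seed, families = sc$families,
                       kappa = sc$kappa %||% 2,
                       cpgMultiplier = sc$cpgMultiplier %||% 10,
                       apobecRate = sc$apobecRate %||% 0)
      simulateGenome(cfg)
    })
    files <- c(files, writeSimulation(sim, file.path(config$outDir, "sim")))
    genome <- simGenome(sim)
    cfgSim <- simConfigOf(sim)
    class(cfgSim) <- "simConfig"
    seeds <- makeSeedLibrary(simTruth(sim), cfgSim)
    outputs$simulate <- sim
  } else {
    genome <- stage("input", readGenome(config$genome))
    if (!is.null(config$seeds))
      seeds <- stage("input", readConsensusLibrary(config$seeds))
  }
  reference <- if (!is.null(config$reference))
    stage("input", readConsensusLibrary(config$reference)) else NULL

  curated <- NULL
  if ("curate" %in% stages) {
    cur <- stage("curate", curateLibrary(seeds, genome, known = reference))
    curated <- cur$library
    p <- file.path(config$outDir, "curation_report.tsv")
    write.table(cur$report, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
    if (!is.null(curated)) {
      p2 <- file.path(config$outDir, "curated.fa")
      files <- c(files, writeConsensusLibrary(curated, p2))
    }
    outputs$curate <- cur
  }

  classified <- curated
  if ("classify" %in% stages && !is.null(curated)) {
    cls <- stage("classify", classifyLibrary(
      curated, reference = reference,
      speciesCode = config$speciesCode %||% "Ucy"))
    classified <- cls$library
    p <- file.path(config$outDir, "classification.tsv")
    write.table(cls$subfamilies, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(config$outDir, "classified.fa")
    files <- c(files, p, writeConsensusLibrary(classified, p2))
    outputs$classify <- cls
  }

  track <- NULL
  if ("mask" %in% stages && !is.null(classified)) {
    track <- stage("mask", maskGenome(classified, genome))
    files <- c(files, writeMaskTrack(track, config$outDir, "mask"))
    outputs$mask <- track
  }

  if ("landscape" %in% stages && !is.null(track)) {
    land <- stage("landscape", landscapeTable(track))
    summ <- stage("landscape", summaryTable(track))
    p1 <- file.path(config$outDir, "landscape.tsv")
    p2 <- file.path(config$outDir, "summary.tsv")
    write.table(land, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summ, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p1, p2)
    outputs$landscape <- list(landscape = land, summary = summ)
  }

  if ("overlap" %in% stages && !is.null(track) && !is.null(reference)) {
    ov <- stage("overlap", {
      base <- maskGenome(reference, genome)
      overlapRatio(base, maskHits(track))
    })
    p <- file.path(config$outDir, "overlap.tsv")
    write.table(data.frame(copies = ov$copies, overlaps = ov$overlaps,
                           ratio = ov$ratio), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, p)
    outputs$overlap <- ov
  }

  if ("ervscan" %in% stages && !is.null(sim)) {
    outputs$ervscan <- stage("ervscan", {
      info <- consensusInfo(simTruth(sim))
      i <- which(info$class == "LTR")[1]
      if (is.na(i)) NULL else {
        cons <- as.character(consensusSeqs(simTruth(sim))[[i]])
        ltrLen <- info$ltr_length[i]
        pseudo <- buildPseudoFullLength(
          substr(cons, 1, ltrLen),
          substr(cons, ltrLen + 1, nchar(cons) - ltrLen))
        cp <- coverageProfile(pseudo, genome)
        st <- classifyCopyStructure(cp$hits, pseudo$regions, cp$consensusLength)
        list(profile = cp, structure = st)
      }
    })
    if (!is.null(outputs$ervscan)) {
      p <- file.path(config$outDir, "erv_structure.tsv")
      write.table(outputs$ervscan$structure, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, p)
    }
  }

  ## manifest: every declared output file with its md5, plus parameter digest
  md5 <- tools::md5sum(sort(unique(files)))
  names(md5) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                     config$outDir), "/?"), "", names(md5))
  manifest <- list(package = "tecur",
                   version = as.character(utils::packageVersion("tecur")),
                   seed = config$seed,
                   parameters = objectDigest(config[setdiff(names(config),
                                                            "outDir")]),
                   files = as.list(md5))
  mPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, pretty = TRUE)
  list(manifest = manifest, manifestHash = unname(tools::md5sum(mPath)),
       outputs = outputs)
}
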