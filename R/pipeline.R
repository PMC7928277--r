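## one-command pipeline: corpus -> RFC -> profiles -> pairs -> rules ->
## network, with a Markdown report and a machine-readable run manifest.
## Rounding for display happens in exactly one place (the *_display columns
## computed upstream); the report and all CSVs reuse those values.

#' Build a pipeline configuration
#'
#' Either the three input paths (`registryPath`, `prescriptionsPath`,
#' `synonymsPath`) or a [GeneratorConfig-class] must be supplied. Defaults
#' are the published analysis parameters: RFC cutoff 0.2 (inclusive), pair
#' threshold 41 (strict), edge threshold 18 (strict), rule confidence 1.
#'
#' @param registryPath,prescriptionsPath,synonymsPath Input CSV paths.
#' @param generator A [GeneratorConfig-class] object (alternative input).
#' @param rfcCutoff RFC cutoff for the frequent filter; default 0.2.
#' @param pairThreshold Support threshold for high-frequency pairs;
#'   default 41.
#' @param edgeThreshold Support threshold for network edges; default 18.
#' @param minConfidence Minimum rule confidence; default 1.
#' @param strict Use strict `>` for the count thresholds (default `TRUE`).
#' @param outDir Output directory.
#' @param seed Seed recorded in the manifest (and used when generating).
#' @param logLevel `"info"` or `"quiet"`.
#' @param dialect `"csv"` or `"tsv"` for the input files.
#' @return A `PipelineConfig` list.
#' @examples
#' cfg <- pipelineConfig(generator = referenceConfig(seed = 1),
#'                       outDir = tempfile("run"))
#' cfg$rfcCutoff
#' @export
pipelineConfig <- function(registryPath = NULL, prescriptionsPath = NULL,
                           synonymsPath = NULL, generator = NULL,
                           rfcCutoff = 0.2, pairThreshold = 41,
                           edgeThreshold = 18, minConfidence = 1,
                           strict = TRUE, outDir = "ethnomine-run",
                           seed = 1L, logLevel = c("info", "quiet"),
                           dialect = c("csv", "tsv")) {
  logLevel <- match.arg(logLevel)
  dialect <- match.arg(dialect)
  havePaths <- !is.null(registryPath) && !is.null(prescriptionsPath) &&
    !is.null(synonymsPath)
  if (!havePaths && is.null(generator)) {
    stop("parameter error: supply the three input paths or a generator ",
         "config", call. = FALSE)
  }
  if (rfcCutoff < 0 || rfcCutoff > 1) {
    stop("parameter error: rfcCutoff must lie in [0, 1]", call. = FALSE)
  }
  if (pairThreshold < 0 || edgeThreshold < 0) {
    stop("parameter error: thresholds must be non-negative", call. = FALSE)
  }
  structure(list(
    registryPath = registryPath, prescriptionsPath = prescriptionsPath,
    synonymsPath = synonymsPath, generator = generator,
    rfcCutoff = rfcCutoff, pairThreshold = pairThreshold,
    edgeThreshold = edgeThreshold, minConfidence = minConfidence,
    strict = strict, outDir = outDir, seed = as.integer(seed),
    logLevel = logLevel, dialect = dialect
  ), class = "PipelineConfig")
}

pipelineLog <- function(config, ...) {
  if (config$logLevel != "quiet") {
    message("[ethnomineR] ", ...)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) the corpus, computes the RFC table and the frequent
#' subset, the categorical profiles, pair statistics, high-frequency pairs,
#' confidence rules, and the co-prescription network, then writes
#' `rfc_table.csv`, `profiles.csv`, `pairs.csv`, `rules.csv`,
#' `network.graphml`, `edges.tsv`, `nodes.tsv`, `report.md`, and
#' `manifest.json` (parameters, seed, input digests, package version) into
#' the output directory. On any stage failure the partial outputs are
#' removed and the error is re-raised with the stage name.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`corpus`, `rfc`,
#'   `frequent`, `profiles`, `pairs`, `highFrequency`, `rules`, `network`,
#'   `files`).
#' @examples
#' cfg <- pipelineConfig(generator = referenceConfig(seed = 1),
#'                       outDir = tempfile("run"), logLevel = "quiet")
#' res <- runPipeline(cfg)
#' res$frequent$material_id[1:3]
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE)
  }
  files <- file.path(config$outDir,
                     c("rfc_table.csv", "profiles.csv", "pairs.csv",
                       "rules.csv", "network.graphml", "edges.tsv",
                       "nodes.tsv", "report.md", "manifest.json"))
  names(files) <- c("rfc", "profiles", "pairs", "rules", "graphml", "edges",
                    "nodes", "report", "manifest")
  stage <- "setup"
  tryCatch({
    stage <- "corpus_io"
    if (!is.null(config$generator)) {
      pipelineLog(config, "generating corpus (seed ",
                  config$generator@seed, ")")
      corpus <- generateCorpus(config$generator)
      inputDigests <- list()
    } else {
      pipelineLog(config, "loading corpus from ", config$registryPath)
      reg <- loadRegistry(config$registryPath, config$dialect)
      syn <- loadSynonyms(config$synonymsPath, config$dialect)
      corpus <- loadPrescriptions(config$prescriptionsPath, syn, reg,
                                  config$dialect)
      inputs <- c(config$registryPath, config$prescriptionsPath,
                  config$synonymsPath)
      inputDigests <- as.list(tools::md5sum(inputs))
    }

    stage <- "ethno_indices"
    rfc <- computeRFC(corpus)
    frequent <- selectFrequent(rfc, config$rfcCutoff)
    pipelineLog(config, nrow(frequent), " frequent materials at RFC >= ",
                config$rfcCutoff)
    freqReg <- registry(corpus)
    freqReg <- freqReg[match(frequent$material_id, freqReg$material_id), ,
                       drop = FALSE]
    profiles <- rbind(
      profileCategorical(freqReg, "kingdom", "per_material"),
      profileCategorical(freqReg, "family", "per_material"),
      profileCategorical(freqReg, "part_used", "per_material"),
      profileCategorical(freqReg, "tcm_property", "per_material"),
      profileCategorical(freqReg, "tcm_flavors", "per_token"),
      if (any(lengths(freqReg$pharmacology_tags) > 0L)) {
        profileCategorical(freqReg, "pharmacology_tags", "per_material")
      }
    )

    stage <- "association_mining"
    pairs <- countPairs(corpus)
    hf <- highFrequencyPairs(pairs, config$pairThreshold, config$strict)
    rules <- associationRules(pairs, minSupport = 1,
                              minConfidence = config$minConfidence)
    network <- buildNetwork(pairs, rfc, config$edgeThreshold,
                            config$rfcCutoff, config$strict)
    pipelineLog(config, nrow(hf), " high-frequency pairs; ",
                nrow(networkEdges(network)), " network edges")

    stage <- "report"
    writeDelimited(rfc, files["rfc"])
    writeDelimited(profiles, files["profiles"])
    writeDelimited(pairs, files["pairs"])
    writeDelimited(rules, files["rules"])
    exportNetwork(network, graphml = files["graphml"],
                  edgeList = files["edges"], nodeList = files["nodes"])
    writePipelineReport(files["report"], config, corpus, frequent, freqReg,
                        profiles, hf, rules, network)
    manifest <- list(
      package = "ethnomineR",
      version = as.character(utils::packageVersion("ethnomineR")),
      seed = config$seed,
      parameters = list(rfc_cutoff = config$rfcCutoff,
                        pair_threshold = config$pairThreshold,
                        edge_threshold = config$edgeThreshold,
                        min_confidence = config$minConfidence,
                        strict = config$strict),
      n_prescriptions = nPrescriptions(corpus),
      n_materials = length(materialIds(corpus)),
      input_digests = inputDigests,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                         pretty = TRUE)

    invisible(list(corpus = corpus, rfc = rfc, frequent = frequent,
                   profiles = profiles, pairs = pairs, highFrequency = hf,
                   rules = rules, network = network, files = files))
  }, error = function(e) {
    unlink(files[file.exists(files)])
    stop("pipeline failed in stage ", sQuote(stage), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

mdTable <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

writePipelineReport <- function(path, config, corpus, frequent, freqReg,
                                profiles, hf, rules, network) {
  op <- if (config$strict) ">" else ">="
  freqTable <- data.frame(
    scientific_name = freqReg$scientific_name,
    local_name = freqReg$local_name,
    family = freqReg$family,
    part_used = freqReg$part_used,
    RFC = sprintf("%.2f", frequent$rfc_display),
    flavor_and_property = unname(mapply(formatFlavorProperty,
                                        freqReg$tcm_flavors,
                                        freqReg$tcm_property)),
    stringsAsFactors = FALSE
  )
  propShow <- profiles[profiles$variable %in%
                         c("tcm_property", "tcm_flavors", "kingdom"), ,
                       drop = FALSE]
  propShow$percent <- paste0(propShow$percent_display, "%")
  lines <- c(
    "# Galactogenous prescription corpus report", "",
    sprintf("- prescriptions: %d", nPrescriptions(corpus)),
    sprintf("- registry materials: %d", length(materialIds(corpus))),
    sprintf("- frequent materials (RFC >= %s): %d", config$rfcCutoff,
            nrow(frequent)),
    sprintf("- high-frequency pairs (support %s %s): %d", op,
            config$pairThreshold, nrow(hf)),
    sprintf("- confidence >= %s rules: %d", config$minConfidence,
            nrow(rules)),
    sprintf("- network: %d nodes, %d edges (support %s %s)",
            nrow(networkNodes(network)), nrow(networkEdges(network)), op,
            config$edgeThreshold),
    sprintf("- core ranking: %s",
            paste(coreRanking(network,
                              k = min(3L, nrow(networkNodes(network)))),
                  collapse = ", ")),
    "", "## Frequently used medicinal materials", "",
    mdTable(freqTable),
    "", "## Profiles (kingdom, property per material; flavors per token)", "",
    mdTable(propShow[, c("variable", "convention", "category", "count",
                         "denominator", "percent")]),
    ""
  )
  if (nrow(hf) > 0L) {
    lines <- c(lines, "## High-frequency drug pairs", "",
               mdTable(hf[, c("material_a", "material_b", "support")]), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
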