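## seeded synthetic prescription-corpus generator.
##
## Each prescription is drawn by independent Bernoulli inclusion from the
## configured marginals; boosted pairs are then coupled by a mixture draw
## (with probability u the pair is forced jointly present, else the
## independent draws stand, so E[support] = n * (u + (1 - u) * p_a * p_b));
## deterministic implications are applied last, in topological order, so no
## generated prescription ever violates one. Prescriptions below the minimum
## size are redrawn up to 100 times, then generation aborts.

#' Construct a generator configuration
#'
#' @param nPrescriptions Number of prescriptions to draw.
#' @param inclusionProb Named numeric vector: marginal inclusion probability
#'   per material id, each in (0, 1].
#' @param coreSet Optional subset of the pool flagged as the planted core.
#' @param implications Optional `data.frame(antecedent, consequent)` of
#'   deterministic rules (must be acyclic).
#' @param pairBoosts Optional `data.frame(material_a, material_b, boost)`.
#' @param minMaterials Minimum materials per prescription; default 1.
#' @param seed Integer seed threaded through all draws.
#' @return A [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(10, c(herb_a = 0.9, herb_b = 0.5), seed = 1)
#' cfg
#' @export
generatorConfig <- function(nPrescriptions, inclusionProb,
                            coreSet = character(0),
                            implications = NULL, pairBoosts = NULL,
                            minMaterials = 1L, seed = 1L) {
  if (is.null(implications)) {
    implications <- data.frame(antecedent = character(0),
                               consequent = character(0),
                               stringsAsFactors = FALSE)
  }
  if (is.null(pairBoosts)) {
    pairBoosts <- data.frame(material_a = character(0),
                             material_b = character(0),
                             boost = numeric(0), stringsAsFactors = FALSE)
  }
  methods::new("GeneratorConfig",
               nPrescriptions = as.integer(nPrescriptions),
               materialIds = names(inclusionProb),
               inclusionProb = inclusionProb,
               coreSet = coreSet,
               implications = implications,
               pairBoosts = pairBoosts,
               minMaterials = as.integer(minMaterials),
               seed = as.integer(seed))
}

## registry rows for generated material ids: Table-1 materials keep their
## transcribed record, synthetic background materials get placeholder
## taxonomy (clearly labelled synthetic).
syntheticRegistry <- function(materialIds) {
  packaged <- galactagogueRegistry()
  known <- packaged[packaged$material_id %in% materialIds, , drop = FALSE]
  missing <- setdiff(materialIds, known$material_id)
  if (length(missing) > 0L) {
    synth <- data.frame(
      material_id = missing,
      scientific_name = paste("Synthetic taxon", missing),
      local_name = missing,
      family = "Syntheticaceae",
      kingdom = "plant",
      part_used = "radix",
      tcm_property = "plain",
      tcm_flavors = I(rep(list("sweet"), length(missing))),
      usage_text = "synthetic background material",
      pharmacology_tags = I(rep(list(character(0)), length(missing))),
      rfc_precomputed = NA_real_,
      stringsAsFactors = FALSE
    )
    known <- rbind(known, synth)
  }
  out <- known[match(materialIds, known$material_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## topological order of implication antecedents (config validity guarantees
## acyclicity); applying rules in this order reaches the fixpoint in one pass
implicationOrder <- function(imp) {
  if (nrow(imp) == 0L) return(integer(0))
  g <- igraph::graph_from_data_frame(imp[, c("antecedent", "consequent")],
                                     directed = TRUE)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  order(match(imp$antecedent, topo))
}

#' Generate a synthetic survey corpus
#'
#' Draws a reproducible corpus under the regime described by the
#' configuration (see [GeneratorConfig-class] for the draw semantics). The
#' RNG state of the session is saved and restored, so generation never
#' perturbs user code; equal configs give byte-identical corpora.
#'
#' @param config A [GeneratorConfig-class] object.
#' @return A [SurveyCorpus-class] object; prescriptions are named
#'   `RX001, RX002, ...`.
#' @examples
#' cfg <- generatorConfig(20, c(herb_a = 0.9, herb_b = 0.5, herb_c = 0.3),
#'                        seed = 42)
#' corpus <- generateCorpus(cfg)
#' computeRFC(corpus)
#' @rdname generateCorpus
#' @export
setMethod("generateCorpus", "GeneratorConfig", function(config) {
  methods::validObject(config)
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", oldSeed, envir = globalenv())
    }
  })
  set.seed(config@seed)

  n <- config@nPrescriptions
  ids <- config@materialIds
  p <- config@inclusionProb
  imp <- config@implications
  impOrd <- implicationOrder(imp)
  pb <- config@pairBoosts
  maxRetry <- 100L

  drawOne <- function() {
    present <- stats::runif(length(p)) < p
    names(present) <- ids
    if (nrow(pb) > 0L) {
      joint <- stats::runif(nrow(pb)) < pb$boost
      for (j in which(joint)) {
        present[pb$material_a[j]] <- TRUE
        present[pb$material_b[j]] <- TRUE
      }
    }
    for (j in impOrd) {
      if (present[imp$antecedent[j]]) present[imp$consequent[j]] <- TRUE
    }
    present
  }

  inc <- matrix(FALSE, nrow = n, ncol = length(ids),
                dimnames = list(sprintf("RX%03d", seq_len(n)), ids))
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      present <- drawOne()
      if (sum(present) >= config@minMaterials) break
      tries <- tries + 1L
      if (tries >= maxRetry) {
        stop("generation error: could not draw a prescription with >= ",
             config@minMaterials, " materials in ", maxRetry, " attempts",
             call. = FALSE)
      }
    }
    inc[i, ] <- present
  }

  info <- data.frame(
    prescription_id = rownames(inc),
    pharmacy_id = paste0("PH", formatC(seq_len(n), width = 3, flag = "0")),
    region = NA_character_, stringsAsFactors = FALSE
  )
  methods::new("SurveyCorpus", registry = syntheticRegistry(ids),
               incidence = inc, prescriptionInfo = info)
})

#' Reference generator configuration emulating the survey aggregates
#'
#' The packaged study conditions: 90 prescriptions over 81 materials. The 19
#' highest marginals are exactly the transcribed RFC values of the frequent
#' materials (0.93 for *Angelica sinensis* down to 0.20), which also form
#' the core set; the remaining 62 background materials draw from a
#' heavy-tailed power-law grid below the 0.2 cutoff
#' (`0.19 * k^-0.7`, floored at 0.01).
#'
#' @param seed Integer seed; default 1.
#' @return A [GeneratorConfig-class] object.
#' @examples
#' cfg <- referenceConfig(seed = 7)
#' cfg
#' @export
referenceConfig <- function(seed = 1L) {
  reg <- galactagogueRegistry()
  frequent <- stats::setNames(reg$rfc_precomputed, reg$material_id)
  nBackground <- 81L - length(frequent)
  background <- pmax(0.19 * seq_len(nBackground)^(-0.7), 0.01)
  names(background) <- sprintf("background_herb_%02d", seq_len(nBackground))
  generatorConfig(
    nPrescriptions = 90L,
    inclusionProb = c(frequent, background),
    coreSet = names(frequent),
    seed = seed
  )
}

#' Packaged registry of the frequently used galactagogue materials
#'
#' The transcription of the published table of the 19 frequently used
#' medicinal materials (RFC >= 0.2) with taxonomy, part used, flavor and
#' property, traditional usage, pharmacology tags and the printed RFC.
#'
#' @return A registry `data.frame` with 19 rows.
#' @examples
#' reg <- galactagogueRegistry()
#' reg$material_id[1:3]
#' @export
galactagogueRegistry <- function() {
  loadRegistry(system.file("extdata", "galactagogue_registry.csv",
                           package = "ethnomineR", mustWork = TRUE))
}
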