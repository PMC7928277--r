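#' Survey corpus of galactogenous prescriptions
#'
#' The central container of the package: a registry of standardized medicinal
#' materials together with a prescription-by-material logical incidence
#' matrix. A prescription is a *set* of canonical material ids (within-
#' prescription repeats collapse on load), so every downstream statistic —
#' citation counts, relative frequency of citation (RFC), pair support,
#' association-rule confidence — is a per-prescription presence count.
#'
#' @slot registry A `data.frame`, one row per material, with columns
#'   `material_id`, `scientific_name`, `local_name`, `family`, `kingdom`,
#'   `part_used`, `tcm_property`, `tcm_flavors` (list of character vectors),
#'   `usage_text`, `pharmacology_tags` (list of character vectors) and
#'   `rfc_precomputed` (numeric, `NA` when not transcribed from a published
#'   table).
#' @slot incidence A logical matrix, prescriptions in rows (rownames =
#'   prescription ids) and registry materials in columns (colnames =
#'   material ids, in registry order). Materials never cited keep an
#'   all-`FALSE` column so they stay visible with RFC 0.
#' @slot prescriptionInfo A `data.frame` with columns `prescription_id`,
#'   `pharmacy_id` and `region` (may be `NA`), aligned with the incidence
#'   rows.
#'
#' @section Accessors:
#' `registry(x)`, `incidence(x)`, `prescriptionInfo(x)`, `nPrescriptions(x)`,
#' `materialIds(x)`, and `prescriptionSets(x)` (a named list of material-id
#' sets, one per prescription).
#'
#' @seealso [loadPrescriptions()], [generateCorpus()], [computeRFC()],
#'   [countPairs()]
#' @examples
#' corpus <- readCorpus(system.file("extdata", package = "ethnomineR"),
#'                      registry = "galactagogue_registry.csv",
#'                      prescriptions = "toy_prescriptions.csv",
#'                      synonyms = "toy_synonyms.csv")
#' nPrescriptions(corpus)
#' prescriptionSets(corpus)[["P1"]]
#' @name SurveyCorpus-class
#' @aliases SurveyCorpus
#' @export
setClass("SurveyCorpus",
  representation(
    registry = "data.frame",
    incidence = "matrix",
    prescriptionInfo = "data.frame"
  )
)

setValidity("SurveyCorpus", function(object) {
  reg <- object@registry
  inc <- object@incidence
  info <- object@prescriptionInfo
  msgs <- character(0)

  regCols <- c("material_id", "scientific_name", "local_name", "family",
               "kingdom", "part_used", "tcm_property", "tcm_flavors",
               "usage_text", "pharmacology_tags", "rfc_precomputed")
  missing <- setdiff(regCols, names(reg))
  if (length(missing) > 0L) {
    return(paste("registry missing column(s):", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(reg$material_id)) {
    msgs <- c(msgs, "duplicate material_id in registry")
  }
  voc <- tcmVocabulary()
  if (!all(reg$tcm_property %in% voc$property)) {
    msgs <- c(msgs, "registry contains an unknown tcm_property token")
  }
  flavorsOk <- vapply(reg$tcm_flavors, function(fl) {
    length(fl) >= 1L && !anyDuplicated(fl) && all(fl %in% voc$flavor)
  }, logical(1))
  if (!all(flavorsOk)) {
    msgs <- c(msgs, "each material needs >=1 distinct known flavors")
  }
  rfcPre <- reg$rfc_precomputed
  if (any(!is.na(rfcPre) & (rfcPre < 0 | rfcPre > 1))) {
    msgs <- c(msgs, "rfc_precomputed outside [0, 1]")
  }

  if (!is.logical(inc)) {
    msgs <- c(msgs, "incidence must be a logical matrix")
  }
  if (!identical(colnames(inc), reg$material_id)) {
    msgs <- c(msgs, "incidence columns must equal registry material_id, in order")
  }
  if (nrow(inc) > 0L && any(rowSums(inc) == 0L)) {
    msgs <- c(msgs, "every prescription must contain >=1 material")
  }
  if (anyDuplicated(rownames(inc))) {
    msgs <- c(msgs, "duplicate prescription ids")
  }
  rn <- rownames(inc)
  if (is.null(rn)) rn <- character(0)
  if (!identical(rn, as.character(info$prescription_id))) {
    msgs <- c(msgs, "prescriptionInfo rows must align with incidence rows")
  }

  if (length(msgs) > 0L) msgs else TRUE
})

#' Thresholded co-prescription network with core ranking
#'
#' An undirected weighted graph over the frequently used materials: nodes are
#' materials whose RFC passes the node cutoff, edges connect pairs whose
#' co-occurrence support passes the edge threshold, edge weight is the raw
#' support count. The core ranking totally orders the nodes by descending
#' citation count, breaking ties by descending weighted degree and then
#' material id, mirroring the convention that the most frequent material sits
#' at the center of the published network diagram.
#'
#' @slot graph An [igraph::igraph] undirected graph; edge attribute `weight`
#'   holds the support count, vertex attributes `fc` and `rfc` the citation
#'   statistics.
#' @slot nodes A `data.frame` with columns `material_id`, `fc`, `rfc`,
#'   `weighted_degree`, `core_rank`.
#' @slot edges A `data.frame` with columns `material_a`, `material_b`
#'   (canonical order `material_a < material_b`) and `support`.
#' @slot edgeThreshold,nodeCutoff,strict The thresholds the network was built
#'   with (see [buildNetwork()]).
#'
#' @section Accessors:
#' `networkNodes(x)`, `networkEdges(x)`, and [coreRanking()].
#'
#' @seealso [buildNetwork()], [exportNetwork()]
#' @name CoPrescriptionNetwork-class
#' @aliases CoPrescriptionNetwork
#' @export
setClass("CoPrescriptionNetwork",
  representation(
    graph = "ANY",
    nodes = "data.frame",
    edges = "data.frame",
    edgeThreshold = "numeric",
    nodeCutoff = "numeric",
    strict = "logical"
  )
)

setValidity("CoPrescriptionNetwork", function(object) {
  msgs <- character(0)
  if (!igraph::is_igraph(object@graph)) {
    return("graph slot must hold an igraph object")
  }
  if (igraph::is_directed(object@graph)) {
    msgs <- c(msgs, "co-prescription graph must be undirected")
  }
  ed <- object@edges
  if (nrow(ed) > 0L) {
    if (!all(ed$material_a %in% object@nodes$material_id) ||
        !all(ed$material_b %in% object@nodes$material_id)) {
      msgs <- c(msgs, "edge endpoints must be network nodes")
    }
    if (any(ed$support <= 0 | ed$support != round(ed$support))) {
      msgs <- c(msgs, "edge weights must be positive integers")
    }
    if (any(ed$material_a >= ed$material_b)) {
      msgs <- c(msgs, "edges must be stored with material_a < material_b")
    }
  }
  nd <- object@nodes
  if (nrow(nd) > 0L && !identical(sort(nd$core_rank), seq_len(nrow(nd)))) {
    msgs <- c(msgs, "core_rank must be a total ranking 1..n")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Configuration for the synthetic prescription-corpus generator
#'
#' Describes the stochastic regime a generated corpus is drawn from: the
#' material pool with marginal inclusion probabilities, an optional core set
#' of always-expected materials, deterministic implications (if the
#' antecedent is drawn, the consequent is forced in — the regime that yields
#' confidence-1 association rules by construction), and pairwise joint
#' boosts implemented by mixture coupling (with probability `boost` the pair
#' is drawn jointly, otherwise independently, so the expected support of a
#' boosted pair is `n * (u + (1 - u) * p_a * p_b)`).
#'
#' @slot nPrescriptions Number of prescriptions to draw.
#' @slot materialIds Material pool (canonical ids).
#' @slot inclusionProb Named marginal inclusion probabilities in (0, 1],
#'   aligned with `materialIds`.
#' @slot coreSet Subset of the pool flagged as the planted core.
#' @slot implications `data.frame(antecedent, consequent)`; must be acyclic.
#' @slot pairBoosts `data.frame(material_a, material_b, boost)` with
#'   `boost` in [0, 1].
#' @slot minMaterials Minimum prescription size; smaller draws are redrawn
#'   up to 100 times, then generation aborts rather than silently distorting
#'   the distribution.
#' @slot seed Integer seed; one seeded generator is threaded through all
#'   draws, so equal configs yield byte-identical corpora.
#'
#' @seealso [generatorConfig()], [referenceConfig()], [generateCorpus()]
#' @name GeneratorConfig-class
#' @aliases GeneratorConfig
#' @export
setClass("GeneratorConfig",
  representation(
    nPrescriptions = "integer",
    materialIds = "character",
    inclusionProb = "numeric",
    coreSet = "character",
    implications = "data.frame",
    pairBoosts = "data.frame",
    minMaterials = "integer",
    seed = "integer"
  )
)

## Kahn topological check: implications must be acyclic so forcing
## consequents in topological order reaches a fixpoint in one sweep.
implicationsAcyclic <- function(imp) {
  if (nrow(imp) == 0L) return(TRUE)
  nodes <- unique(c(imp$antecedent, imp$consequent))
  edges <- imp
  repeat {
    hasIncoming <- unique(edges$consequent)
    sources <- setdiff(nodes, hasIncoming)
    if (length(sources) == 0L) return(nrow(edges) == 0L)
    edges <- edges[!(edges$antecedent %in% sources), , drop = FALSE]
    nodes <- setdiff(nodes, sources)
    if (length(nodes) == 0L) return(TRUE)
  }
}

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  p <- object@inclusionProb
  if (length(p) != length(object@materialIds) ||
      !identical(names(p), object@materialIds)) {
    msgs <- c(msgs, "inclusionProb must be named by materialIds, in order")
  }
  if (any(p <= 0 | p > 1)) {
    msgs <- c(msgs, "inclusion probabilities must lie in (0, 1]")
  }
  if (anyDuplicated(object@materialIds)) {
    msgs <- c(msgs, "duplicate material ids in pool")
  }
  if (!all(object@coreSet %in% object@materialIds)) {
    msgs <- c(msgs, "coreSet must be a subset of the material pool")
  }
  imp <- object@implications
  if (nrow(imp) > 0L) {
    if (!all(c(imp$antecedent, imp$consequent) %in% object@materialIds)) {
      msgs <- c(msgs, "implication members must be in the material pool")
    }
    if (!implicationsAcyclic(imp)) {
      msgs <- c(msgs, "implications must be acyclic")
    }
  }
  pb <- object@pairBoosts
  if (nrow(pb) > 0L) {
    if (!all(c(pb$material_a, pb$material_b) %in% object@materialIds)) {
      msgs <- c(msgs, "boosted pair members must be in the material pool")
    }
    if (any(pb$boost < 0 | pb$boost > 1)) {
      msgs <- c(msgs, "pair boosts must lie in [0, 1]")
    }
  }
  if (object@nPrescriptions < 1L) {
    msgs <- c(msgs, "nPrescriptions must be >= 1")
  }
  if (object@minMaterials < 1L) {
    msgs <- c(msgs, "minMaterials must be >= 1")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

## ---- accessors --------------------------------------------------------

#' @rdname SurveyCorpus-class
#' @export
setMethod("registry", "SurveyCorpus", function(x) x@registry)

#' @rdname SurveyCorpus-class
#' @export
setMethod("incidence", "SurveyCorpus", function(x) x@incidence)

#' @rdname SurveyCorpus-class
#' @export
setMethod("prescriptionInfo", "SurveyCorpus", function(x) x@prescriptionInfo)

#' @rdname SurveyCorpus-class
#' @export
setMethod("nPrescriptions", "SurveyCorpus", function(x) nrow(x@incidence))

#' @rdname SurveyCorpus-class
#' @export
setMethod("materialIds", "SurveyCorpus", function(x) x@registry$material_id)

#' @rdname SurveyCorpus-class
#' @export
setMethod("prescriptionSets", "SurveyCorpus", function(x) {
  inc <- x@incidence
  sets <- lapply(seq_len(nrow(inc)), function(i) colnames(inc)[inc[i, ]])
  names(sets) <- rownames(inc)
  sets
})

#' @rdname CoPrescriptionNetwork-class
#' @export
setMethod("networkNodes", "CoPrescriptionNetwork", function(x) x@nodes)

#' @rdname CoPrescriptionNetwork-class
#' @export
setMethod("networkEdges", "CoPrescriptionNetwork", function(x) x@edges)

## ---- show methods -----------------------------------------------------

setMethod("show", "SurveyCorpus", function(object) {
  cat("SurveyCorpus:", nrow(object@incidence), "prescriptions x",
      nrow(object@registry), "registry materials\n")
  cited <- sum(colSums(object@incidence) > 0L)
  cat("  materials cited at least once:", cited, "\n")
  cat("  pharmacies:",
      length(unique(object@prescriptionInfo$pharmacy_id)), "\n")
})

setMethod("show", "CoPrescriptionNetwork", function(object) {
  cat("CoPrescriptionNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  op <- if (object@strict) ">" else ">="
  cat("  edge threshold: support", op, object@edgeThreshold,
      "| node cutoff: RFC >=", object@nodeCutoff, "\n")
  if (nrow(object@nodes) > 0L) {
    top <- object@nodes$material_id[order(object@nodes$core_rank)]
    cat("  core:", paste(utils::head(top, 3), collapse = ", "), "\n")
  }
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nPrescriptions, "prescriptions,",
      length(object@materialIds), "materials (seed", object@seed, ")\n")
  cat("  core set:", length(object@coreSet),
      "| implications:", nrow(object@implications),
      "| pair boosts:", nrow(object@pairBoosts), "\n")
})
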