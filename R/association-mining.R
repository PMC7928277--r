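## pairwise co-occurrence mining over prescriptions: support counts,
## high-frequency drug pairs, confidence-based association rules, and the
## thresholded co-prescription network with core-material ranking.
##
## Support is the raw count of prescriptions containing both materials (the
## published pair frequencies are raw counts); confidence of A -> B is
## support / fc(A). All orderings are totally specified so output never
## depends on iteration order.

#' Count pairwise co-occurrence over a corpus
#'
#' Exact support for every unordered material pair present together in at
#' least one prescription, with both directional confidences. Pairs are
#' stored once, with `material_a < material_b` lexicographically; `fc_a` and
#' `fc_b` are carried so confidence-1 can be decided by integer equality
#' (`support == fc`), never by floating-point comparison.
#'
#' @param corpus A [SurveyCorpus-class] object.
#' @return A `data.frame(material_a, material_b, support, fc_a, fc_b,
#'   conf_a_to_b, conf_b_to_a)` sorted by descending support, then
#'   `material_a`, `material_b`. The attribute `n` holds the corpus size.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P3 = c("angelica_sinensis", "lycium_chinense")))
#' countPairs(corpus)
#' @rdname countPairs
#' @export
setMethod("countPairs", "SurveyCorpus", function(corpus) {
  inc <- incidence(corpus)
  ## order columns lexicographically so upper-triangle extraction yields
  ## canonical material_a < material_b directly
  inc <- inc[, order(colnames(inc)), drop = FALSE]
  co <- crossprod(inc * 1L)            # co-occurrence counts; diag = fc
  fc <- diag(co)
  ut <- which(upper.tri(co), arr.ind = TRUE)
  support <- co[ut]
  keep <- support >= 1L
  ut <- ut[keep, , drop = FALSE]
  support <- as.integer(support[keep])
  a <- colnames(co)[ut[, 1]]
  b <- colnames(co)[ut[, 2]]
  out <- data.frame(
    material_a = a,
    material_b = b,
    support = support,
    fc_a = as.integer(fc[ut[, 1]]),
    fc_b = as.integer(fc[ut[, 2]]),
    stringsAsFactors = FALSE
  )
  out$conf_a_to_b <- out$support / out$fc_a
  out$conf_b_to_a <- out$support / out$fc_b
  out <- out[order(-out$support, out$material_a, out$material_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- nPrescriptions(corpus)
  out
})

#' Filter to high-frequency drug pairs
#'
#' Retains pairs whose support passes the count threshold — strictly
#' (`support > threshold`, the literal reading of "co-occurred more than 41
#' times", the default) or inclusively (`support >= threshold`). Output is
#' sorted by descending support.
#'
#' @param stats Pair statistics from [countPairs()].
#' @param threshold Non-negative co-occurrence count threshold; default 41.
#' @param strict If `TRUE` (default) use `>`, else `>=`.
#' @return The retained rows of `stats`.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P3 = c("angelica_sinensis", "lycium_chinense")))
#' highFrequencyPairs(countPairs(corpus), threshold = 1)
#' @export
highFrequencyPairs <- function(stats, threshold = 41, strict = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("parameter error: threshold must be a single non-negative count",
         call. = FALSE)
  }
  keep <- if (strict) stats$support > threshold else stats$support >= threshold
  out <- stats[keep, , drop = FALSE]
  out <- out[order(-out$support, out$material_a, out$material_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- attr(stats, "n")
  out
}

#' Extract directional association rules from pair statistics
#'
#' Emits both directions of every qualifying pair independently: rule
#' `A -> B` has support `support(A, B)` and confidence
#' `support(A, B) / fc(A)`. Confidence-1 rules (the published setting:
#' confidence set to unity finds always-co-prescribed partners) are decided
#' by the integer equality `support == fc(antecedent)`.
#'
#' @param stats Pair statistics from [countPairs()].
#' @param minSupport Minimum support count; default 1.
#' @param minConfidence Minimum confidence in [0, 1]; default 1.
#' @return A `data.frame(antecedent, consequent, support, confidence)`
#'   sorted by descending support, then antecedent, consequent.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P3 = c("angelica_sinensis", "lycium_chinense")))
#' associationRules(countPairs(corpus), minConfidence = 1)
#' @export
associationRules <- function(stats, minSupport = 1, minConfidence = 1) {
  if (!is.numeric(minConfidence) || length(minConfidence) != 1L ||
      minConfidence < 0 || minConfidence > 1) {
    stop("parameter error: minConfidence must lie in [0, 1]", call. = FALSE)
  }
  rules <- data.frame(
    antecedent = c(stats$material_a, stats$material_b),
    consequent = c(stats$material_b, stats$material_a),
    support = c(stats$support, stats$support),
    fc_antecedent = c(stats$fc_a, stats$fc_b),
    stringsAsFactors = FALSE
  )
  rules$confidence <- rules$support / rules$fc_antecedent
  keep <- rules$support >= minSupport &
    if (minConfidence == 1) {
      rules$support == rules$fc_antecedent   # exact, no float comparison
    } else {
      rules$confidence >= minConfidence - 1e-12
    }
  out <- rules[keep, c("antecedent", "consequent", "support", "confidence"),
               drop = FALSE]
  out <- out[order(-out$support, out$antecedent, out$consequent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the thresholded co-prescription network
#'
#' Nodes are the frequently used materials (RFC at or above `nodeCutoff`,
#' matching the published network that shows only the 19 frequent materials;
#' set `nodeCutoff = 0` for the unrestricted graph). Edges connect node pairs
#' whose support passes `edgeThreshold` (strictly by default, the literal
#' "co-appeared more than 18 times"); edge weight is the support count. The
#' core ranking orders nodes by descending citation count, ties by
#' descending weighted degree, then material id.
#'
#' @param stats Pair statistics from [countPairs()].
#' @param rfc RFC table from [computeRFC()] on the same corpus.
#' @param edgeThreshold Co-occurrence count threshold; default 18.
#' @param nodeCutoff RFC cutoff for node inclusion; default 0.2.
#' @param strict If `TRUE` (default) edges require `support > edgeThreshold`,
#'   else `>=`.
#' @return A [CoPrescriptionNetwork-class] object.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P3 = c("angelica_sinensis", "lycium_chinense")))
#' buildNetwork(countPairs(corpus), computeRFC(corpus),
#'              edgeThreshold = 1, nodeCutoff = 0.2)
#' @export
buildNetwork <- function(stats, rfc, edgeThreshold = 18, nodeCutoff = 0.2,
                         strict = TRUE) {
  unknown <- setdiff(unique(c(stats$material_a, stats$material_b)),
                     rfc$material_id)
  if (length(unknown) > 0L) {
    stop("integrity error: pair references material(s) absent from the RFC ",
         "table: ", paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  nodes <- selectFrequent(rfc, nodeCutoff)
  edges <- stats[stats$material_a %in% nodes$material_id &
                 stats$material_b %in% nodes$material_id, , drop = FALSE]
  edges <- highFrequencyPairs(edges, edgeThreshold, strict)
  edgeDf <- data.frame(material_a = edges$material_a,
                       material_b = edges$material_b,
                       support = edges$support,
                       stringsAsFactors = FALSE)

  wdeg <- stats::setNames(numeric(nrow(nodes)), nodes$material_id)
  if (nrow(edgeDf) > 0L) {
    for (i in seq_len(nrow(edgeDf))) {
      wdeg[edgeDf$material_a[i]] <- wdeg[edgeDf$material_a[i]] + edgeDf$support[i]
      wdeg[edgeDf$material_b[i]] <- wdeg[edgeDf$material_b[i]] + edgeDf$support[i]
    }
  }
  nodeDf <- data.frame(material_id = nodes$material_id,
                       fc = nodes$fc, rfc = nodes$rfc,
                       weighted_degree = as.numeric(wdeg[nodes$material_id]),
                       stringsAsFactors = FALSE)
  ord <- order(-nodeDf$fc, -nodeDf$weighted_degree, nodeDf$material_id)
  nodeDf$core_rank <- NA_integer_
  nodeDf$core_rank[ord] <- seq_len(nrow(nodeDf))

  graph <- igraph::graph_from_data_frame(
    d = if (nrow(edgeDf) > 0L) {
      data.frame(from = edgeDf$material_a, to = edgeDf$material_b,
                 weight = edgeDf$support, stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0), weight = numeric(0))
    },
    directed = FALSE,
    vertices = data.frame(name = nodeDf$material_id, fc = nodeDf$fc,
                          rfc = nodeDf$rfc, core_rank = nodeDf$core_rank,
                          stringsAsFactors = FALSE)
  )
  methods::new("CoPrescriptionNetwork", graph = graph, nodes = nodeDf,
               edges = edgeDf, edgeThreshold = edgeThreshold,
               nodeCutoff = nodeCutoff, strict = strict)
}

#' Rank the core medicinal materials of a network
#'
#' Total, deterministic ordering of the network nodes: descending citation
#' count, ties by descending weighted degree, then material id. The top rank
#' is the primary core material; ranks 2-3 the secondary core. This reads
#' the published "distance from the center" as frequency, with connectivity
#' only as a tie-break.
#'
#' @return Character vector of the top `k` material ids, in rank order. If
#'   `k` exceeds the node count, all nodes are returned with a warning.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P3 = c("angelica_sinensis", "lycium_chinense")))
#' net <- buildNetwork(countPairs(corpus), computeRFC(corpus),
#'                     edgeThreshold = 1)
#' coreRanking(net, k = 2)
#' @rdname coreRanking
#' @export
setMethod("coreRanking", "CoPrescriptionNetwork", function(network, k = 3L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("parameter error: k must be >= 1", call. = FALSE)
  }
  nodes <- network@nodes
  ranked <- nodes$material_id[order(nodes$core_rank)]
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds the node count (", length(ranked),
            "); returning all nodes")
    k <- length(ranked)
  }
  ranked[seq_len(k)]
})

#' Export a co-prescription network to files
#'
#' Writes the graph as GraphML (node attributes `fc`, `rfc`, `core_rank`;
#' edge attribute `weight`) and as plain text: an edge-list TSV
#' (`material_a`, `material_b`, `support`) plus a node-attribute TSV.
#'
#' @param network A [CoPrescriptionNetwork-class] object.
#' @param graphml,edgeList,nodeList Output paths; any may be `NULL` to skip.
#' @return Invisibly, the character vector of files written.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(
#'   P1 = c("angelica_sinensis", "tetrapanax_papyrifer"),
#'   P2 = c("angelica_sinensis", "tetrapanax_papyrifer")))
#' net <- buildNetwork(countPairs(corpus), computeRFC(corpus),
#'                     edgeThreshold = 1)
#' out <- exportNetwork(net, graphml = tempfile(fileext = ".graphml"),
#'                      edgeList = tempfile(fileext = ".tsv"))
#' @export
exportNetwork <- function(network, graphml = NULL, edgeList = NULL,
                          nodeList = NULL) {
  stopifnot(methods::is(network, "CoPrescriptionNetwork"))
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(network@graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgeList)) {
    utils::write.table(network@edges, edgeList, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, edgeList)
  }
  if (!is.null(nodeList)) {
    utils::write.table(network@nodes, nodeList, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, nodeList)
  }
  invisible(written)
}
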