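test_that("pair support and confidences match hand enumeration", {
  corpus <- corpusFromSets(list(P1 = c("A", "B"), P2 = c("A", "B"),
                                P3 = c("A", "C")))
  st <- countPairs(corpus)
  ab <- st[st$material_a == "A" & st$material_b == "B", ]
  ac <- st[st$material_a == "A" & st$material_b == "C", ]
  expect_equal(ab$support, 2L)
  expect_equal(ac$support, 1L)
  expect_equal(ab$conf_b_to_a, 1)        # B -> A certain
  expect_equal(ab$conf_a_to_b, 2 / 3)    # A -> B 2 of 3
  # support never exceeds either member's citation count
  expect_true(all(st$support <= pmin(st$fc_a, st$fc_b)))
  # canonical storage: each unordered pair once, a < b
  expect_true(all(st$material_a < st$material_b))
})

test_that("miner equals exhaustive brute-force enumeration on small corpora", {
  for (seed in 1:25) {
    pool <- LETTERS[1:sample(3:8, 1)]
    sets <- randomSets(sample(2:6, 1), pool, seed = 100 + seed)
    st <- countPairs(corpusFromSets(sets, ids = pool))
    oracle <- brutePairs(sets)
    got <- st[, c("material_a", "material_b", "support")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, label = paste("seed", 100 + seed))
  }
})

test_that("high-frequency pair thresholds are strict by default", {
  fake <- data.frame(
    material_a = c("a", "b", "c"), material_b = c("x", "y", "z"),
    support = c(42L, 41L, 40L), fc_a = 50L, fc_b = 50L,
    conf_a_to_b = 1, conf_b_to_a = 1, stringsAsFactors = FALSE
  )
  expect_equal(nrow(highFrequencyPairs(fake, 41, strict = TRUE)), 1L)
  expect_equal(nrow(highFrequencyPairs(fake, 41, strict = FALSE)), 2L)
  # sorted descending, empty in -> empty out
  expect_equal(highFrequencyPairs(fake, 0)$support, c(42L, 41L, 40L))
  expect_equal(nrow(highFrequencyPairs(fake[0, ], 41)), 0L)
  expect_error(highFrequencyPairs(fake, -1), "parameter error")
})

test_that("raising any threshold never adds pairs, rules or edges", {
  sets <- randomSets(12, letters[1:7], seed = 7)
  corpus <- corpusFromSets(sets, ids = letters[1:7])
  st <- countPairs(corpus)
  rfc <- computeRFC(corpus)
  pairKey <- function(df) paste(df$material_a, df$material_b)
  prevPairs <- pairKey(st)
  for (thr in 0:6) {
    cur <- pairKey(highFrequencyPairs(st, thr))
    expect_true(all(cur %in% prevPairs), label = paste("pair thr", thr))
    prevPairs <- cur
  }
  prevRules <- NULL
  for (minc in c(0, 0.25, 0.5, 0.75, 1)) {
    r <- associationRules(st, minSupport = 1, minConfidence = minc)
    key <- paste(r$antecedent, r$consequent)
    if (!is.null(prevRules)) expect_true(all(key %in% prevRules))
    prevRules <- key
  }
  prevEdges <- NULL
  for (thr in 0:6) {
    net <- buildNetwork(st, rfc, edgeThreshold = thr, nodeCutoff = 0)
    key <- pairKey(networkEdges(net))
    if (!is.null(prevEdges)) expect_true(all(key %in% prevEdges))
    prevEdges <- key
  }
})

test_that("association rules carry exact confidences in both directions", {
  # fc(A) = 4, support(A,B) = 3 -> confidence 0.75
  sets <- list(P1 = c("A", "B"), P2 = c("A", "B"), P3 = c("A", "B"),
               P4 = "A", P5 = "B")
  st <- countPairs(corpusFromSets(sets))
  rules <- associationRules(st, minSupport = 1, minConfidence = 0)
  aToB <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(aToB$confidence, 0.75)
  expect_equal(aToB$support, 3L)
  # both directions emitted independently
  expect_equal(nrow(rules), 2L * nrow(st))
  # min_support above the maximum support -> empty
  expect_equal(nrow(associationRules(st, minSupport = 99)), 0L)
  expect_error(associationRules(st, minConfidence = 2), "parameter error")
})

test_that("confidence-1 rules hold iff no counterexample prescription exists", {
  # B planted in every prescription containing A
  sets <- list(P1 = c("A", "B"), P2 = c("A", "B", "C"), P3 = c("B", "C"),
               P4 = "C")
  st <- countPairs(corpusFromSets(sets))
  r1 <- associationRules(st, minConfidence = 1)
  expect_true(any(r1$antecedent == "A" & r1$consequent == "B"))
  expect_true(confidenceOneHolds(sets, "A", "B"))

  # one counterexample kills the rule
  sets2 <- c(sets, list(P5 = c("A", "C")))
  r2 <- associationRules(countPairs(corpusFromSets(sets2)),
                         minConfidence = 1)
  expect_false(any(r2$antecedent == "A" & r2$consequent == "B"))
  expect_false(confidenceOneHolds(sets2, "A", "B"))

  # soundness on random corpora: rule set == direct-scan predicate
  for (seed in 1:10) {
    pool <- letters[1:5]
    rs <- randomSets(6, pool, seed = 200 + seed)
    rules <- associationRules(countPairs(corpusFromSets(rs, ids = pool)),
                              minConfidence = 1)
    for (a in pool) for (b in setdiff(pool, a)) {
      inRules <- any(rules$antecedent == a & rules$consequent == b)
      coOccur <- any(vapply(rs, function(s) all(c(a, b) %in% s), logical(1)))
      expect_equal(inRules, confidenceOneHolds(rs, a, b) && coOccur,
                   label = paste(seed, a, b))
    }
  }
})

test_that("planted joint inclusion yields support near its binomial expectation", {
  # mixture coupling: p(A and B) = u + (1-u) pa pb = 0.8 with pa = pb = 0.5
  u <- (0.8 - 0.25) / 0.75
  cfg <- generatorConfig(
    nPrescriptions = 90,
    inclusionProb = c(A = 0.5, B = 0.5, filler = 1),
    pairBoosts = data.frame(material_a = "A", material_b = "B", boost = u),
    seed = 11
  )
  st <- countPairs(generateCorpus(cfg))
  ab <- st[st$material_a == "A" & st$material_b == "B", ]
  sd3 <- 3 * sqrt(90 * 0.8 * 0.2)
  expect_lt(abs(ab$support - 72), sd3)
})

test_that("the network keeps frequent nodes and thresholded edges", {
  sets <- list(P1 = c("A", "B", "C"), P2 = c("A", "B"), P3 = c("A", "B"),
               P4 = c("A", "D"), P5 = "E")
  corpus <- corpusFromSets(sets)
  st <- countPairs(corpus)
  rfc <- computeRFC(corpus)

  # infinite threshold -> edgeless graph over the frequent nodes
  netInf <- buildNetwork(st, rfc, edgeThreshold = Inf, nodeCutoff = 0.2)
  expect_equal(nrow(networkEdges(netInf)), 0L)
  expect_gt(nrow(networkNodes(netInf)), 0L)

  # threshold 1 (strict) equals brute-force enumeration above 1
  net1 <- buildNetwork(st, rfc, edgeThreshold = 1, nodeCutoff = 0)
  oracle <- brutePairs(sets)
  oracle <- oracle[oracle$support > 1, ]
  got <- networkEdges(net1)
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got[order(got$material_a, got$material_b), ],
               oracle[order(oracle$material_a, oracle$material_b), ])

  # graph mirrors the edge table
  expect_equal(igraph::gsize(net1@graph), nrow(networkEdges(net1)))
  expect_false(igraph::is_directed(net1@graph))

  # pair referencing a material missing from the RFC table is an error
  badRfc <- rfc[rfc$material_id != "A", ]
  expect_error(buildNetwork(st, badRfc, 1, 0), "integrity error.*A")
})

test_that("core ranking is total, deterministic, fc-major with degree tie-break", {
  sets <- list(P1 = c("A", "B", "C"), P2 = c("A", "B"), P3 = c("A", "C"),
               P4 = c("B", "C"))
  corpus <- corpusFromSets(sets)
  net <- buildNetwork(countPairs(corpus), computeRFC(corpus),
                      edgeThreshold = 0, nodeCutoff = 0)
  # A, B, C all fc 3; all weighted degrees equal -> lexicographic order
  expect_equal(coreRanking(net, 3), c("A", "B", "C"))
  expect_warning(all3 <- coreRanking(net, 10), "exceeds")
  expect_equal(length(all3), 3L)
  expect_error(coreRanking(net, 0), "parameter error")

  # single-node network: that node, rank 1
  solo <- corpusFromSets(list(P1 = "X", P2 = "X"))
  netSolo <- buildNetwork(countPairs(solo), computeRFC(solo), 18, 0.2)
  expect_equal(coreRanking(netSolo, 1), "X")
})

test_that("network exports round-trip through GraphML and TSV", {
  sets <- list(P1 = c("A", "B"), P2 = c("A", "B"), P3 = c("A", "C"))
  corpus <- corpusFromSets(sets)
  net <- buildNetwork(countPairs(corpus), computeRFC(corpus),
                      edgeThreshold = 1, nodeCutoff = 0)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nds <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, graphml = gml, edgeList = tsv, nodeList = nds)

  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(back), nrow(networkEdges(net)))
  expect_setequal(igraph::V(back)$name, networkNodes(net)$material_id)
  expect_equal(sort(igraph::E(back)$weight), sort(networkEdges(net)$support))

  edges <- read.delim(tsv)
  expect_equal(nrow(edges), nrow(networkEdges(net)))
  nodes <- read.delim(nds)
  expect_true(all(c("material_id", "fc", "rfc", "core_rank") %in% names(nodes)))
})
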