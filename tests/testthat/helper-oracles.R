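# independent oracles and tiny-corpus builders shared across tests.
# The oracles deliberately use naive set scans, never the package's
# incidence-matrix code path.

# minimal valid registry for a set of material ids
testRegistry <- function(ids) {
  data.frame(
    material_id = ids,
    scientific_name = paste("Testus", ids),
    local_name = ids,
    family = "Testaceae",
    kingdom = "plant",
    part_used = "radix",
    tcm_property = "plain",
    tcm_flavors = I(rep(list("sweet"), length(ids))),
    usage_text = "",
    pharmacology_tags = I(rep(list(character(0)), length(ids))),
    rfc_precomputed = NA_real_,
    stringsAsFactors = FALSE
  )
}

corpusFromSets <- function(sets, ids = sort(unique(unlist(sets)))) {
  if (is.null(names(sets))) {
    names(sets) <- sprintf("P%02d", seq_along(sets))
  }
  makeCorpus(testRegistry(ids), sets)
}

# naive per-material presence count by direct set scan
bruteFc <- function(sets, ids) {
  vapply(ids, function(m) {
    sum(vapply(sets, function(s) m %in% s, logical(1)))
  }, integer(1))
}

# naive pair support: scan every prescription, enumerate its 2-subsets
brutePairs <- function(sets) {
  counts <- new.env(parent = emptyenv())
  for (s in sets) {
    s <- sort(unique(s))
    if (length(s) < 2L) next
    cmb <- utils::combn(s, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      prev <- if (exists(key, envir = counts)) get(key, envir = counts) else 0L
      assign(key, prev + 1L, envir = counts)
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(data.frame(material_a = character(0), material_b = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    material_a = vapply(parts, `[`, character(1), 1),
    material_b = vapply(parts, `[`, character(1), 2),
    support = vapply(keys, get, integer(1), envir = counts,
                     USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  out[order(-out$support, out$material_a, out$material_b), , drop = FALSE]
}

# direct scan: does any prescription contain a without b?
confidenceOneHolds <- function(sets, a, b) {
  !any(vapply(sets, function(s) (a %in% s) && !(b %in% s), logical(1)))
}

randomSets <- function(nPrescriptions, materialPool, seed) {
  set.seed(seed)
  sets <- replicate(nPrescriptions, {
    k <- sample.int(length(materialPool), 1L)
    sample(materialPool, k)
  }, simplify = FALSE)
  names(sets) <- sprintf("P%02d", seq_along(sets))
  sets
}

# all non-empty subsets of a material pool
allNonEmptySubsets <- function(pool) {
  n <- length(pool)
  lapply(seq_len(2^n - 1L), function(mask) {
    pool[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
  })
}

extdataPath <- function(...) {
  system.file("extdata", ..., package = "ethnomineR", mustWork = TRUE)
}
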