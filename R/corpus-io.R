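## corpus I/O: read, validate and standardize the survey tables
## (registry, long-format prescriptions, synonym map), plus a round-trip
## writer. All files are RFC-4180 CSV (TSV accepted), UTF-8, header row.

#' Parse a compound "flavor(s); property" cell
#'
#' Registry tables carry flavor and thermal property in one cell, e.g.
#' `"Sweet and pungent; warm"`: flavors before the semicolon (joined by
#' "and"), exactly one property after it. The token "plain" is legal on both
#' sides and is disambiguated purely by position.
#'
#' @param x Character vector of compound cells.
#' @return A list with one element per input, each holding `flavors`
#'   (character vector) and `property` (single string), lower-cased and
#'   vocabulary-checked.
#' @examples
#' parseFlavorProperty("Sweet and pungent; warm")
#' parseFlavorProperty("Sweet and plain; plain")
#' @export
parseFlavorProperty <- function(x) {
  voc <- tcmVocabulary()
  lapply(seq_along(x), function(i) {
    parts <- strsplit(x[i], ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("vocabulary error in row ", i,
           ": expected 'flavor(s); property', got ", sQuote(x[i]),
           call. = FALSE)
    }
    flavors <- tolower(trimws(strsplit(parts[1], "\\band\\b")[[1]]))
    flavors <- flavors[nzchar(flavors)]
    property <- tolower(trimws(parts[2]))
    badFlavor <- setdiff(flavors, voc$flavor)
    if (length(badFlavor) > 0L) {
      stop("vocabulary error in row ", i, ": unknown flavor token(s) ",
           paste(sQuote(badFlavor), collapse = ", "), call. = FALSE)
    }
    if (!property %in% voc$property) {
      stop("vocabulary error in row ", i, ": unknown property token ",
           sQuote(property), call. = FALSE)
    }
    if (length(flavors) == 0L || anyDuplicated(flavors)) {
      stop("vocabulary error in row ", i,
           ": need >=1 distinct flavors", call. = FALSE)
    }
    list(flavors = flavors, property = property)
  })
}

## inverse of parseFlavorProperty, used by writeCorpus for round-trips;
## reproduces the published cell style ("Sweet and pungent; warm").
formatFlavorProperty <- function(flavors, property) {
  joined <- paste(flavors, collapse = " and ")
  substr(joined, 1, 1) <- toupper(substr(joined, 1, 1))
  paste0(joined, "; ", property)
}

#' Load a material registry
#'
#' Reads one row per standardized medicinal material and validates it:
#' required columns present (schema error naming the missing column),
#' property/flavor/kingdom tokens in vocabulary (error with row number),
#' unique `material_id` (integrity error), `rfc_precomputed` in [0, 1] when
#' present. The compound `flavor_and_property` cell is parsed exactly (see
#' [parseFlavorProperty()]).
#'
#' @param path Path to a delimited file with header
#'   `material_id, scientific_name, local_name, family, kingdom, part_used,
#'   flavor_and_property, traditional_usage, pharmacology_tags,
#'   rfc_precomputed` (tags separated by `;` within the cell).
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A registry `data.frame` (see [SurveyCorpus-class]).
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' nrow(reg)
#' reg$tcm_flavors[[1]]
#' @export
loadRegistry <- function(path, dialect = c("csv", "tsv")) {
  raw <- readDelimited(path, dialect)
  stopIfMissingColumns(raw, c("material_id", "scientific_name", "local_name",
                              "family", "kingdom", "part_used",
                              "flavor_and_property", "traditional_usage",
                              "pharmacology_tags", "rfc_precomputed"),
                       "registry")
  if (nrow(raw) == 0L) {
    return(emptyRegistry())
  }
  if (anyDuplicated(raw$material_id)) {
    dup <- unique(raw$material_id[duplicated(raw$material_id)])
    stop("integrity error: duplicate material_id ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  voc <- tcmVocabulary()
  kingdom <- tolower(trimws(raw$kingdom))
  badK <- which(!kingdom %in% voc$kingdom)
  if (length(badK) > 0L) {
    stop("vocabulary error in row ", badK[1], ": unknown kingdom ",
         sQuote(raw$kingdom[badK[1]]), call. = FALSE)
  }
  fp <- parseFlavorProperty(raw$flavor_and_property)
  tags <- strsplit(ifelse(is.na(raw$pharmacology_tags), "",
                          raw$pharmacology_tags), ";", fixed = TRUE)
  tags <- lapply(tags, function(t) sort(unique(trimws(t[nzchar(trimws(t))]))))
  rfcPre <- suppressWarnings(as.numeric(raw$rfc_precomputed))
  rfcPre[!nzchar(trimws(as.character(raw$rfc_precomputed)))] <- NA_real_
  if (any(!is.na(rfcPre) & (rfcPre < 0 | rfcPre > 1))) {
    stop("integrity error: rfc_precomputed outside [0, 1]", call. = FALSE)
  }
  data.frame(
    material_id = raw$material_id,
    scientific_name = raw$scientific_name,
    local_name = raw$local_name,
    family = raw$family,
    kingdom = kingdom,
    part_used = tolower(trimws(raw$part_used)),
    tcm_property = vapply(fp, `[[`, character(1), "property"),
    tcm_flavors = I(lapply(fp, `[[`, "flavors")),
    usage_text = raw$traditional_usage,
    pharmacology_tags = I(tags),
    rfc_precomputed = rfcPre,
    stringsAsFactors = FALSE
  )
}

emptyRegistry <- function() {
  data.frame(
    material_id = character(0), scientific_name = character(0),
    local_name = character(0), family = character(0),
    kingdom = character(0), part_used = character(0),
    tcm_property = character(0), tcm_flavors = I(list()),
    usage_text = character(0), pharmacology_tags = I(list()),
    rfc_precomputed = numeric(0), stringsAsFactors = FALSE
  )
}

#' Load a synonym table
#'
#' Maps raw (vernacular, scientific, or variant) names to canonical material
#' ids. The mapping must be single-valued; under the `"normalized"` policy
#' keys are matched after case folding, trimming, and collapse of internal
#' whitespace runs — nothing fuzzier happens silently.
#'
#' @param path Delimited file with header `raw_name, material_id`.
#' @param dialect `"csv"` or `"tsv"`.
#' @param matchPolicy `"normalized"` (default) or `"exact"`.
#' @return A `data.frame(raw_name, material_id)` with attribute
#'   `match_policy`.
#' @examples
#' syn <- loadSynonyms(system.file("extdata", "toy_synonyms.csv",
#'                                 package = "ethnomineR"))
#' attr(syn, "match_policy")
#' @export
loadSynonyms <- function(path, dialect = c("csv", "tsv"),
                         matchPolicy = c("normalized", "exact")) {
  matchPolicy <- match.arg(matchPolicy)
  raw <- readDelimited(path, dialect)
  stopIfMissingColumns(raw, c("raw_name", "material_id"), "synonym table")
  key <- if (matchPolicy == "normalized") normalizeName(raw$raw_name) else raw$raw_name
  conflict <- tapply(raw$material_id, key, function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    stop("integrity error: synonym mapping not single-valued for ",
         paste(sQuote(names(conflict)[conflict]), collapse = ", "),
         call. = FALSE)
  }
  out <- unique(data.frame(raw_name = raw$raw_name,
                           material_id = raw$material_id,
                           stringsAsFactors = FALSE))
  attr(out, "match_policy") <- matchPolicy
  out
}

#' Standardize raw material names
#'
#' Resolves raw names through the synonym table (exact first, then under the
#' table's match policy), falling back to names that already are canonical
#' material ids. Unmappable names raise one error listing every offender —
#' they are never silently dropped.
#'
#' @param rawNames Character vector of raw names.
#' @param synonyms A synonym table from [loadSynonyms()].
#' @param registry A registry `data.frame`; targets must exist here.
#' @return Character vector of canonical material ids.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' syn <- loadSynonyms(system.file("extdata", "toy_synonyms.csv",
#'                                 package = "ethnomineR"))
#' standardizeNames(c("Tang kuei", "  tang  kuei "), syn, reg)
#' @export
standardizeNames <- function(rawNames, synonyms, registry) {
  badTarget <- setdiff(synonyms$material_id, registry$material_id)
  if (length(badTarget) > 0L) {
    stop("integrity error: synonym target(s) not in registry: ",
         paste(sQuote(badTarget), collapse = ", "), call. = FALSE)
  }
  policy <- attr(synonyms, "match_policy")
  if (is.null(policy)) policy <- "normalized"

  mapped <- synonyms$material_id[match(rawNames, synonyms$raw_name)]
  if (policy == "normalized") {
    normKey <- normalizeName(synonyms$raw_name)
    normHit <- synonyms$material_id[match(normalizeName(rawNames), normKey)]
    mapped[is.na(mapped)] <- normHit[is.na(mapped)]
  }
  ## already-canonical ids pass through (standardization idempotence)
  isCanonical <- is.na(mapped) & rawNames %in% registry$material_id
  mapped[isCanonical] <- rawNames[isCanonical]

  if (anyNA(mapped)) {
    offenders <- sort(unique(rawNames[is.na(mapped)]))
    stop("standardization error: unmappable raw name(s): ",
         paste(sQuote(offenders), collapse = ", "), call. = FALSE)
  }
  mapped
}

#' Assemble a survey corpus from prescription sets
#'
#' Low-level constructor behind [loadPrescriptions()] and
#' [generateCorpus()]: builds the prescription-by-material incidence matrix
#' and validates referential integrity.
#'
#' @param registry A registry `data.frame`.
#' @param prescriptionSets Named list (names = prescription ids) of character
#'   vectors of canonical material ids; duplicates within a set collapse.
#' @param prescriptionInfo Optional `data.frame(prescription_id, pharmacy_id,
#'   region)`; defaults to one pharmacy per prescription.
#' @return A [SurveyCorpus-class] object.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(P1 = c("angelica_sinensis",
#'                                       "tetrapanax_papyrifer")))
#' nPrescriptions(corpus)
#' @export
makeCorpus <- function(registry, prescriptionSets, prescriptionInfo = NULL) {
  ids <- names(prescriptionSets)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("integrity error: prescription ids must be unique and non-empty",
         call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(prescriptionSets)), registry$material_id)
  if (length(unknown) > 0L) {
    stop("integrity error: material(s) not in registry: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  empty <- vapply(prescriptionSets, function(s) length(unique(s)) == 0L,
                  logical(1))
  if (any(empty)) {
    stop("integrity error: empty prescription(s) after deduplication: ",
         paste(sQuote(ids[empty]), collapse = ", "), call. = FALSE)
  }
  inc <- matrix(FALSE, nrow = length(ids), ncol = nrow(registry),
                dimnames = list(ids, registry$material_id))
  for (i in seq_along(prescriptionSets)) {
    inc[i, unique(prescriptionSets[[i]])] <- TRUE
  }
  if (is.null(prescriptionInfo)) {
    prescriptionInfo <- data.frame(
      prescription_id = ids,
      pharmacy_id = paste0("PH", formatC(seq_along(ids), width = 3, flag = "0")),
      region = NA_character_, stringsAsFactors = FALSE
    )
  } else {
    stopIfMissingColumns(prescriptionInfo, c("prescription_id", "pharmacy_id"),
                         "prescription info")
    if (!"region" %in% names(prescriptionInfo)) {
      prescriptionInfo$region <- NA_character_
    }
    prescriptionInfo <- prescriptionInfo[
      match(ids, prescriptionInfo$prescription_id),
      c("prescription_id", "pharmacy_id", "region"), drop = FALSE]
    rownames(prescriptionInfo) <- NULL
  }
  methods::new("SurveyCorpus", registry = registry, incidence = inc,
               prescriptionInfo = prescriptionInfo)
}

#' Load a long-format prescription table into a survey corpus
#'
#' Reads rows of `(prescription_id, pharmacy_id, raw_material_name)`
#' (optional `region`), standardizes raw names through the synonym table,
#' collapses repeated mentions of one material within a prescription to a
#' single set member, and validates the corpus invariants.
#'
#' @param path Delimited prescription file.
#' @param synonyms Synonym table from [loadSynonyms()].
#' @param registry Registry `data.frame` from [loadRegistry()].
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [SurveyCorpus-class] object.
#' @examples
#' dir <- system.file("extdata", package = "ethnomineR")
#' reg <- loadRegistry(file.path(dir, "galactagogue_registry.csv"))
#' syn <- loadSynonyms(file.path(dir, "toy_synonyms.csv"))
#' corpus <- loadPrescriptions(file.path(dir, "toy_prescriptions.csv"),
#'                             syn, reg)
#' nPrescriptions(corpus)
#' @export
loadPrescriptions <- function(path, synonyms, registry,
                              dialect = c("csv", "tsv")) {
  raw <- readDelimited(path, dialect)
  stopIfMissingColumns(raw, c("prescription_id", "pharmacy_id",
                              "raw_material_name"), "prescription table")
  if (nrow(raw) == 0L) {
    stop("integrity error: prescription table has no rows", call. = FALSE)
  }
  canonical <- standardizeNames(raw$raw_material_name, synonyms, registry)
  ids <- unique(raw$prescription_id)
  sets <- split(canonical, factor(raw$prescription_id, levels = ids))
  info <- unique(data.frame(
    prescription_id = raw$prescription_id,
    pharmacy_id = raw$pharmacy_id,
    region = if ("region" %in% names(raw)) {
      reg0 <- as.character(raw$region)
      ifelse(!is.na(reg0) & nzchar(trimws(reg0)), reg0, NA_character_)
    } else NA_character_,
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(info$prescription_id)) {
    stop("integrity error: prescription assigned to multiple pharmacies",
         call. = FALSE)
  }
  makeCorpus(registry, sets, info)
}

#' Write a survey corpus to a directory
#'
#' Emits `registry.csv`, `prescriptions.csv` (long format, canonical ids as
#' raw names) and `synonyms.csv` (identity mapping) in the package's CSV
#' schemas. Output is deterministic: `loadCorpus(writeCorpus(x))` reproduces
#' an equal corpus field-wise, and repeated writes are byte-identical.
#'
#' @param corpus A [SurveyCorpus-class] object.
#' @param outDir Output directory (created if absent).
#' @return Invisibly, the named character vector of files written.
#' @seealso [readCorpus()]
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' corpus <- makeCorpus(reg, list(P1 = "angelica_sinensis"))
#' files <- writeCorpus(corpus, file.path(tempdir(), "corpus-demo"))
#' basename(files)
#' @export
writeCorpus <- function(corpus, outDir) {
  stopifnot(methods::is(corpus, "SurveyCorpus"))
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create ", outDir, call. = FALSE)
  }
  reg <- registry(corpus)
  regOut <- data.frame(
    material_id = reg$material_id,
    scientific_name = reg$scientific_name,
    local_name = reg$local_name,
    family = reg$family,
    kingdom = reg$kingdom,
    part_used = reg$part_used,
    flavor_and_property = unname(mapply(formatFlavorProperty, reg$tcm_flavors,
                                        reg$tcm_property)),
    traditional_usage = reg$usage_text,
    pharmacology_tags = vapply(reg$pharmacology_tags, paste,
                               character(1), collapse = ";"),
    rfc_precomputed = ifelse(is.na(reg$rfc_precomputed), "",
                             format(reg$rfc_precomputed, trim = TRUE)),
    stringsAsFactors = FALSE
  )
  sets <- prescriptionSets(corpus)
  info <- prescriptionInfo(corpus)
  long <- data.frame(
    prescription_id = rep(names(sets), lengths(sets)),
    pharmacy_id = rep(info$pharmacy_id, lengths(sets)),
    region = rep(ifelse(is.na(info$region), "", info$region), lengths(sets)),
    raw_material_name = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  syn <- data.frame(raw_name = reg$material_id, material_id = reg$material_id,
                    stringsAsFactors = FALSE)
  files <- c(registry = file.path(outDir, "registry.csv"),
             prescriptions = file.path(outDir, "prescriptions.csv"),
             synonyms = file.path(outDir, "synonyms.csv"))
  writeDelimited(regOut, files["registry"])
  writeDelimited(long, files["prescriptions"])
  writeDelimited(syn, files["synonyms"])
  invisible(files)
}

#' Read a survey corpus from a directory of CSV tables
#'
#' Convenience wrapper around [loadRegistry()], [loadSynonyms()] and
#' [loadPrescriptions()]; the inverse of [writeCorpus()].
#'
#' @param dir Directory holding the three tables.
#' @param registry,prescriptions,synonyms File names within `dir`.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [SurveyCorpus-class] object.
#' @examples
#' corpus <- readCorpus(system.file("extdata", package = "ethnomineR"),
#'                      registry = "galactagogue_registry.csv",
#'                      prescriptions = "toy_prescriptions.csv",
#'                      synonyms = "toy_synonyms.csv")
#' corpus
#' @export
readCorpus <- function(dir, registry = "registry.csv",
                       prescriptions = "prescriptions.csv",
                       synonyms = "synonyms.csv",
                       dialect = c("csv", "tsv")) {
  reg <- loadRegistry(file.path(dir, registry), dialect)
  syn <- loadSynonyms(file.path(dir, synonyms), dialect)
  loadPrescriptions(file.path(dir, prescriptions), syn, reg, dialect)
}
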