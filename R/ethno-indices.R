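## citation statistics and categorical profiles over a survey corpus.
##
## RFC (relative frequency of citation) = FC / N, where FC is the number of
## prescriptions containing the material and N the number of prescriptions
## in the corpus. Counting is exact on integers; rounding happens only in
## the *_display columns.

#' Compute citation counts and relative frequency of citation
#'
#' One row per registry material (materials never cited stay visible with
#' `fc = 0`), with the exact citation count `fc`, the corpus size `n`, and
#' `rfc = fc / n`. Rows are sorted by descending RFC, ties broken by
#' ascending material id. `rfc_display` is RFC rounded half-up to 2 decimals,
#' the convention of published tables; all computation uses the exact
#' fraction.
#'
#' @param corpus A [SurveyCorpus-class] object with at least one
#'   prescription.
#' @return A `data.frame(material_id, fc, n, rfc, rfc_display)`.
#' @examples
#' corpus <- readCorpus(system.file("extdata", package = "ethnomineR"),
#'                      registry = "galactagogue_registry.csv",
#'                      prescriptions = "toy_prescriptions.csv",
#'                      synonyms = "toy_synonyms.csv")
#' head(computeRFC(corpus), 3)
#' @rdname computeRFC
#' @export
setMethod("computeRFC", "SurveyCorpus", function(corpus) {
  n <- nPrescriptions(corpus)
  if (n == 0L) {
    stop("degenerate corpus: zero prescriptions", call. = FALSE)
  }
  fc <- as.integer(colSums(incidence(corpus)))
  out <- data.frame(
    material_id = materialIds(corpus),
    fc = fc,
    n = n,
    rfc = fc / n,
    stringsAsFactors = FALSE
  )
  out$rfc_display <- roundHalfUp(out$rfc, 2)
  out <- out[order(-out$rfc, out$material_id), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Filter an RFC table to the frequently used materials
#'
#' Retains materials with `rfc >= cutoff` (inclusive, the published
#' convention for the RFC filter: a material cited in exactly 20% of
#' prescriptions is frequent at the default cutoff). Row order is preserved.
#' The comparison is done on integer counts (`fc >= cutoff * n`) so boundary
#' cases never depend on floating-point representation of the ratio.
#'
#' @param rfcTable Output of [computeRFC()].
#' @param cutoff RFC cutoff in [0, 1]; default 0.2.
#' @return The retained rows of `rfcTable`.
#' @examples
#' corpus <- readCorpus(system.file("extdata", package = "ethnomineR"),
#'                      registry = "galactagogue_registry.csv",
#'                      prescriptions = "toy_prescriptions.csv",
#'                      synonyms = "toy_synonyms.csv")
#' selectFrequent(computeRFC(corpus), cutoff = 0.5)
#' @export
selectFrequent <- function(rfcTable, cutoff = 0.2) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop("parameter error: cutoff must be a single value in [0, 1]",
         call. = FALSE)
  }
  keep <- rfcTable$fc >= cutoff * rfcTable$n - 1e-9
  out <- rfcTable[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

singleValuedVariables <- c("kingdom", "family", "part_used", "tcm_property")
multiValuedVariables <- c("tcm_flavors", "pharmacology_tags")

#' Profile a categorical registry variable
#'
#' Tabulates a registry variable under an explicit counting convention.
#' `per_material` counts each material once per category it carries
#' (denominator = number of materials, so proportions of a multi-valued
#' variable may sum above 1); `per_token` counts every mention (denominator =
#' total mentions, proportions sum to 1) and is only defined for the
#' multi-valued variables (`tcm_flavors`, `pharmacology_tags`). The published
#' convention is per-material for properties (11/19 warm) and per-token for
#' flavors (14/26 sweet).
#'
#' @param materials A registry `data.frame` (typically the frequent subset).
#' @param variable One of `kingdom`, `family`, `part_used`, `tcm_property`,
#'   `tcm_flavors`, `pharmacology_tags`.
#' @param convention `"per_material"` or `"per_token"`.
#' @return A `data.frame(variable, convention, category, count, denominator,
#'   proportion, percent_display)` sorted by descending count then category;
#'   `percent_display` is the proportion rounded half-up to a whole percent.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' profileCategorical(reg, "tcm_property", "per_material")
#' profileCategorical(reg, "tcm_flavors", "per_token")
#' @export
profileCategorical <- function(materials,
                               variable = c("kingdom", "family", "part_used",
                                            "tcm_property", "tcm_flavors",
                                            "pharmacology_tags"),
                               convention = c("per_material", "per_token")) {
  variable <- match.arg(variable)
  convention <- match.arg(convention)
  if (nrow(materials) == 0L) {
    stop("parameter error: empty material list", call. = FALSE)
  }
  multi <- variable %in% multiValuedVariables
  if (convention == "per_token" && !multi) {
    stop("convention error: per_token is only defined for multi-valued ",
         "variables (tcm_flavors, pharmacology_tags)", call. = FALSE)
  }
  if (multi) {
    mentions <- materials[[variable]]
    if (convention == "per_material") {
      ## one count per material per category it carries
      tokens <- unlist(lapply(mentions, unique), use.names = FALSE)
      denominator <- nrow(materials)
    } else {
      tokens <- unlist(mentions, use.names = FALSE)
      denominator <- length(tokens)
    }
  } else {
    tokens <- materials[[variable]]
    denominator <- nrow(materials)
  }
  tab <- table(tokens)
  out <- data.frame(
    variable = variable,
    convention = convention,
    category = names(tab),
    count = as.integer(tab),
    denominator = denominator,
    stringsAsFactors = FALSE
  )
  out$proportion <- out$count / out$denominator
  out$percent_display <- roundHalfUp(100 * out$proportion)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count materials carrying a pharmacology tag
#'
#' Per-material summary of one condition token: how many materials carry the
#' tag in `pharmacology_tags`, and the proportion over all materials. A tag
#' carried by no material yields a zero count with a warning (not an error),
#' so misspelt tags surface without stopping a pipeline.
#'
#' @param materials A registry `data.frame`.
#' @param tag Condition token, e.g. `"breast_cancer"`.
#' @return A `data.frame(tag, count, denominator, proportion,
#'   percent_display)` with one row.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "galactagogue_registry.csv",
#'                                 package = "ethnomineR"))
#' pharmacologySummary(reg, "breast_cancer")
#' @export
pharmacologySummary <- function(materials, tag) {
  if (nrow(materials) == 0L) {
    stop("parameter error: empty material list", call. = FALSE)
  }
  stopifnot(is.character(tag), length(tag) == 1L)
  hit <- vapply(materials$pharmacology_tags, function(t) tag %in% t,
                logical(1))
  count <- sum(hit)
  if (count == 0L) {
    warning("tag ", sQuote(tag), " not carried by any material")
  }
  data.frame(
    tag = tag,
    count = count,
    denominator = nrow(materials),
    proportion = count / nrow(materials),
    percent_display = roundHalfUp(100 * count / nrow(materials)),
    stringsAsFactors = FALSE
  )
}
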