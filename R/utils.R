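## Controlled vocabularies for material records.

#' Controlled vocabularies for material records
#'
#' Token sets used to validate registry fields: the five thermal properties,
#' the seven flavors, and the recognised kingdoms of origin. "plain" is a
#' legal token in both the property and the flavor vocabulary; the two uses
#' are disambiguated positionally when parsing a compound
#' "flavor(s); property" cell, never lexically.
#'
#' @return A named list of character vectors with elements `property`,
#'   `flavor` and `kingdom`.
#' @examples
#' tcmVocabulary()$property
#' @export
tcmVocabulary <- function() {
  list(
    property = c("hot", "warm", "plain", "cool", "cold"),
    flavor   = c("sour", "bitter", "sweet", "pungent", "salty", "plain",
                 "astringent"),
    kingdom  = c("plant", "animal", "fungus")
  )
}

#' Round half away from zero
#'
#' Display percentages and RFC values are rounded half-up (2.5 -> 3), not to
#' even as base [round()] does; all internal computation stays on the exact
#' fractions.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## Case-fold, trim, and squeeze internal whitespace. This is the entire
## "normalized" match policy: nothing fuzzier happens silently.
normalizeName <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

## shared column checks -------------------------------------------------

stopIfMissingColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

readDelimited <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- if (dialect == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, encoding = "UTF-8",
                    na.strings = character(0), check.names = FALSE,
                    comment.char = "")
}

writeDelimited <- function(df, path) {
  utils::write.table(df, path, sep = ",", qmethod = "double",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
}
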