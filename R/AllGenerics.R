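#' @rdname SurveyCorpus-class
#' @param x,object A `SurveyCorpus` (or, where documented, another package
#'   object).
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))

#' @rdname SurveyCorpus-class
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname SurveyCorpus-class
#' @export
setGeneric("prescriptionInfo", function(x) standardGeneric("prescriptionInfo"))

#' @rdname SurveyCorpus-class
#' @export
setGeneric("nPrescriptions", function(x) standardGeneric("nPrescriptions"))

#' @rdname SurveyCorpus-class
#' @export
setGeneric("materialIds", function(x) standardGeneric("materialIds"))

#' @rdname SurveyCorpus-class
#' @export
setGeneric("prescriptionSets", function(x) standardGeneric("prescriptionSets"))

#' @rdname computeRFC
#' @export
setGeneric("computeRFC", function(corpus) standardGeneric("computeRFC"))

#' @rdname countPairs
#' @export
setGeneric("countPairs", function(corpus) standardGeneric("countPairs"))

#' @rdname generateCorpus
#' @export
setGeneric("generateCorpus", function(config) standardGeneric("generateCorpus"))

#' @rdname CoPrescriptionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoPrescriptionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname coreRanking
#' @param network A `CoPrescriptionNetwork`.
#' @param k Number of top-ranked materials to return.
#' @export
setGeneric("coreRanking", function(network, k = 3L) standardGeneric("coreRanking"))
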