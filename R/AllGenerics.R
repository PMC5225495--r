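#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname accessors
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname accessors
#' @export
setGeneric("envelopes", function(x) standardGeneric("envelopes"))

#' @rdname accessors
#' @export
setGeneric("edgeValues", function(x) standardGeneric("edgeValues"))

#' @rdname accessors
#' @export
setGeneric("edgeMetric", function(x) standardGeneric("edgeMetric"))

#' @rdname kuramotoOrder
#' @export
setGeneric("kuramotoOrder", function(x, ...) standardGeneric("kuramotoOrder"))

#' @rdname metastability
#' @export
setGeneric("metastability", function(x, ...) standardGeneric("metastability"))

#' @rdname pairwiseCoupling
#' @export
setGeneric("pairwiseCoupling", function(x, ...)
  standardGeneric("pairwiseCoupling"))

#' @rdname bandpassFilter
#' @export
setGeneric("bandpassFilter", function(x, lowHz = 0.04, highHz = 0.07, ...)
  standardGeneric("bandpassFilter"))

#' @rdname analyticPhase
#' @export
setGeneric("analyticPhase", function(x, trim = 10L, ...)
  standardGeneric("analyticPhase"))

#' @rdname tsnr
#' @export
setGeneric("tsnr", function(x) standardGeneric("tsnr"))

#' @rdname partialCorrelation
#' @export
setGeneric("partialCorrelation", function(x, lambda = 0.1, ...)
  standardGeneric("partialCorrelation"))

#' @rdname scanDuration
#' @export
setGeneric("scanDuration", function(x) standardGeneric("scanDuration"))
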