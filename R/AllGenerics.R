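#' @rdname dosages
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname markerMap
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))

#' @rdname populations
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname populations
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))
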