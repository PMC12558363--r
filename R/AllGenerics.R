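#' @rdname internalExons
#' @export
setGeneric("internalExons", function(x, ...) standardGeneric("internalExons"))

#' @rdname junctionCatalog
#' @export
setGeneric("junctionCatalog", function(x, ...) standardGeneric("junctionCatalog"))

#' @rdname dedupUmis
#' @export
setGeneric("dedupUmis", function(x, ...) standardGeneric("dedupUmis"))

#' @rdname filterRareChains
#' @export
setGeneric("filterRareChains", function(x, ...) standardGeneric("filterRareChains"))
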