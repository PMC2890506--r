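#' @rdname geneCopy
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname geneCopy
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname geneCopy
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname geneCopy
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname geneCopy
#' @export
setGeneric("geneLength", function(x) standardGeneric("geneLength"))

#' @rdname homoeologAlignment-accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname homoeologAlignment-accessors
#' @export
setGeneric("columnRegion", function(x) standardGeneric("columnRegion"))

#' @rdname homoeologAlignment-accessors
#' @export
setGeneric("colToPos", function(x, genome) standardGeneric("colToPos"))

#' @rdname homoeologAlignment-accessors
#' @export
setGeneric("posToCol", function(x, genome) standardGeneric("posToCol"))

#' @rdname tileGene
#' @export
setGeneric("chosenPairs", function(x) standardGeneric("chosenPairs"))

#' @rdname tileGene
#' @export
setGeneric("coveredBp", function(x) standardGeneric("coveredBp"))

#' @rdname tileGene
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))
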