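#' @rdname computeAF
#' @export
setGeneric("computeAF", function(x, ...) standardGeneric("computeAF"))

#' @rdname applySiteFilters
#' @export
setGeneric("applySiteFilters", function(x, ...)
    standardGeneric("applySiteFilters"))

#' @rdname decomposeBlockSub
#' @export
setGeneric("decomposeBlockSub", function(x, ...)
    standardGeneric("decomposeBlockSub"))

#' @rdname buildAFMatrix
#' @export
setGeneric("buildAFMatrix", function(x, ...) standardGeneric("buildAFMatrix"))

#' @rdname genomeScan
#' @export
setGeneric("genomeScan", function(x, ...) standardGeneric("genomeScan"))

#' @rdname afMatrix
#' @export
setGeneric("afMatrix", function(x, ...) standardGeneric("afMatrix"))

#' @rdname poolInfo
#' @export
setGeneric("poolInfo", function(x, ...) standardGeneric("poolInfo"))
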