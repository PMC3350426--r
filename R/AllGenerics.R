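#' Accessors for ComparisonSet assays and simulation slots
#'
#' Thin accessors in place of direct slot/assay access: \code{ratios} (log2),
#' \code{sigmas}, \code{pValues}, \code{intensities}, \code{wabFlags},
#' \code{comparisonInfo}, and for \linkS4class{ArraySimulation}:
#' \code{arrayTables}, \code{arrayManifest}, \code{simTruth}.
#'
#' @param x a \linkS4class{ComparisonSet} or \linkS4class{ArraySimulation}
#' @return matrices (probes x comparisons) for the assay accessors; data.frames
#'   for the metadata accessors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))
#' @rdname accessors
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("wabFlags", function(x) standardGeneric("wabFlags"))
#' @rdname accessors
#' @export
setGeneric("comparisonInfo", function(x) standardGeneric("comparisonInfo"))
#' @rdname accessors
#' @export
setGeneric("arrayTables", function(x) standardGeneric("arrayTables"))
#' @rdname accessors
#' @export
setGeneric("arrayManifest", function(x) standardGeneric("arrayManifest"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname accessors
#' @export
setMethod("ratios", "ComparisonSet", function(x) assay(x, "ratio"))
#' @rdname accessors
#' @export
setMethod("sigmas", "ComparisonSet", function(x) assay(x, "sigma"))
#' @rdname accessors
#' @export
setMethod("pValues", "ComparisonSet", function(x) assay(x, "p"))
#' @rdname accessors
#' @export
setMethod("intensities", "ComparisonSet", function(x) assay(x, "intensity"))
#' @rdname accessors
#' @export
setMethod("wabFlags", "ComparisonSet", function(x) assay(x, "wab"))
#' @rdname accessors
#' @export
setMethod("comparisonInfo", "ComparisonSet",
          function(x) as.data.frame(colData(x)))
#' @rdname accessors
#' @export
setMethod("arrayTables", "ArraySimulation", function(x) x@arrays)
#' @rdname accessors
#' @export
setMethod("arrayManifest", "ArraySimulation", function(x) x@manifest)
#' @rdname accessors
#' @export
setMethod("simTruth", "ArraySimulation", function(x) x@truth)
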