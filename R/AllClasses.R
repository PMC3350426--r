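#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Per-gene, per-comparison summaries of a dye-swap experiment
#'
#' A \code{ComparisonSet} extends \linkS4class{SummarizedExperiment} and holds
#' one row per probe and one column per comparison, with assays:
#' \describe{
#'   \item{ratio}{error-weighted log2 expression ratio, oriented so that the
#'     numerator sample of the comparison is on top (male/female for the three
#'     sex comparisons, 8 wk/younger age for the four developmental ones);}
#'   \item{sigma}{combined log2-scale standard error of the weighted ratio;}
#'   \item{p}{two-sided normal-theory p-value of the weighted ratio;}
#'   \item{intensity}{mean normalized channel intensity (linear units) over the
#'     contributing arrays;}
#'   \item{wab}{logical, TRUE iff the probe was well above background on every
#'     contributing array.}
#' }
#' \code{rowData} carries \code{probe_id} and \code{gene_symbol}; \code{colData}
#' describes each comparison (label, hybridized samples, ratio orientation).
#'
#' @seealso [summarizeComparisons()] which builds one.
#' @export
setClass("ComparisonSet", contains = "SummarizedExperiment")

setValidity("ComparisonSet", function(object) {
  need <- c("ratio", "sigma", "p", "intensity", "wab")
  have <- names(assays(object))
  if (!all(need %in% have))
    return(paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  p <- assay(object, "p")
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values outside [0, 1]")
  s <- assay(object, "sigma")
  if (any(s <= 0, na.rm = TRUE)) return("non-positive sigma")
  rd <- rowData(object)
  if (!all(c("probe_id", "gene_symbol") %in% colnames(rd)))
    return("rowData must contain probe_id and gene_symbol")
  cd <- colData(object)
  if (!all(c("label", "numerator", "denominator") %in% colnames(cd)))
    return("colData must contain label, numerator, denominator")
  TRUE
})

#' A simulated dye-swap microarray experiment
#'
#' Container returned by [simulateArrays()]: the probe-level intensity table
#' for every array, the array manifest (comparison, replicate, dye
#' orientation), the per-gene truth table (with realized developmental calls
#' and the low-expressed flag), and the design and noise parameter lists used.
#'
#' @slot arrays named list of per-array data.frames with columns
#'   \code{probe_id}, \code{gene_symbol}, \code{red_raw}, \code{green_raw},
#'   \code{bg_mean}, \code{bg_sd}.
#' @slot manifest data.frame, one row per array.
#' @slot truth per-gene truth data.frame (see [generateTruth()]).
#' @slot design list from [experimentDesign()].
#' @slot noise list from [noiseParams()].
#' @export
setClass("ArraySimulation",
  representation(arrays = "list", manifest = "data.frame",
                 truth = "data.frame", design = "list", noise = "list"))

setValidity("ArraySimulation", function(object) {
  if (length(object@arrays) != nrow(object@manifest))
    return("one manifest row per array required")
  cols <- c("probe_id", "gene_symbol", "red_raw", "green_raw", "bg_mean", "bg_sd")
  ok <- vapply(object@arrays, function(a) all(cols %in% names(a)), logical(1))
  if (!all(ok)) return("array tables missing required columns")
  TRUE
})

#' @describeIn ArraySimulation-class compact display
#' @param object an \code{ArraySimulation}
#' @export
setMethod("show", "ArraySimulation", function(object) {
  cat("ArraySimulation:", length(object@arrays), "arrays,",
      nrow(object@arrays[[1]]), "probes,", nrow(object@truth), "genes\n")
  cat("  comparisons:", paste(unique(object@manifest$label), collapse = " "), "\n")
  nlow <- sum(object@truth$low_expressed)
  cat("  truth:", sum(object@truth$true_class != "sex-independent"),
      "sex-specific genes,", nlow, "near background\n")
  invisible(NULL)
})
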