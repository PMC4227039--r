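#' @name accessors
#' @title Accessors for SphereScan classes
#' @param x an object.
#' @param ... unused.
#' @return The requested component: residue count, coordinate matrix,
#'   residue sequence, mutation counts, etc.
NULL

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x, ...) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("chainId", function(x, ...) standardGeneric("chainId"))

#' @rdname accessors
#' @export
setGeneric("residueSequence", function(x, ...) standardGeneric("residueSequence"))

#' @rdname accessors
#' @export
setGeneric("structurePositions", function(x, ...) standardGeneric("structurePositions"))

#' @rdname accessors
#' @export
setGeneric("mutationCounts", function(x, ...) standardGeneric("mutationCounts"))

#' @rdname accessors
#' @export
setGeneric("totalMutations", function(x, ...) standardGeneric("totalMutations"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("sphereCenters", function(x, ...) standardGeneric("sphereCenters"))

#' @rdname accessors
#' @export
setGeneric("coveredMutations", function(x, ...) standardGeneric("coveredMutations"))

#' Is a tally blank (fewer than two mapped mutation occurrences)?
#'
#' Structures without tertiary data on at least two mutation occurrences
#' carry no clustering information and are excluded from analysis.
#'
#' @param x a [MutationTally-class].
#' @return logical(1).
#' @examples
#' isBlank(new("MutationTally", counts = setNames(2L, "5"),
#'             structureCounts = c(0L, 0L, 0L, 0L, 2L),
#'             total = 2L, nUnmapped = 0L))
#' @export
setGeneric("isBlank", function(x) standardGeneric("isBlank"))
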