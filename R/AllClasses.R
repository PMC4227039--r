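#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SphereScan, .registration = TRUE
NULL

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

#' StructureModel: one chain/conformation of a protein structure
#'
#' Holds the ordered residues of a single polypeptide chain in a single
#' conformation, each represented by its alpha-carbon coordinates in
#' Angstrom. Residues without an alpha-carbon atom are absent from the
#' model; canonical positions are reconciled onto the model separately
#' (see [reconcile()]).
#'
#' @slot coords numeric matrix, N x 3, alpha-carbon coordinates (Angstrom).
#' @slot structurePos character, author residue labels from the coordinate
#'   file (residue number plus any insertion code), unique within the model.
#' @slot resno integer, numeric part of the author residue number.
#' @slot aminoAcid character, one-letter residue codes (standard 20 or "X").
#' @slot chainId character(1), selected chain label.
#' @slot conformation integer(1), 1-based index of the selected model block.
#'
#' @examples
#' m <- makeStructure(5, geometry = "linear")
#' nResidues(m)
#' @export
setClass("StructureModel",
  representation(coords = "matrix", structurePos = "character",
                 resno = "integer", aminoAcid = "character",
                 chainId = "character", conformation = "integer"))

setValidity("StructureModel", function(object) {
  msg <- character(0)
  n <- nrow(object@coords)
  if (n < 1) msg <- c(msg, "model must contain at least one residue")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(object@structurePos) != n || length(object@aminoAcid) != n ||
      length(object@resno) != n)
    msg <- c(msg, "residue annotation lengths must match coords")
  if (anyDuplicated(object@structurePos))
    msg <- c(msg, "structure positions must be unique within the model")
  if (!all(object@aminoAcid %in% c(AA_LETTERS, "X")))
    msg <- c(msg, "amino acids must be one of the 20 standard letters or 'X'")
  if (length(msg)) msg else TRUE
})

#' MutationTally: per-residue aggregated mutation counts
#'
#' Aggregated, sample-level missense mutation occurrences, keyed both by
#' canonical protein position and by structure residue index after
#' reconciliation. Two samples mutating the same residue contribute two
#' occurrences.
#'
#' @slot counts named integer, canonical position -> mapped occurrences.
#' @slot structureCounts integer length N, occurrences per structure residue.
#' @slot total integer(1), total mapped occurrences (sum of counts).
#' @slot nUnmapped integer(1), filtered occurrences dropped for lack of
#'   structure coordinates.
#' @export
setClass("MutationTally",
  representation(counts = "integer", structureCounts = "integer",
                 total = "integer", nUnmapped = "integer"))

setValidity("MutationTally", function(object) {
  msg <- character(0)
  if (length(object@counts)) {
    pos <- as.integer(names(object@counts))
    if (anyNA(pos) || any(pos < 1))
      msg <- c(msg, "canonical positions must be integers >= 1")
    if (any(object@counts < 1)) msg <- c(msg, "counts values must be >= 1")
  }
  if (object@total != sum(object@counts))
    msg <- c(msg, "total must equal the sum of counts")
  if (object@total != sum(object@structureCounts))
    msg <- c(msg, "structureCounts must sum to total")
  if (length(msg)) msg else TRUE
})

#' ResidueMapping: canonical-to-structure residue reconciliation
#'
#' @slot canonicalPos integer, canonical positions with a defined mapping.
#' @slot structureIdx integer, parallel structure residue indices (1..N);
#'   NA where the canonical position has no coordinates.
#' @slot mode character(1), "structure_numbering" or "alignment".
#' @slot identity numeric(1), fraction of aligned identical residues
#'   (alignment mode; NA otherwise).
#' @export
setClass("ResidueMapping",
  representation(canonicalPos = "integer", structureIdx = "integer",
                 mode = "character", identity = "numeric"))

setValidity("ResidueMapping", function(object) {
  msg <- character(0)
  if (length(object@canonicalPos) != length(object@structureIdx))
    msg <- c(msg, "canonicalPos and structureIdx must be parallel")
  mapped <- object@structureIdx[!is.na(object@structureIdx)]
  if (anyDuplicated(mapped))
    msg <- c(msg, "mapping must be injective over mapped positions")
  if (!object@mode %in% c("structure_numbering", "alignment"))
    msg <- c(msg, "mode must be 'structure_numbering' or 'alignment'")
  if (length(msg)) msg else TRUE
})

#' SphereConfiguration: an optimal set of non-overlapping spheres
#'
#' @slot s integer(1), number of spheres.
#' @slot r numeric(1), common sphere radius (Angstrom).
#' @slot centers integer, residue indices of the sphere centers (ascending);
#'   empty when no non-overlapping configuration exists.
#' @slot centerLabels character, author residue labels of the centers.
#' @slot covered numeric(1), mutation occurrences in the union of the closed
#'   balls (NA when infeasible).
#' @slot members list of integer vectors, residues within each sphere.
#' @slot feasible logical(1).
#' @export
setClass("SphereConfiguration",
  representation(s = "integer", r = "numeric", centers = "integer",
                 centerLabels = "character", covered = "numeric",
                 members = "list", feasible = "logical"))

setValidity("SphereConfiguration", function(object) {
  msg <- character(0)
  if (object@feasible) {
    if (length(object@centers) != object@s)
      msg <- c(msg, "feasible configuration must have s centers")
    if (is.na(object@covered) || object@covered < 0)
      msg <- c(msg, "covered must be a non-negative count")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationMatrix: observed and simulated coverage over the (s, r) grid
#'
#' Row 1 is the observed dataset; rows 2..T+1 are uniform-null simulations.
#' Cell means and standard deviations are taken over the simulation rows
#' only; cells that are geometrically infeasible or have zero standard
#' deviation are excluded from every row's maximum.
#'
#' @slot grid data.frame with columns s, r, feasible, sigmaZero, included.
#' @slot X numeric matrix, (T+1) x ncell covered counts (NA if infeasible).
#' @slot mu,sigma numeric, per-cell simulation mean and sd.
#' @slot Z numeric length T+1, per-row maximum standardized coverage.
#' @slot T integer(1), number of null simulations.
#' @slot seed integer(1), seed that produced the simulation stream.
#' @export
setClass("SimulationMatrix",
  representation(grid = "data.frame", X = "matrix", mu = "numeric",
                 sigma = "numeric", Z = "numeric", T = "integer",
                 seed = "integer"))

setValidity("SimulationMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@X) != object@T + 1L)
    msg <- c(msg, "X must have T+1 rows (observed + simulations)")
  if (ncol(object@X) != nrow(object@grid))
    msg <- c(msg, "X must have one column per grid cell")
  if (length(object@Z) != object@T + 1L)
    msg <- c(msg, "Z must have length T+1")
  if (length(msg)) msg else TRUE
})

#' HotspotResult: hotspot test result for one structure
#'
#' @slot pValue numeric(1), Monte-Carlo tail probability
#'   #\{i : Z_i >= Z_0\} / T.
#' @slot pFloor logical(1), TRUE when no simulation reached Z_0 and the
#'   p-value is reported as "< 1/T".
#' @slot pText character(1), textual report (e.g. "<1.00E-03").
#' @slot bestS,bestR best grid cell (smallest s then r on ties).
#' @slot hotspots [SphereConfiguration-class] at the best cell.
#' @slot perCell list of observed-row configurations for every grid cell.
#' @slot simulation [SimulationMatrix-class] behind the p-value.
#' @export
setClass("HotspotResult",
  representation(pValue = "numeric", pFloor = "logical", pText = "character",
                 bestS = "integer", bestR = "numeric",
                 hotspots = "SphereConfiguration", perCell = "list",
                 simulation = "SimulationMatrix"))

setValidity("HotspotResult", function(object) {
  msg <- character(0)
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StudyResult: multi-structure study with rough-FDR adjustment
#'
#' @slot k integer(1), number of analyzed (non-blank) structures.
#' @slot alpha numeric(1), nominal level.
#' @slot rfdr numeric(1), alpha * (k + 1) / (2k).
#' @slot threshold numeric(1), effective threshold after rounding down.
#' @slot rows data.frame, one row per manifest entry.
#' @slot perGene data.frame, minimum p-value per gene.
#' @export
setClass("StudyResult",
  representation(k = "integer", alpha = "numeric", rfdr = "numeric",
                 threshold = "numeric", rows = "data.frame",
                 perGene = "data.frame"))
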