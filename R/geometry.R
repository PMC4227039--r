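# Structure ingest and alpha-carbon geometry.
#
# Each residue is represented by the spatial coordinates of its alpha-carbon
# atom; spheres of radius r around those points define candidate hotspots.

#' Read a protein structure from a PDB-format file
#'
#' Parses ATOM records (via bio3d) and returns the alpha-carbon trace of a
#' single chain and a single conformation. Selection follows fixed
#' conventions: when `chain = "auto"` the first chain appearing in the ATOM
#' records is used; the first listed conformation (MODEL block) is used by
#' default; for alternate-location indicators the first encountered altloc of
#' each atom is kept. Residues lacking an alpha-carbon atom are skipped.
#'
#' @param path path to a PDB-format file.
#' @param chain chain identifier, or `"auto"` (default) for the first chain
#'   in the ATOM records.
#' @param conformation 1-based index of the MODEL block to use (default 1).
#' @param includeNonStandard also accept HETATM-coded amino acids such as
#'   MSE (default `FALSE`).
#' @return a [StructureModel-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructurePDB(makeStructure(10, geometry = "linear"), pdb)
#' m <- readStructure(pdb)
#' nResidues(m)
#' @export
readStructure <- function(path, chain = "auto", conformation = 1L,
                          includeNonStandard = FALSE) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  types <- if (includeNonStandard) c("ATOM", "HETATM") else "ATOM"
  keep <- atoms$type %in% types & atoms$elety == "CA"
  if (includeNonStandard) {
    # HETATM CA records are accepted only for amino-acid residues
    aa <- suppressWarnings(bio3d::aa321(atoms$resid))
    keep <- keep & !(atoms$type == "HETATM" & is.na(aa))
  }
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0)
    stop("structure-empty error: no alpha-carbon (CA) ATOM records in ", path)

  chains <- unique(atoms$chain)
  if (identical(chain, "auto")) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]

  nModels <- nrow(pdb$xyz)
  conformation <- as.integer(conformation)
  if (conformation < 1 || conformation > nModels)
    stop("conformation ", conformation, " not found; file has ",
         nModels, " conformation(s)")

  # first-encountered altloc per residue position
  insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  posLabel <- paste0(atoms$resno, insert)
  first <- !duplicated(posLabel)
  atoms <- atoms[first, , drop = FALSE]
  posLabel <- posLabel[first]

  xyzRow <- pdb$xyz[conformation, ]
  idx <- as.integer(rownames(atoms))   # row index into the full atom table
  ca <- cbind(xyzRow[3 * (idx - 1) + 1],
              xyzRow[3 * (idx - 1) + 2],
              xyzRow[3 * (idx - 1) + 3])
  aa <- suppressWarnings(bio3d::aa321(atoms$resid))
  aa[is.na(aa) | !aa %in% AA_LETTERS] <- "X"

  new("StructureModel",
      coords = unname(ca),
      structurePos = posLabel,
      resno = as.integer(atoms$resno),
      aminoAcid = aa,
      chainId = chain,
      conformation = conformation)
}

#' @rdname accessors
#' @export
setMethod("nResidues", "StructureModel", function(x, ...) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("coords", "StructureModel", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("chainId", "StructureModel", function(x, ...) x@chainId)

#' @rdname accessors
#' @export
setMethod("residueSequence", "StructureModel",
          function(x, ...) paste(x@aminoAcid, collapse = ""))

#' @rdname accessors
#' @export
setMethod("structurePositions", "StructureModel", function(x, ...) x@structurePos)

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", nResidues(object), "residues, chain",
      object@chainId, ", conformation", object@conformation, "\n")
})

#' Euclidean distance between two residues
#'
#' @param model a [StructureModel-class].
#' @param i,j residue indices (1..N).
#' @return distance in Angstrom.
#' @examples
#' m <- makeStructure(5, geometry = "linear")
#' residueDistance(m, 1, 2)  # 3.8
#' @export
residueDistance <- function(model, i, j) {
  n <- nResidues(model)
  if (any(c(i, j) < 1) || any(c(i, j) > n))
    stop("residue index out of range 1..", n)
  sqrt(sum((model@coords[i, ] - model@coords[j, ])^2))
}

#' All pairwise alpha-carbon distances
#'
#' @param model a [StructureModel-class].
#' @return N x N numeric matrix (Angstrom).
#' @export
distanceMatrix <- function(model) {
  as.matrix(stats::dist(model@coords))
}

#' Residues within radius r of a center residue
#'
#' Closed-ball membership: residues whose alpha-carbon lies at Euclidean
#' distance <= r from the center's alpha-carbon. Always contains the center.
#'
#' @param model a [StructureModel-class].
#' @param center residue index (1..N).
#' @param r radius in Angstrom (> 0).
#' @param dmat optional precomputed [distanceMatrix()].
#' @return integer vector of residue indices (ascending).
#' @examples
#' m <- makeStructure(10, geometry = "linear")
#' neighborhood(m, 5, 4)  # residues 4, 5, 6
#' @export
neighborhood <- function(model, center, r, dmat = NULL) {
  n <- nResidues(model)
  if (center < 1 || center > n) stop("center index out of range 1..", n)
  if (r <= 0) stop("radius must be positive")
  if (is.null(dmat)) {
    d <- sqrt(colSums((t(model@coords) - model@coords[center, ])^2))
  } else {
    d <- dmat[center, ]
  }
  # closed ball with a 1e-9 A guard so exact-boundary membership is not
  # decided by floating-point representation error
  which(d <= r + 1e-9)
}

#' Neighborhoods of every residue at a common radius
#'
#' @param model a [StructureModel-class].
#' @param r radius in Angstrom.
#' @param dmat optional precomputed [distanceMatrix()].
#' @return list of N integer vectors.
#' @export
neighborhoodList <- function(model, r, dmat = NULL) {
  if (is.null(dmat)) dmat <- distanceMatrix(model)
  lapply(seq_len(nrow(dmat)), function(i) which(dmat[i, ] <= r + 1e-9))
}
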