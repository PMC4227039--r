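# Synthetic structures and mutation tables with known ground truth.
#
# The generator emulates the statistical setting the hotspot test assumes:
# a uniform mutation background over residues, optionally with a spatially
# concentrated excess (the planted hotspot). With zero hotspots the generator
# follows the same law as the null simulation, which is the basis of the
# calibration tests.

#' Generate a synthetic alpha-carbon backbone
#'
#' Geometries: `"linear"` places residue i at (spacing * i, 0, 0); `"helix"`
#' is an ideal alpha-helix (rise 1.5 A, 100 degrees per residue, radius
#' 2.3 A, giving consecutive alpha-carbon distances close to the canonical
#' 3.8 A); `"random_coil"` is a self-avoiding random chain with consecutive
#' spacing of spacing +/- 0.1 A and a 4 A exclusion between non-adjacent
#' residues. Residue letters are drawn uniformly from the 20 standard amino
#' acids under the given seed.
#'
#' @param N residue count (>= 1).
#' @param geometry one of `"linear"`, `"helix"`, `"random_coil"`.
#' @param spacing consecutive alpha-carbon spacing in Angstrom (default 3.8).
#' @param seed integer seed (sequence, and coil geometry).
#' @param chain chain label for the emitted model (default "A").
#' @return a [StructureModel-class].
#' @examples
#' m <- makeStructure(10, geometry = "helix")
#' residueDistance(m, 1, 2)
#' @export
makeStructure <- function(N, geometry = c("helix", "linear", "random_coil"),
                          spacing = 3.8, seed = 1L, chain = "A") {
  geometry <- match.arg(geometry)
  if (N < 1) stop("N must be >= 1")
  withSeed(seed, {
    aa <- sample(AA_LETTERS, N, replace = TRUE)
    coordsM <- switch(geometry,
      linear = cbind(spacing * seq_len(N), 0, 0),
      helix = {
        t <- (seq_len(N) - 1) * 100 * pi / 180
        cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(N) - 1))
      },
      random_coil = selfAvoidingChain(N, spacing))
    new("StructureModel", coords = unname(coordsM),
        structurePos = as.character(seq_len(N)),
        resno = seq_len(N), aminoAcid = aa,
        chainId = chain, conformation = 1L)
  })
}

# self-avoiding chain: consecutive spacing +/- 0.1, non-adjacent >= 4 A
selfAvoidingChain <- function(N, spacing, exclusion = 4, maxTries = 200L) {
  repeat {
    xyz <- matrix(0, nrow = N, ncol = 3)
    ok <- TRUE
    for (i in seq_len(N)[-1]) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        step <- spacing + stats::runif(1, -0.1, 0.1)
        cand <- xyz[i - 1, ] + u * step
        if (i > 2) {
          d <- sqrt(colSums((t(xyz[seq_len(i - 2), , drop = FALSE]) - cand)^2))
          if (any(d < exclusion)) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
}

aa123 <- function(x) {
  tab <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR", X = "UNK")
  unname(tab[x])
}

pdbAtomLines <- function(model, serialStart = 1L) {
  n <- nResidues(model)
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serialStart - 1L + seq_len(n), aa123(model@aminoAcid),
          model@chainId, model@resno,
          model@coords[, 1], model@coords[, 2], model@coords[, 3])
}

#' Write a StructureModel as a minimal PDB-format file
#'
#' Emits fixed-column ATOM records (alpha-carbons only, occupancy 1.00,
#' B-factor 0.00) round-trippable through [readStructure()] to the format's
#' 3-decimal coordinate precision. Additional conformations may be supplied
#' as extra coordinate matrices, written as successive MODEL blocks.
#'
#' @param model a [StructureModel-class].
#' @param path output path.
#' @param extraConformations optional list of N x 3 matrices written as
#'   MODEL 2, 3, ...
#' @return the path, invisibly.
#' @export
writeStructurePDB <- function(model, path, extraConformations = NULL) {
  lines <- character(0)
  if (is.null(extraConformations)) {
    lines <- pdbAtomLines(model)
  } else {
    allCoords <- c(list(model@coords), extraConformations)
    for (mi in seq_along(allCoords)) {
      mm <- model
      mm@coords <- allCoords[[mi]]
      lines <- c(lines, sprintf("MODEL     %4d", mi), pdbAtomLines(mm),
                 "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a synthetic per-sample mutation table
#'
#' Hotspot mutations are placed uniformly within each hotspot span (the
#' `span` residues centered at `center`); background mutations are placed
#' uniformly over all residues. Rows carry an accepted somatic status,
#' missense type and whole-genome screen, so [filterMutations()] is a no-op
#' on generated tables. Sample ids are assigned round-robin. Deterministic
#' given the seed.
#'
#' @param model a [StructureModel-class] (positions are canonical = author
#'   numbering for synthetic structures).
#' @param hotspots list of `list(center =, span =, count =)` entries.
#' @param background count of uniformly scattered mutations.
#' @param nSamples number of sample ids to spread mutations over.
#' @param gene gene symbol for the table.
#' @param seed integer seed.
#' @return data.frame of mutation records.
#' @export
makeMutations <- function(model, hotspots = list(), background = 0L,
                          nSamples = 3L, gene = "SYNGENE1", seed = 1L) {
  n <- nResidues(model)
  withSeed(seed, {
    pos <- integer(0)
    for (h in hotspots) {
      start <- h$center - h$span %/% 2L
      span <- seq(start, start + h$span - 1L)
      span <- span[span >= 1 & span <= n]
      if (!length(span)) stop("hotspot span outside 1..", n)
      pos <- c(pos, sample(span, h$count, replace = TRUE))
    }
    if (background > 0)
      pos <- c(pos, sample.int(n, background, replace = TRUE))
    if (!length(pos)) {
      data.frame(gene = character(0), sample_id = character(0),
                 position = integer(0), wt_aa = character(0),
                 mut_aa = character(0), mutation_type = character(0),
                 somatic_status = character(0), screen_type = character(0))
    } else {
      wt <- model@aminoAcid[pos]
      mut <- vapply(wt, function(w) sample(setdiff(AA_LETTERS, w), 1), "")
      data.frame(
        gene = gene,
        sample_id = sprintf("S%03d", ((seq_along(pos) - 1L) %% nSamples) + 1L),
        position = pos,
        wt_aa = wt,
        mut_aa = unname(mut),
        mutation_type = "missense",
        somatic_status = "Confirmed somatic variant",
        screen_type = "whole_genome")
    }
  })
}

#' Materialize a complete synthetic study directory
#'
#' Writes structures (PDB), mutation tables (TSV), canonical sequences
#' (FASTA) and a manifest wired for [runStudy()] / [cmdStudy()]. The first
#' `nPlanted` structures carry a planted hotspot (default 50 mutations in a
#' 3-residue span plus 10 background); the rest are background-only nulls.
#'
#' @param dir output directory (created if needed).
#' @param nStructures number of structures (default 20).
#' @param nPlanted number with a planted hotspot (default 2).
#' @param N residues per structure (default 200).
#' @param hotspotCount,hotspotSpan planted hotspot size (default 50 in 3).
#' @param background background mutations per structure (default 10).
#' @param geometry backbone geometry (default "helix").
#' @param seed master seed; per-structure seeds are derived from it and the
#'   structure id, so manifest order does not matter.
#' @return path to the manifest TSV, invisibly.
#' @export
makeStudyFixture <- function(dir, nStructures = 20L, nPlanted = 2L, N = 200L,
                             hotspotCount = 50L, hotspotSpan = 3L,
                             background = 10L, geometry = "helix",
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nStructures)
  for (i in seq_len(nStructures)) {
    id <- sprintf("SYN%03d", i)
    sSeed <- subSeed(seed, id)
    model <- makeStructure(N, geometry = geometry, seed = sSeed)
    hot <- if (i <= nPlanted)
      list(list(center = N %/% 2L, span = hotspotSpan, count = hotspotCount))
    else list()
    mut <- makeMutations(model, hotspots = hot, background = background,
                         nSamples = 5L, gene = paste0("GENE_", id),
                         seed = sSeed + 1L)
    pdbPath <- file.path(dir, paste0(id, ".pdb"))
    tsvPath <- file.path(dir, paste0(id, ".tsv"))
    faPath <- file.path(dir, paste0(id, ".fasta"))
    writeStructurePDB(model, pdbPath)
    writeMutationsTSV(mut, tsvPath)
    writeFastaSequence(residueSequence(model), id, faPath)
    rows[[i]] <- data.frame(
      structure_path = basename(pdbPath), chain = "A", conformation = 1L,
      gene = paste0("GENE_", id), mutation_table_path = basename(tsvPath),
      fasta_path = basename(faPath), reconciliation_mode = "alignment")
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifestPath)
}
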