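# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# a MutationTally straight from a structure-indexed count vector
tallyFromCounts <- function(counts) {
  counts <- as.integer(counts)
  nz <- which(counts > 0)
  new("MutationTally",
      counts = stats::setNames(counts[nz], as.character(nz)),
      structureCounts = counts,
      total = sum(counts), nUnmapped = 0L)
}

# the five-residue worked instance: counts 50/40/30/20/10 on residues
# mutually farther apart than 2r (linear backbone, 3.8 A spacing, r = 2)
workedExample <- function() {
  model <- makeStructure(30, geometry = "linear", seed = 11)
  counts <- integer(30)
  counts[c(1, 7, 13, 19, 25)] <- c(50L, 40L, 30L, 20L, 10L)
  list(model = model, tally = tallyFromCounts(counts), r = 2)
}

# random small instance for oracle-equivalence checks
randomInstance <- function(seed) {
  set.seed(seed)
  n <- sample(5:30, 1)
  coordsM <- matrix(stats::runif(3 * n, 0, 25), ncol = 3)
  model <- new("StructureModel", coords = coordsM,
               structurePos = as.character(seq_len(n)),
               resno = seq_len(n),
               aminoAcid = sample(c("A", "G", "L", "S"), n, replace = TRUE),
               chainId = "A", conformation = 1L)
  counts <- integer(n)
  hit <- sample(n, sample(2:min(8, n), 1))
  counts[hit] <- sample(1:20, length(hit), replace = TRUE)
  r <- stats::runif(1, 1, 8)
  s <- sample(2:3, 1)
  list(model = model, tally = tallyFromCounts(counts), r = r, s = s)
}

# structure + tally with a planted hotspot, reconciled by structure numbering
plantedFixture <- function(N = 200, count = 50, span = 3, background = 10,
                           seed = 101) {
  model <- makeStructure(N, geometry = "helix", seed = seed)
  mut <- makeMutations(model,
                       hotspots = list(list(center = N %/% 2, span = span,
                                            count = count)),
                       background = background, nSamples = 5, seed = seed + 1)
  mapping <- reconcile(model = model, mode = "structure_numbering")
  tally <- suppressMessages(tallyMutations(mut, mapping, model))
  list(model = model, tally = tally, mutations = mut,
       span = (N %/% 2 - span %/% 2) + seq_len(span) - 1L)
}

# minimal hand-written two-chain PDB text with altlocs and a HETATM residue
twoChainPDBText <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       3.800   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA BGLY A   2       3.900   0.000   0.000  0.40  0.00           C",
    "ATOM      5  CA  LEU A   3       7.600   0.000   0.000  1.00  0.00           C",
    "HETATM    6  CA  MSE A   4      11.400   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  SER B   1       0.000   8.000   0.000  1.00  0.00           C",
    "ATOM      8  CA  THR B   2       3.800   8.000   0.000  1.00  0.00           C",
    "END")
}
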