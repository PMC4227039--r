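mkRecords <- function() {
  data.frame(
    gene = "G1",
    sample_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S1"),
    position = c(5L, 20L, 6L, 21L, 5L, 9L, 5L),
    wt_aa = "A", mut_aa = "V",
    mutation_type = c("missense", "missense", "missense", "missense",
                      "missense", "nonsense", "missense"),
    somatic_status = c("Confirmed somatic variant",
                       "confirmed somatic variant",
                       "Reported in another cancer sample as somatic",
                       "  confirmed somatic variant ",
                       "Confirmed somatic variant",
                       "Confirmed somatic variant",
                       "variant of unknown origin"),
    screen_type = c("whole_genome", "whole_gene", "whole_genome",
                    "whole_genome", "whole_genome", "whole_genome", "whole_genome"))
}

test_that("filtering keeps accepted missense somatic records and dedupes", {
  recs <- mkRecords()
  kept <- filterMutations(recs)
  # row 6 (nonsense) and row 7 (unaccepted status) are dropped
  expect_equal(nrow(kept), 5)
  expect_true(all(tolower(kept$mutation_type) == "missense"))

  # byte-identical duplicate differing only in source study is removed
  dup <- rbind(recs[1, ], recs)
  expect_equal(nrow(filterMutations(dup)), 5)

  # indel dropped
  recs$mutation_type[1] <- "indel"
  expect_equal(nrow(filterMutations(recs)), 4)

  # malformed rows are rejected with their row number
  bad <- mkRecords()
  bad$position[3] <- -1L
  expect_error(filterMutations(bad), "row\\(s\\) 3")
  bad2 <- mkRecords()
  bad2$wt_aa[2] <- "B"
  expect_error(filterMutations(bad2), "residue letter")
})

test_that("round-tripping a mutation table preserves the filtered records", {
  recs <- filterMutations(mkRecords())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeMutationsTSV(recs, tsv)
  back <- readMutations(tsv)
  expect_equal(back$position, recs$position)
  expect_equal(back$sample_id, recs$sample_id)
})

test_that("identical sequences reconcile to the identity mapping", {
  m <- makeStructure(40, geometry = "helix", seed = 21)
  map <- reconcile(residueSequence(m), m, mode = "alignment")
  expect_equal(map@identity, 1.0)
  expect_equal(mapPositions(map, 1:40), 1:40)
})

test_that("terminal truncation reconciles to an offset map", {
  full <- makeStructure(50, geometry = "helix", seed = 22)
  trunc <- new("StructureModel", coords = coords(full)[6:50, ],
               structurePos = as.character(1:45), resno = 1:45,
               aminoAcid = full@aminoAcid[6:50], chainId = "A",
               conformation = 1L)
  map <- reconcile(residueSequence(full), trunc, mode = "alignment")
  expect_equal(mapPositions(map, 6:50), 1:45)       # p maps to p - 5
  expect_true(all(is.na(mapPositions(map, 1:5))))   # missing N-terminus
})

test_that("low alignment identity fails reconciliation instead of mismapping", {
  m <- makeStructure(40, geometry = "helix", seed = 23)
  scrambled <- paste(rev(strsplit(residueSequence(m), "")[[1]]), collapse = "")
  expect_error(reconcile(scrambled, m, mode = "alignment"),
               "reconciliation-failed")
})

test_that("structure-numbering mode maps through author residue numbers", {
  m <- makeStructure(10, geometry = "linear", seed = 24)
  m@resno <- m@resno + 100L   # authors number 101..110
  m@structurePos <- as.character(m@resno)
  map <- reconcile(model = m, mode = "structure_numbering")
  expect_equal(mapPositions(map, 101:110), 1:10)
  expect_true(is.na(mapPositions(map, 5)))
})

test_that("tallies count sample-level occurrences and drop unmapped ones", {
  m <- makeStructure(30, geometry = "linear", seed = 25)
  map <- reconcile(model = m, mode = "structure_numbering")
  # samples A {5, 20}, B {6, 21}, C {5}: the worked aggregation example
  recs <- data.frame(
    gene = "G1", sample_id = c("A", "A", "B", "B", "C"),
    position = c(5L, 20L, 6L, 21L, 5L),
    wt_aa = "A", mut_aa = "V", mutation_type = "missense",
    somatic_status = "Confirmed somatic variant", screen_type = "whole_genome")
  tl <- tallyMutations(recs, map, m)
  expect_equal(mutationCounts(tl),
               c("5" = 2L, "6" = 1L, "20" = 1L, "21" = 1L))
  expect_equal(totalMutations(tl), 5L)
  expect_equal(tl@structureCounts[c(5, 6, 20, 21)], c(2L, 1L, 1L, 1L))

  # a position with no coordinates is dropped with a log message
  recs2 <- recs
  recs2$position[2] <- 999L
  expect_message(tl2 <- tallyMutations(recs2, map, m), "dropped")
  expect_equal(totalMutations(tl2), 4L)
  expect_equal(tl2@nUnmapped, 1L)
  expect_equal(totalMutations(tl2) + tl2@nUnmapped, nrow(recs2))

  # empty input
  tl0 <- tallyMutations(recs[0, ], map, m)
  expect_equal(totalMutations(tl0), 0L)
})

test_that("blankness is fewer than two mapped occurrences", {
  m <- makeStructure(10, geometry = "linear", seed = 26)
  map <- reconcile(model = m, mode = "structure_numbering")
  rec <- function(n, pos = 5L) data.frame(
    gene = "G", sample_id = paste0("S", seq_len(n)), position = pos,
    wt_aa = "A", mut_aa = "V", mutation_type = "missense",
    somatic_status = "Confirmed somatic variant", screen_type = "whole_genome")
  expect_true(isBlank(tallyMutations(rec(0)[0, ], map, m)))
  expect_true(isBlank(tallyMutations(rec(1), map, m)))
  # two occurrences on ONE residue already satisfy the threshold
  expect_false(isBlank(tallyMutations(rec(2), map, m)))
})

test_that("filter and tally are invariant under input row order", {
  m <- makeStructure(60, geometry = "helix", seed = 27)
  map <- reconcile(model = m, mode = "structure_numbering")
  mut <- makeMutations(m, hotspots = list(list(center = 30, span = 5,
                                               count = 15)),
                       background = 10, nSamples = 4, seed = 28)
  base <- tallyMutations(filterMutations(mut), map, m)
  for (s in 1:3) {
    perm <- mut[sample.int(nrow(mut)), ]
    tl <- tallyMutations(filterMutations(perm), map, m)
    expect_equal(mutationCounts(tl), mutationCounts(base))
    expect_equal(totalMutations(tl), totalMutations(base))
  }
})

test_that("wild-type disagreement with the canonical sequence only warns", {
  m <- makeStructure(20, geometry = "linear", seed = 29)
  map <- reconcile(model = m, mode = "structure_numbering")
  recs <- data.frame(
    gene = "G", sample_id = c("S1", "S2"), position = c(3L, 4L),
    wt_aa = c(m@aminoAcid[3], if (m@aminoAcid[4] == "W") "Y" else "W"),
    mut_aa = "V", mutation_type = "missense",
    somatic_status = "Confirmed somatic variant", screen_type = "whole_genome")
  expect_warning(tl <- tallyMutations(recs, map, m, residueSequence(m)),
                 "wild-type")
  expect_equal(totalMutations(tl), 2L)
})
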