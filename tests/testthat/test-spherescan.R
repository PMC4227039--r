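test_that("coverage vectors aggregate counts over closed-ball neighborhoods", {
  m <- makeStructure(10, geometry = "linear", seed = 31)
  counts <- integer(10); counts[5] <- 10L
  tl <- tallyFromCounts(counts)
  # r below the minimum inter-residue spacing: raw counts
  cv1 <- coverageVector(m, tl, 1)
  expect_equal(cv1$coverage, as.numeric(counts))
  # r = 4 spans one residue either side
  cv4 <- coverageVector(m, tl, 4)
  expect_equal(cv4$coverage[4:6], c(10, 10, 10))
  expect_equal(sum(cv4$coverage), 30)
  expect_equal(cv4$order[1], 4)  # ties broken by ascending index
})

test_that("the five-residue worked example yields 90 covered by two spheres", {
  wx <- workedExample()
  # sorted candidates head in count order 50, 40, 30, 20, 10
  cv <- coverageVector(wx$model, wx$tally, wx$r)
  expect_equal(cv$order[1:5], c(1L, 7L, 13L, 19L, 25L))
  cfg <- bestSpheres(wx$model, wx$tally, s = 2, r = wx$r)
  expect_true(cfg@feasible)
  expect_equal(coveredMutations(cfg), 90)
  expect_equal(sphereCenters(cfg), c(1L, 7L))
})

test_that("the traversal pops elements in non-increasing priority order", {
  wx <- workedExample()
  en <- enumerateElements(wx$model, wx$tally, s = 2, r = wx$r, maxPops = 8)
  expect_equal(en$priority[1:4], c(90, 80, 70, 70))
  expect_equal(unlist(en[1, c("i", "j")]), c(i = 2, j = 1))
  expect_true(all(diff(en$priority) <= 1e-9))
  en3 <- enumerateElements(wx$model, wx$tally, s = 3, r = wx$r, maxPops = 8)
  expect_equal(en3$priority[1], 120)  # (3,2,1) = 30+40+50
  expect_true(all(diff(en3$priority) <= 1e-9))
})

test_that("a single sphere takes the coverage maximum", {
  wx <- workedExample()
  cfg <- bestSpheres(wx$model, wx$tally, s = 1, r = wx$r)
  expect_equal(sphereCenters(cfg), 1L)
  expect_equal(coveredMutations(cfg), 50)
  bf <- bruteForceSpheres(wx$model, wx$tally, s = 1, r = wx$r)
  expect_equal(sphereCenters(bf), 1L)
})

test_that("best-first search matches the brute-force oracle on random instances", {
  for (seed in 1:40) {
    inst <- randomInstance(seed)
    fast <- bestSpheres(inst$model, inst$tally, s = inst$s, r = inst$r)
    slow <- bruteForceSpheres(inst$model, inst$tally, s = inst$s, r = inst$r)
    expect_equal(fast@feasible, slow@feasible, info = paste("seed", seed))
    if (fast@feasible)
      expect_identical(coveredMutations(fast), coveredMutations(slow),
                       info = paste("seed", seed))
  }
})

test_that("infeasible configurations are flagged, not fabricated", {
  # two residues 3 A apart cannot host two spheres of radius 2 (needs >= 4 A)
  m <- new("StructureModel", coords = rbind(c(0, 0, 0), c(3, 0, 0)),
           structurePos = c("1", "2"), resno = 1:2,
           aminoAcid = c("A", "G"), chainId = "A", conformation = 1L)
  tl <- tallyFromCounts(c(3L, 2L))
  cfg <- bestSpheres(m, tl, s = 2, r = 2)
  expect_false(cfg@feasible)
  expect_false(bruteForceSpheres(m, tl, s = 2, r = 2)@feasible)
  # s = 3 on a 2-residue structure is infeasible outright
  expect_false(bestSpheres(m, tl, s = 3, r = 1)@feasible)
  # tangency (centers exactly 2r apart) is allowed
  m2 <- new("StructureModel", coords = rbind(c(0, 0, 0), c(4, 0, 0)),
            structurePos = c("1", "2"), resno = 1:2,
            aminoAcid = c("A", "G"), chainId = "A", conformation = 1L)
  expect_true(bestSpheres(m2, tallyFromCounts(c(3L, 2L)), s = 2, r = 2)@feasible)
})

test_that("per-sphere counts sum to the union count without tangency", {
  for (seed in 41:55) {
    inst <- randomInstance(seed)
    cfg <- bestSpheres(inst$model, inst$tally, s = inst$s, r = inst$r)
    if (!cfg@feasible) next
    dmat <- distanceMatrix(inst$model)
    # skip the measure-zero case of a residue tangent to two spheres
    tangent <- any(abs(dmat[cfg@centers, , drop = FALSE] - inst$r) < 1e-6)
    if (tangent) next
    perSphere <- vapply(cfg@members, function(ix)
      sum(inst$tally@structureCounts[ix]), numeric(1))
    expect_equal(sum(perSphere), coveredMutations(cfg))
  }
})

test_that("maximum coverage is monotone in s and, for one sphere, in r", {
  for (seed in 56:65) {
    inst <- randomInstance(seed)
    covs <- vapply(1:3, function(s) {
      cfg <- bestSpheres(inst$model, inst$tally, s = s, r = inst$r)
      if (cfg@feasible) coveredMutations(cfg) else NA_real_
    }, numeric(1))
    ok <- !is.na(covs)
    expect_true(all(diff(covs[ok]) >= 0), info = paste("seed", seed))
    oneSphere <- vapply(c(1, 2, 4, 6, 8, 10), function(r)
      coveredMutations(bestSpheres(inst$model, inst$tally, s = 1, r = r)),
      numeric(1))
    expect_true(all(diff(oneSphere) >= 0), info = paste("seed", seed))
  }
})

test_that("the search-space size is the binomial count of center subsets", {
  expect_equal(searchSpaceSize(10, 1), 10)
  expect_equal(searchSpaceSize(10, 2), 45)
  expect_equal(searchSpaceSize(10, 3), 120)
})

test_that("s above 3 requires the experimental flag", {
  wx <- workedExample()
  expect_error(bestSpheres(wx$model, wx$tally, s = 4, r = 2), "experimental")
})
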