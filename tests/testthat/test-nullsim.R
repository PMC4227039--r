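test_that("null simulations conserve totals and are uniform over residues", {
  m <- makeStructure(20, geometry = "helix", seed = 41)
  tl <- tallyFromCounts(c(rep(0L, 9), 100L, rep(0L, 10)))
  sims <- simulateNull(m, tl, T = 2000, seed = 42)
  expect_true(all(rowSums(sims) == 100))
  # multinomial uniform law: per-residue mean ~ 5
  tot <- colSums(sims)
  gof <- stats::chisq.test(tot, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(tot) / 2000, 5, tolerance = 0.01)

  # single-residue structure: everything lands on residue 1
  m1 <- new("StructureModel", coords = matrix(0, 1, 3), structurePos = "1",
            resno = 1L, aminoAcid = "A", chainId = "A", conformation = 1L)
  s1 <- simulateNull(m1, tallyFromCounts(5L), T = 10, seed = 1)
  expect_true(all(s1 == 5))

  # determinism given the seed
  expect_identical(simulateNull(m, tl, T = 50, seed = 7),
                   simulateNull(m, tl, T = 50, seed = 7))
})

test_that("the coverage matrix standardizes per cell and excludes sigma-zero cells", {
  # tiny structure where a big radius always covers everything: sd == 0
  m <- makeStructure(4, geometry = "linear", seed = 43)
  tl <- tallyFromCounts(c(2L, 0L, 1L, 0L))
  mat <- buildMatrix(m, tl, radii = c(1, 50), maxSpheres = 1, T = 50, seed = 44)
  grid <- mat@grid
  big <- which(grid$r == 50)
  expect_true(all(mat@X[, big] == totalMutations(tl)))
  expect_true(grid$sigmaZero[big])
  expect_false(grid$included[big])

  # single included cell: Z is that cell's standardized value
  small <- which(grid$r == 1)
  expect_true(grid$included[small])
  zExp <- (mat@X[, small] - mat@mu[small]) / mat@sigma[small]
  expect_equal(mat@Z, unname(zExp))

  # degenerate analysis: every cell excluded -> p = 1 with a warning
  matBad <- buildMatrix(m, tl, radii = c(50, 60), maxSpheres = 1,
                        T = 20, seed = 45)
  expect_warning(res <- hotspotPValue(matBad, m, tl), "degenerate")
  expect_equal(pValue(res), 1)
})

test_that("observed row equals the sphere optimizer cell by cell", {
  fx <- plantedFixture(N = 60, count = 15, background = 8, seed = 46)
  mat <- buildMatrix(fx$model, fx$tally, radii = c(2, 5, 8), maxSpheres = 3,
                     T = 30, seed = 47)
  for (ci in seq_len(nrow(mat@grid))) {
    cfg <- bestSpheres(fx$model, fx$tally, mat@grid$s[ci], mat@grid$r[ci])
    if (cfg@feasible) {
      expect_equal(mat@X[1, ci], coveredMutations(cfg))
    } else {
      expect_false(mat@grid$feasible[ci])
    }
  }
})

test_that("the p-value is the upper tail of Z with ties counting against", {
  fx <- plantedFixture(N = 50, count = 12, background = 6, seed = 48)
  mat <- buildMatrix(fx$model, fx$tally, radii = c(3, 6), maxSpheres = 2,
                     T = 40, seed = 49)
  res <- hotspotPValue(mat, fx$model, fx$tally)
  Z0 <- mat@Z[1]
  expect_equal(pValue(res), sum(mat@Z[-1] >= Z0) / 40)
  expect_equal(res@pFloor, pValue(res) == 0)
  expect_equal(res@hotspots@covered, mat@X[1, which(mat@grid$s == res@bestS &
                                                    mat@grid$r == res@bestR)])

  # relabeling simulation rows leaves the p-value unchanged
  perm <- mat
  ix <- 1L + sample(40)
  perm@X <- mat@X[c(1L, ix), ]
  perm@Z <- mat@Z[c(1L, ix)]
  expect_equal(pValue(hotspotPValue(perm, fx$model, fx$tally)), pValue(res))

  # Z0 no larger than any simulated Z gives p = 1
  worst <- mat
  worst@Z[1] <- min(mat@Z[-1]) - 1
  expect_equal(pValue(hotspotPValue(worst, fx$model, fx$tally)), 1)
})

test_that("p-values are floored and formatted as < 1/T", {
  expect_equal(formatPValue(0, TRUE, 1000), "<1.00E-03")
  expect_equal(formatPValue(0, TRUE, 200), "<5.00E-03")
  expect_equal(formatPValue(0.011, FALSE, 1000), "1.10E-02")
})

test_that("identical inputs and seed reproduce the full result", {
  fx <- plantedFixture(N = 50, count = 12, background = 6, seed = 50)
  a <- analyzeTally(fx$model, fx$tally, radii = c(3, 6), T = 60, seed = 51)
  b <- analyzeTally(fx$model, fx$tally, radii = c(3, 6), T = 60, seed = 51)
  expect_identical(pValue(a), pValue(b))
  expect_identical(a@simulation@Z, b@simulation@Z)
  expect_identical(sphereCenters(a@hotspots), sphereCenters(b@hotspots))
})

test_that("a planted hotspot drives Z0 into the null tail", {
  fx <- plantedFixture(N = 120, count = 30, background = 8, seed = 52)
  mat <- buildMatrix(fx$model, fx$tally, radii = 1:10, maxSpheres = 3,
                     T = 200, seed = 53)
  expect_gt(mat@Z[1], stats::quantile(mat@Z[-1], 0.99))
})
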