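# Monte-Carlo null and hotspot p-value.
#
# Under the null, every mutation occurrence is placed independently and
# uniformly over the N residues of the structure. For each (s, r) grid cell
# the optimal covered count is computed for the observed data and for each of
# T simulated datasets; each cell is standardized by its simulation mean and
# standard deviation, each dataset keeps its maximum standardized value Z,
# and the p-value is the tail fraction of simulations with Z_i >= Z_0.

#' Simulate uniform-null mutation placements
#'
#' Each simulation reassigns all `totalMutations(tally)` occurrences
#' independently and uniformly (with replacement) over the model's residues;
#' totals are conserved per simulation.
#'
#' @param model a [StructureModel-class].
#' @param tally a [MutationTally-class] (defines the total to place).
#' @param T number of simulations.
#' @param seed integer seed controlling the stream.
#' @param weights optional per-residue placement weights (experimental hook;
#'   the supported null is uniform).
#' @return integer matrix, T x N, simulated per-residue counts.
#' @export
simulateNull <- function(model, tally, T = 1000L, seed = 1L, weights = NULL) {
  n <- nResidues(model)
  total <- totalMutations(tally)
  if (!is.null(weights) && length(weights) != n)
    stop("weights must have one entry per residue")
  withSeed(seed, {
    sims <- matrix(0L, nrow = T, ncol = n)
    for (i in seq_len(T)) {
      hits <- sample.int(n, total, replace = TRUE, prob = weights)
      sims[i, ] <- tabulate(hits, nbins = n)
    }
    sims
  })
}

# evaluate expr with a local RNG state seeded from `seed`
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default (s, r) grid
#'
#' @param radii radii in Angstrom (default 1..10).
#' @param maxSpheres maximum sphere count (default 3).
#' @return data.frame with columns `s` and `r`, ordered by s then r.
#' @export
defaultGrid <- function(radii = 1:10, maxSpheres = 3L) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be positive and strictly increasing")
  expand.grid(r = as.numeric(radii), s = seq_len(maxSpheres))[, c("s", "r")]
}

#' Build the observed-vs-simulated coverage matrix
#'
#' Row 1 holds the observed optimal covered counts per grid cell; rows
#' 2..T+1 re-run the optimizer on each simulated dataset. Cells with no
#' admissible configuration (a geometric property, identical for all rows)
#' or with zero simulation standard deviation are excluded from every row's
#' maximum, and Z_i is the maximum standardized coverage over included cells.
#'
#' @param model a [StructureModel-class].
#' @param tally a non-blank [MutationTally-class].
#' @param radii radii grid in Angstrom (default 1..10).
#' @param maxSpheres maximum sphere count (default 3).
#' @param T number of null simulations (default 1000).
#' @param seed integer seed.
#' @return a [SimulationMatrix-class].
#' @export
buildMatrix <- function(model, tally, radii = 1:10, maxSpheres = 3L,
                        T = 1000L, seed = 1L) {
  if (isBlank(tally))
    stop("blank tally: fewer than two mapped mutation occurrences")
  grid <- defaultGrid(radii, maxSpheres)
  ncell <- nrow(grid)
  dmat <- distanceMatrix(model)
  nbByR <- lapply(unique(grid$r), function(r) neighborhoodList(model, r, dmat))
  names(nbByR) <- as.character(unique(grid$r))

  sims <- simulateNull(model, tally, T = T, seed = seed)
  X <- matrix(NA_real_, nrow = T + 1L, ncol = ncell)
  feasible <- logical(ncell)
  obsCounts <- as.numeric(tally@structureCounts)

  for (ci in seq_len(ncell)) {
    s <- grid$s[ci]
    nb <- nbByR[[as.character(grid$r[ci])]]
    r <- grid$r[ci]
    res <- .sphere_search_cpp(obsCounts, nb, dmat, r, as.integer(s))
    feasible[ci] <- isTRUE(res$feasible)
    if (!feasible[ci]) next   # admissibility depends on geometry only
    X[1L, ci] <- res$covered
    for (i in seq_len(T)) {
      ri <- .sphere_search_cpp(as.numeric(sims[i, ]), nb, dmat, r,
                               as.integer(s))
      X[i + 1L, ci] <- ri$covered
    }
  }

  mu <- rep(NA_real_, ncell)
  sigma <- rep(NA_real_, ncell)
  simRows <- X[-1L, , drop = FALSE]
  mu[feasible] <- colMeans(simRows[, feasible, drop = FALSE])
  sigma[feasible] <- apply(simRows[, feasible, drop = FALSE], 2, stats::sd)
  sigmaZero <- feasible & !is.na(sigma) & sigma == 0
  included <- feasible & !sigmaZero

  Z <- rep(NA_real_, T + 1L)
  if (any(included)) {
    Zmat <- sweep(sweep(X[, included, drop = FALSE], 2, mu[included]),
                  2, sigma[included], "/")
    Z <- apply(Zmat, 1, max)
  }
  grid$feasible <- feasible
  grid$sigmaZero <- sigmaZero
  grid$included <- included
  new("SimulationMatrix", grid = grid, X = X, mu = mu, sigma = sigma,
      Z = Z, T = as.integer(T), seed = as.integer(seed))
}

setMethod("show", "SimulationMatrix", function(object) {
  cat("SimulationMatrix:", object@T, "simulations over",
      nrow(object@grid), "grid cells (", sum(object@grid$included),
      "included )\n")
})

#' Format a Monte-Carlo p-value for reporting
#'
#' @param pValue numeric tail fraction.
#' @param pFloor logical; TRUE when no simulation reached Z_0.
#' @param T number of simulations.
#' @return character(1), e.g. `"<1.00E-03"` at T = 1000.
#' @export
formatPValue <- function(pValue, pFloor, T) {
  if (pFloor) sprintf("<%.2E", 1 / T) else sprintf("%.2E", pValue)
}

#' Monte-Carlo p-value and hotspot extraction
#'
#' The p-value is the fraction of simulations with Z_i >= Z_0 (ties count
#' against significance). When no simulation reaches Z_0 the p-value is
#' floored and reported as "< 1/T". The best cell is the included cell with
#' the largest observed standardized coverage (ties broken by smaller s, then
#' smaller r), and the reported hotspots are the optimal configuration there.
#'
#' @param matrix a [SimulationMatrix-class].
#' @param model the [StructureModel-class] it was built on.
#' @param tally the observed [MutationTally-class].
#' @return a [HotspotResult-class].
#' @export
hotspotPValue <- function(matrix, model, tally) {
  grid <- matrix@grid
  T <- matrix@T
  included <- grid$included
  dmat <- distanceMatrix(model)
  perCell <- lapply(seq_len(nrow(grid)), function(ci)
    bestSpheres(model, tally, grid$s[ci], grid$r[ci], dmat = dmat))
  if (!any(included)) {
    warning("degenerate analysis: every grid cell excluded; p = 1")
    empty <- newSphereConfiguration(model, list(feasible = FALSE),
                                    grid$s[1], grid$r[1])
    return(new("HotspotResult", pValue = 1, pFloor = FALSE,
               pText = formatPValue(1, FALSE, T),
               bestS = NA_integer_, bestR = NA_real_, hotspots = empty,
               perCell = perCell, simulation = matrix))
  }
  Z0 <- matrix@Z[1L]
  Zi <- matrix@Z[-1L]
  count <- sum(Zi >= Z0)
  pValue <- count / T
  pFloor <- count == 0L
  zObs <- (matrix@X[1L, ] - matrix@mu) / matrix@sigma
  zObs[!included] <- -Inf
  bestCell <- which.max(zObs)   # grid ordered by s then r: first max wins ties
  new("HotspotResult", pValue = pValue, pFloor = pFloor,
      pText = formatPValue(pValue, pFloor, T),
      bestS = as.integer(grid$s[bestCell]), bestR = grid$r[bestCell],
      hotspots = perCell[[bestCell]], perCell = perCell,
      simulation = matrix)
}

#' @rdname accessors
#' @export
setMethod("pValue", "HotspotResult", function(x, ...) x@pValue)

setMethod("show", "HotspotResult", function(object) {
  cat("HotspotResult: p", object@pText, "\n")
  if (!is.na(object@bestS)) {
    cat("  best cell: s =", object@bestS, ", r =", object@bestR, "A\n")
    show(object@hotspots)
  }
})

#' Run the full single-structure hotspot analysis
#'
#' Convenience pipeline: simulate the null, build the coverage matrix and
#' compute the hotspot p-value for one structure and tally.
#'
#' @inheritParams buildMatrix
#' @return a [HotspotResult-class].
#' @examples
#' m <- makeStructure(60, geometry = "helix", seed = 7)
#' mut <- makeMutations(m, hotspots = list(list(center = 30, span = 3, count = 20)),
#'                      background = 5, seed = 7)
#' tl <- tallyMutations(mut, reconcile(model = m, mode = "structure_numbering"), m)
#' res <- analyzeTally(m, tl, radii = c(3, 6), T = 100, seed = 1)
#' pValue(res)
#' @export
analyzeTally <- function(model, tally, radii = 1:10, maxSpheres = 3L,
                         T = 1000L, seed = 1L) {
  mat <- buildMatrix(model, tally, radii = radii, maxSpheres = maxSpheres,
                     T = T, seed = seed)
  hotspotPValue(mat, model, tally)
}
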