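# Non-overlapping sphere cover optimization.
#
# Candidate sphere centers are ALL residues (a sphere centered at any residue,
# not only mutated ones, can cover more occurrences). Per radius r, each
# candidate's coverage is the sum of mutation occurrences over its closed-ball
# neighborhood; the s-sphere optimum is found by a best-first traversal of the
# strictly-decreasing index lattice over the coverage-sorted candidates, which
# terminates at the first geometrically admissible (pairwise center distance
# >= 2r) element popped. Tangency (distance exactly 2r) is allowed.

#' Per-candidate coverage at radius r
#'
#' For each residue, the total mutation occurrences within the closed ball of
#' radius r around its alpha-carbon, together with the candidate order sorted
#' by coverage (descending, ties broken by ascending residue index).
#'
#' @param model a [StructureModel-class].
#' @param tally a [MutationTally-class].
#' @param r radius in Angstrom.
#' @param dmat optional precomputed [distanceMatrix()].
#' @return list with `coverage` (numeric length N) and `order` (integer,
#'   residue indices in sorted order).
#' @export
coverageVector <- function(model, tally, r, dmat = NULL) {
  nb <- neighborhoodList(model, r, dmat)
  counts <- tally@structureCounts
  cov <- vapply(nb, function(ix) sum(counts[ix]), numeric(1))
  list(coverage = cov, order = order(-cov, seq_along(cov)))
}

newSphereConfiguration <- function(model, res, s, r) {
  if (isTRUE(res$feasible)) {
    centers <- as.integer(res$centers)
    new("SphereConfiguration", s = as.integer(s), r = as.numeric(r),
        centers = centers,
        centerLabels = model@structurePos[centers],
        covered = as.numeric(res$covered),
        members = lapply(centers, function(ct) neighborhood(model, ct, r)),
        feasible = TRUE)
  } else {
    new("SphereConfiguration", s = as.integer(s), r = as.numeric(r),
        centers = integer(0), centerLabels = character(0),
        covered = NA_real_, members = list(), feasible = FALSE)
  }
}

#' Optimal non-overlapping spheres by best-first search
#'
#' Finds s spheres of common radius r, centered at residue alpha-carbons with
#' pairwise center distances of at least 2r, whose union covers the maximum
#' number of mutation occurrences. The search pops elements of the sorted
#' candidate lattice in non-increasing priority order (priority = sum of
#' per-sphere coverages, an upper bound on the union coverage), so the first
#' admissible element popped is a global optimum; the reported `covered` value
#' is always the recomputed union count.
#'
#' @param model a [StructureModel-class].
#' @param tally a [MutationTally-class].
#' @param s number of spheres (1, 2 or 3; larger values are experimental and
#'   must be enabled with `experimental = TRUE`).
#' @param r radius in Angstrom.
#' @param dmat,nb optional precomputed [distanceMatrix()] /
#'   [neighborhoodList()] (reused heavily by the null simulation).
#' @param experimental allow s > 3.
#' @return a [SphereConfiguration-class]; `feasible` is `FALSE` when no
#'   non-overlapping configuration exists.
#' @examples
#' m <- makeStructure(20, geometry = "linear")
#' mut <- makeMutations(m, hotspots = list(list(center = 5, span = 1, count = 4)))
#' tl <- tallyMutations(mut, reconcile(model = m, mode = "structure_numbering"), m)
#' bestSpheres(m, tl, s = 1, r = 4)
#' @export
bestSpheres <- function(model, tally, s, r, dmat = NULL, nb = NULL,
                        experimental = FALSE) {
  if (s > 3 && !experimental)
    stop("s > 3 is experimental; pass experimental = TRUE")
  if (s > 3) stop("s > 3 is not implemented by the search kernel")
  if (s < 1) stop("s must be >= 1")
  if (nResidues(model) < s)
    return(newSphereConfiguration(model, list(feasible = FALSE), s, r))
  if (is.null(dmat)) dmat <- distanceMatrix(model)
  if (is.null(nb)) nb <- neighborhoodList(model, r, dmat)
  res <- .sphere_search_cpp(as.numeric(tally@structureCounts), nb, dmat,
                            as.numeric(r), as.integer(s))
  newSphereConfiguration(model, res, s, r)
}

#' Traversal order of the candidate lattice
#'
#' Runs the same best-first lattice traversal as [bestSpheres()] but without
#' the non-overlap acceptance test, returning the first `maxPops` elements in
#' the order they are popped. Useful to inspect the search: popped priorities
#' are non-increasing, so the traversal considers sphere pairs/triples from
#' the most to the least promising.
#'
#' @inheritParams bestSpheres
#' @param maxPops number of elements to enumerate.
#' @return data.frame with the sorted-order tuple columns `i`, `j`, `k`
#'   (`k` = 0 for s = 2) and `priority`.
#' @export
enumerateElements <- function(model, tally, s, r, maxPops = 10L,
                              dmat = NULL, nb = NULL) {
  if (is.null(dmat)) dmat <- distanceMatrix(model)
  if (is.null(nb)) nb <- neighborhoodList(model, r, dmat)
  res <- .sphere_search_cpp(as.numeric(tally@structureCounts), nb, dmat,
                            as.numeric(r), as.integer(s),
                            enumerate_only = TRUE,
                            max_pops = as.integer(maxPops))
  tup <- matrix(res$tuples, ncol = 3, byrow = TRUE)
  data.frame(i = tup[, 1], j = tup[, 2], k = tup[, 3], priority = res$pops)
}

#' Brute-force oracle for the sphere optimizer
#'
#' Exhaustively enumerates all s-subsets of residue centers, keeps those with
#' pairwise center distances >= 2r, and maximizes the union coverage; ties are
#' broken by the lexicographically smallest center tuple. Exponential in s and
#' guarded to N <= 50: this is a verification oracle, not the production
#' search path, and shares no code with the best-first kernel.
#'
#' @inheritParams bestSpheres
#' @param maxN guard on the structure size (default 50).
#' @return a [SphereConfiguration-class].
#' @export
bruteForceSpheres <- function(model, tally, s, r, maxN = 50L) {
  n <- nResidues(model)
  if (n > maxN)
    stop("brute force refused: N = ", n, " exceeds guard ", maxN)
  if (n < s)
    return(newSphereConfiguration(model, list(feasible = FALSE), s, r))
  dmat <- distanceMatrix(model)
  nb <- neighborhoodList(model, r, dmat)
  counts <- tally@structureCounts
  combos <- utils::combn(n, s)
  best <- NULL
  bestCov <- -Inf
  for (ci in seq_len(ncol(combos))) {
    cen <- combos[, ci]
    if (s > 1) {
      d <- dmat[cen, cen, drop = FALSE]
      if (any(d[upper.tri(d)] < 2 * r - 1e-9)) next
    }
    covered <- sum(counts[unique(unlist(nb[cen]))])
    if (covered > bestCov) {  # combn order is lexicographic: first win = lex smallest
      bestCov <- covered
      best <- cen
    }
  }
  if (is.null(best))
    return(newSphereConfiguration(model, list(feasible = FALSE), s, r))
  newSphereConfiguration(model,
                         list(feasible = TRUE, centers = best,
                              covered = bestCov), s, r)
}

#' Size of the s-sphere search space
#'
#' Number of candidate center subsets for s spheres on an N-residue protein
#' (ignoring the non-overlap constraint): N for one sphere, choose(N, 2) for
#' two, choose(N, 3) for three.
#'
#' @param N protein length in residues.
#' @param s number of spheres.
#' @return numeric count.
#' @examples
#' searchSpaceSize(1068, 3)  # 202,461,116
#' @export
searchSpaceSize <- function(N, s) {
  choose(N, s)
}

#' @rdname accessors
#' @export
setMethod("sphereCenters", "SphereConfiguration", function(x, ...) x@centers)

#' @rdname accessors
#' @export
setMethod("coveredMutations", "SphereConfiguration", function(x, ...) x@covered)

setMethod("show", "SphereConfiguration", function(object) {
  if (object@feasible) {
    cat("SphereConfiguration: s =", object@s, ", r =", object@r,
        "A; centers", paste(object@centerLabels, collapse = ", "),
        "; covered =", object@covered, "\n")
  } else {
    cat("SphereConfiguration: s =", object@s, ", r =", object@r,
        "A; infeasible (no non-overlapping configuration)\n")
  }
})

#' Serialize a sphere configuration to a JSON-ready list
#'
#' @param config a [SphereConfiguration-class].
#' @param model the [StructureModel-class] it was computed on.
#' @return list suitable for [jsonlite::write_json()].
#' @export
configAsList <- function(config, model) {
  list(s = config@s, r = config@r, feasible = config@feasible,
       covered = if (config@feasible) config@covered else NULL,
       spheres = if (config@feasible) lapply(seq_along(config@centers),
         function(ix) list(
           center_label = config@centerLabels[ix],
           radius = config@r,
           member_residues = model@structurePos[config@members[[ix]]])) else list())
}
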