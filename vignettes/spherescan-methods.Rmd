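---
title: "SphereScan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SphereScan: methods and design notes}
  %\VignetteEncoding{UTF-8}
---

# The model

SphereScan tests whether somatic missense mutations cluster in
three-dimensional space on a protein structure more than uniform chance
allows. The ingredients:

- **Geometry.** Each residue is a single point, its α-carbon coordinate in
  Å. A candidate hotspot is a closed ball of radius *r* around a residue's
  α-carbon; "within the sphere" means distance ≤ *r*. Candidate centers are
  *all* residues, not only mutated ones: a sphere centered between two
  mutated residues can cover more occurrences than one centered on either.
- **Counts.** Mutations are aggregated at the sample level over all sources
  (tumor samples, cell lines): two samples mutating the same residue
  contribute two occurrences. Only missense substitutions with an accepted
  somatic status from whole-gene or whole-genome screens enter the tally,
  and exact duplicates on (gene, sample, position, wild-type, mutant) are
  removed so one cell line reported by several studies is counted once.
- **The optimum.** For sphere counts *s* ∈ {1, 2, 3} and each radius on the
  grid (default 1–10 Å), X₀,ₛ,ᵣ is the maximum number of occurrences covered
  by the union of *s* spheres whose pairwise center distances are ≥ 2*r*.
  The non-overlap constraint keeps mutation-to-sphere assignment
  unambiguous: overlapping optima would collapse onto the same strong
  cluster and report it several times.
- **The null.** Every residue is equally likely to be hit. Each of *T*
  simulations redistributes all occurrences independently and uniformly over
  the *N* residues and re-solves the same optimization. Sample identity is
  discarded under the null: the statistic depends only on the aggregated
  count vector, so per-occurrence multinomial placement loses nothing.
- **The statistic and p-value.** Each (s, r) cell is standardized by its
  simulation mean and standard deviation; each dataset (observed and each
  simulation) keeps the maximum standardized value Z over the grid; the
  p-value is #{i : Zᵢ ≥ Z₀}/T. Taking a single row-maximum gives one p-value
  per structure regardless of how many hotspots are reported, avoiding any
  per-pair multiple-comparison penalty. Ties Zᵢ = Z₀ count against
  significance. When the count is zero the p-value is reported as "< 1/T"
  (at T = 1000, "<1.00E-03").
- **Across structures.** With *k* analyzed structures, significance is
  assessed at the rough-FDR cutoff α(k + 1)/(2k), a good approximation to
  FDR control for large numbers of positively correlated or independent
  tests. The effective threshold is rounded *down* (default 3 decimals, so
  α = 0.05 and k = 1110 give 0.025) for conservatism.

# The search

For fixed (s, r), candidates are sorted by per-sphere coverage (descending,
ties by ascending residue index). Elements of the strictly-decreasing index
lattice — pairs (i, j) with i > j for s = 2, triples (i, j, k) with
i > j > k for s = 3 — carry the priority c(i) + c(j) (+ c(k)), the sum of
per-sphere coverages. Starting from the top element ((2,1) or (3,2,1)), the
search pops the maximum-priority element, tests the geometric non-overlap of
its centers, and either terminates (the first admissible pop is a global
optimum, since priorities never increase along the traversal and priority
bounds union coverage from above) or pushes the element's lattice successors
(each coordinate advanced by one where strict decrease allows). The reported
`covered` value is always the recomputed union count, never the priority, so
coverage is never over-reported even in the boundary case where a residue is
tangent to two spheres.

Properties relied on and tested:

- popped priorities are non-increasing (asserted inside the kernel);
- the result equals a brute-force scan over all C(N, s) subsets on hundreds
  of random instances (the oracle is an independent R implementation);
- covered counts are monotone in *s* (when feasible) and, for one sphere, in
  *r*.

When no admissible configuration exists (e.g., three spheres on a structure
whose residues all sit within 2*r* of each other) the cell is flagged
infeasible. Admissibility depends only on the geometry, not on the counts,
so an infeasible cell is excluded for the observed row and every simulation
alike.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| radii | 1–10 | Å | spans one-residue to multi-turn neighborhoods at the canonical 3.8 Å Cα–Cα spacing; optimal radii in practice fall well inside the grid, and larger values can be supplied |
| maxSpheres | 3 | — | hotspot counts above three are rare, and the worst-case search cost grows as N^s |
| T | 1000 | simulations | resolves p-values to 10⁻³; larger T sharpens the floor |
| alpha | 0.05 | — | nominal level entering the rFDR threshold |
| identityFloor | 0.90 | fraction | below this alignment identity, reconciliation fails rather than risk a silently wrong residue mapping |
| gap opening / extension | 10 / 0.5 | score | standard global protein-alignment penalties with BLOSUM62 |

# Reconciliation

Mutation databases number residues in the canonical protein sequence;
coordinate files use author numbering that may be offset, gapped, or
decorated with insertion codes. Two modes are provided:
`structure_numbering` trusts the author numbers (canonical position p maps
to the residue numbered p), and `alignment` (the robust default for real
data) maps positions through the aligned non-gap columns of a global
pairwise alignment between the canonical sequence and the structure-derived
sequence. Wild-type letters disagreeing with the canonical sequence raise a
warning, not an error — isoform drift between databases is common enough
that a hard failure would be brittle. Structures with coordinates for fewer
than two mutation occurrences are "blank": no clustering is possible, and
they are excluded before the study-level k is counted.

Structure ingest keeps the first chain appearing in the ATOM records (unless
one is requested), the first MODEL block (user-overridable), and the first
encountered alternate location of each atom; residues missing an α-carbon
are skipped and the reconciliation step maps around the gap. HETATM-coded
amino acids (e.g., selenomethionine) are excluded by default and can be
opted in.

# Numerical choices

- Closed-ball membership and the non-overlap test use a 10⁻⁹ Å guard
  (d ≤ r + ε, d ≥ 2r − ε) so that exact-boundary cases — common in
  synthetic lattices where distances are exact multiples of the spacing —
  are not decided by floating-point representation error. Tangency (centers
  exactly 2r apart) is admissible.
- Ties are broken deterministically everywhere: candidate sorting by
  ascending residue index, heap pops by lexicographically smallest tuple,
  brute-force ties by lexicographically smallest center set, best-cell ties
  by smaller s then smaller r.
- Cells with zero simulation standard deviation (e.g., a radius so large
  that every placement is fully covered) carry no ordering information and
  are excluded from every row's maximum; if every cell is excluded the
  analysis is degenerate and p = 1 is reported with a warning.
- Simulation means and standard deviations are computed over the simulation
  rows only; the observed row is not included.
- Floored p-values ("< 1/T") are compared against study thresholds as
  1/(2T), the midpoint of what the floor asserts; at T = 1000 any floored
  value passes a 0.025 threshold.
- Every source of randomness flows from one master seed. Per-structure
  sub-seeds are a stable 31-based string hash of (seed, structure id) modulo
  2³¹ − 1, so study results are independent of manifest row order and
  reproducible from the result file alone.

# The synthetic generator

`makeStructure()` emits ideal backbones — a straight line at 3.8 Å spacing,
an ideal α-helix (rise 1.5 Å, 100° per residue, radius 2.3 Å, consecutive
Cα distance ≈ 3.83 Å), or a self-avoiding random coil (spacing ± 0.1 Å,
4 Å exclusion between non-adjacent residues) — and `makeMutations()` plants
a uniform background plus optional concentrated hotspot spans, with
metadata chosen so the ingest filters are a no-op. With zero hotspots the
generator follows exactly the law of the null simulation, which is what the
calibration test exploits: over 500 background-only datasets (100-residue
helix, 30 mutations, default grid, T = 200) the empirical P(p ≤ 0.05) must
sit within ±0.03 of 0.05. The planted-hotspot recovery test (200 residues,
50 mutations in a 3-residue span, 10 background, T = 1000) must floor the
p-value and recover the span. These problem sizes keep the full suite
comfortably desk-scale while leaving the Monte-Carlo error well inside the
asserted bands.

What the generator does **not** emulate: real folds (loops, domains,
contact order), heterogeneous residue-level mutability (CpG context,
transcription-coupled repair), isoform mismatch beyond simple truncation,
and correlated samples. Passing tests therefore demonstrate correctness of
the machinery and calibration under the stated uniform null — not that the
uniform null is adequate for any particular real protein. The null
simulator exposes a per-residue weight hook for non-uniform placement, but
only the uniform null is supported, documented behavior.

# Known limitations

- At most three spheres by default (s > 3 is accepted behind an
  experimental flag but unsupported); per-sphere heterogeneous radii are
  not considered.
- One chain and one conformation per analysis; no mmCIF input; side-chain
  atoms are ignored by construction of the α-carbon representation.
- The worst-case search cost is the full C(N, s) enumeration when spheres
  keep overlapping; in practice the first admissible pop arrives within a
  handful of iterations.
- The rFDR adjustment is the only multiple-structure correction offered;
  per-gene summaries report the minimum p-value over a gene's structures
  and are flagged as such, with per-structure rows remaining authoritative.
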