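# SphereScan

Identification of statistically significant 3D mutational hotspots on
protein structures.

## The problem

A small set of somatic "driver" mutations push a tumor forward while a much
larger body of "passenger" mutations accumulate without effect. Drivers tend
to cluster in functionally important regions of a protein — binding pockets,
activation loops — and those regions are spatial, not sequential: residues
far apart in the sequence can sit next to each other in the folded
structure. Methods that test mutation clustering along the 1D sequence, or
that remap the structure to 1D before testing, lose that information and pay
a multiple-comparison penalty for examining every pair of mutations.

SphereScan works directly in 3D. Each residue is represented by its
α-carbon coordinates; aggregated, sample-level missense mutation counts are
mapped onto the residues; and the method asks how many mutations the best
*s* non-overlapping spheres of radius *r* can cover, compared with what
uniform chance would allow.

## The statistic

For sphere counts *s* ∈ {1, 2, 3} and radii *r* ∈ {1, …, 10} Å:

- *X*₀,ₛ,ᵣ = the maximum number of mutation occurrences covered by *s*
  spheres of radius *r* centered at residue α-carbons with pairwise center
  distances ≥ 2*r* (so no two spheres overlap and every mutation belongs to
  one sphere).
- *T* ≥ 1000 null datasets are simulated by placing each mutation occurrence
  independently and uniformly over the *N* residues; *X*ᵢ,ₛ,ᵣ is the same
  optimum for simulation *i*.
- Each (s, r) cell is standardized by its simulation mean and standard
  deviation, μₛ,ᵣ and σₛ,ᵣ, and each dataset keeps its maximum standardized
  value Zᵢ = maxₛ,ᵣ (Xᵢ,ₛ,ᵣ − μₛ,ᵣ)/σₛ,ᵣ.
- The structure's single p-value is #{i : Zᵢ ≥ Z₀}/T, reported as
  "< 1/T" when no simulation reaches the observed Z₀.

The optimizer sorts candidate centers by per-sphere coverage and walks the
strictly-decreasing index lattice best-first: popped priorities (sums of
per-sphere coverages) never increase, so the first geometrically admissible
element popped is a global optimum — typically after a handful of pops
rather than the ~N³/6 subsets a brute-force scan would visit. A brute-force
oracle is included and the equivalence is property-tested.

Across *k* structures, hotspots are flagged at the rough false-discovery-rate
threshold rFDR = α(k + 1)/(2k), rounded down for conservatism.

## Worked example

Everything below is generated in code — a 200-residue ideal helix with 50
mutations planted in the 3-residue span 99–101 plus 10 background mutations
spread over 5 samples:

```r
library(SphereScan)

model   <- makeStructure(200, geometry = "helix", seed = 101)
muts    <- makeMutations(model,
                         hotspots = list(list(center = 100, span = 3, count = 50)),
                         background = 10, nSamples = 5, seed = 102)
mapping <- reconcile(model = model, mode = "structure_numbering")
tally   <- tallyMutations(muts, mapping, model)
tally
#> MutationTally: 60 mapped occurrence(s) at 13 position(s); 0 dropped

result <- analyzeTally(model, tally, radii = 1:10, T = 1000, seed = 103)
result
#> HotspotResult: p <1.00E-03
#>   best cell: s = 1 , r = 4 A
#> SphereConfiguration: s = 1 , r = 4 A; centers 100 ; covered = 50
```

No simulation out of 1000 reached the observed maximum standardized
coverage, so the p-value is floored at < 1.00E-03; the best cell is a single
4 Å sphere at residue 100 covering all 50 planted mutations. The rFDR
threshold that would apply in a 1,110-structure study is

```r
rfdrThreshold(0.05, 1110)
#> [1] 0.02502252
```

For real data, read the structure with `readStructure("file.pdb")`, the
mutation table with `readMutations("muts.tsv")` (TSV columns `gene`,
`sample_id`, `position`, `wt_aa`, `mut_aa`, `mutation_type`,
`somatic_status`, `screen_type`), filter with `filterMutations()`, and
reconcile numbering by pairwise alignment against the canonical sequence
(`reconcile(seq, model, mode = "alignment")`). Multi-structure studies run
from a manifest via `runStudy()`, or from the shell via
`inst/cli/spherescan.R` (subcommands `analyze`, `study`, `fixtures`).

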