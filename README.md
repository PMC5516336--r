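# kgs2 — reference-anchored rescoring of protein–ligand binding affinities

Scoring functions used in structure-based drug design predict binding
affinity from a complex's 3D structure, but their errors are large and
systematic: related complexes tend to be mis-scored the same way. `kgs2`
improves any scoring function's predictions — without modifying the
scoring function — by finding, in a library of complexes with measured
affinities, a **reference complex** that closely resembles the query, and
anchoring the query's prediction to the reference's experimental value:

```
Q̂_bind = R_exp + k · (Q_score − R_score)        (anchored)
Q̂_bind = b + k · Q_score                        (fallback, no reference)
```

where `k` and `b` come from an ordinary linear regression of experimental
affinities (in logKa units, i.e. −log Kd/Ki/IC50) on raw scores over a
training set. Subtracting the reference's raw score cancels the scoring
function's shared systematic error; what remains is the smaller
uncertainty of the reference's measured affinity.

The resemblance judgment is structural. Each complex is reduced to a **3D
interaction fingerprint**:

1. **Interaction units** — every (3 covalently bonded protein heavy atoms,
   1 ligand heavy atom) contact within vdW radii + 1 Å, typed like
   `GLY:CA-C-O|O.2`, with the ligand atom expressed in the fragment's
   local frame.
2. **Interaction patterns** — per unit type, preferred geometries mined
   from a structure library with Gaussian mixtures
   `p(x) = Σ π_k N(x | μ_k, Σ_k)` (≤ 15 components, BIC-selected);
   components kept with occurrence > 100 and weight ≥ 0.01.
3. **Fingerprint nodes** — each pocket unit matching a pattern
   (Mahalanobis distance D < 2.5) contributes a node pair: the residue's
   Cα (labelled by residue type) and the ligand atom (labelled by SYBYL
   type).
4. **Similarity** — node sets are compared by a correspondence graph
   (distance-compatibility ratio 1.1), Bron–Kerbosch maximum cliques,
   Kabsch superposition, and one-to-one overlap counting (< 1 Å); with
   ≥ 5 overlapped pairs the Tanimoto index
   `SI = N_pq / (N_p + N_q − N_pq)` ranks candidate references
   (selection cutoff `SI ≥ 0.10` by default).

The package reads PDB proteins and Mol2/SDF ligands (PDBbind-layout
directories work unmodified via a TSV index), and includes calibration,
set evaluation (Pearson R and regression SD), docking-pose re-ranking, a
cutoff-sweep applicability analysis, and a synthetic fixture generator
that plants known interaction patterns so the entire pipeline is testable
offline.

## Worked example

```r
library(kgs2)

# a small synthetic reference library of twinned complexes
lib <- make_library(n_pairs = 12, seed = 1)

# mine interaction patterns (unit occurrences inflated for a small library)
units <- aggregate_units(lib$complexes)
set.seed(99)
patterns <- mine_patterns(replicate_units(units, times = 5, jitter_sd = 0.2))
#> <kgs_pattern_library> 4 patterns across 4 unit types (from 480 units)

# fingerprint all complexes; search a reference for one query
fps <- fingerprint_library(lib$complexes, patterns)
fps[["CPX001"]]
#> <kgs_fingerprint> CPX001 - 8 nodes ( 4 protein / 4 ligand )
hit <- search_reference(fps[["CPX001"]], fps, kgs_config())
hit$reference
#> <kgs_similarity> CPX001 vs CPX002: Np=8 Nq=8 Npq=8 SI=1.000 (qualified)

# calibrate the scoring function, then anchor the query's score
cal <- calibrate(lib$scores)
cal
#> <kgs_calibration> k=0.4152 b=1.777 R=0.883 SD=1.101 (n=24)
raw <- setNames(lib$scores$raw_score, lib$scores$complex_id)
adj <- score_query(lib$complexes[["CPX001"]], raw[["CPX001"]], fps, raw,
                   cal, patterns)
```

The query's raw score is 13.29. Its fingerprint's best qualified match is
its planted twin `CPX002` (SI = 1.00), whose experimental affinity anchors
the prediction to **8.78 logKa** — against a true affinity of 8.81 —
whereas the plain calibrated score (the fallback `b + k·Q_score`) would
give 7.30. The gap between the two is exactly the systematic score error
that anchoring cancels.

A thin command line wraps the same functions
(`exec/kgs2 <make-fixtures|mine-patterns|fingerprint|search|calibrate|score|rerank>`);
every run writes its resolved configuration next to its outputs.

## Scope

Base scoring functions are consumed as numeric inputs, never computed.
Pose generation, protonation/structure repair, and treatment of structural
waters or metal ions as interaction partners are out of scope; virtual
screening is not a supported use.
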