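---
title: "Reference-anchored rescoring with 3D protein-ligand interaction fingerprints"
author: "kgs2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored rescoring with 3D protein-ligand interaction fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgs2)
```

## The idea

Scoring functions estimate the binding affinity of a protein-ligand complex
from its 3D structure, but their errors are large and, importantly,
*systematic*: two closely related complexes tend to be mis-scored in the
same direction. kgs2 exploits this. Instead of trusting the calibrated
linear map from raw score to affinity,

$$\hat{Q}_{bind} = b + k \cdot Q_{score},$$

it looks for a **reference complex** $R$ in a library of complexes with
known experimental affinities that closely resembles the query $Q$, and
anchors the prediction to the reference's measured value $R_{exp}$:

$$\hat{Q}_{bind} = R_{exp} + k \cdot (Q_{score} - R_{score}).$$

Subtracting the two raw scores cancels whatever systematic error the
scoring function makes on this *kind* of complex; what remains is the
(much smaller) uncertainty of the reference's experimental affinity. The
slope $k$ (logKa per score unit) is obtained once per scoring function by
ordinary least squares of experimental affinity on raw score over a
training set (`calibrate()`); the same fit supplies the fallback intercept
$b$ used when no acceptable reference exists.

Everything else in the package serves one purpose: deciding, from 3D
structure alone, *which* library complex resembles the query enough to be
its anchor.

## From structures to interaction units

A complex is read from a PDB file (protein) and a SYBYL Mol2 or SDF file
(ligand); Mol2 is preferred because it carries SYBYL atom types (`O.2`,
`C.3`, ...) verbatim, while for SDF the type is perceived from element and
bond orders by a documented table. Hydrogens are excluded throughout; van
der Waals radii follow Bondi (1964).

The elementary descriptor is the **interaction unit**: three covalently
bonded heavy atoms of one residue (the *protein fragment*) plus one ligand
heavy atom in contact, where contact means a centre-to-centre distance
below the sum of the two vdW radii plus a 1 A margin. Each unit is typed
by a string such as `GLY:CA-C-O|O.2` (residue, fragment atom names in a
canonical orientation, ligand SYBYL type), and its geometry is reduced to
the ligand atom's coordinates in the fragment's local frame: origin at the
middle atom, x axis toward the first end atom, xy plane through all three,
z axis toward the ligand's side. This makes unit geometry invariant under
rigid motion of the complex, which the test suite checks directly.

Two conventions the unit definition needs but the geometry does not fix:
fragment paths are oriented so the first end atom's name is
lexicographically smallest (ties broken by serial number), and fragments
whose internal angle at the middle atom is below 1 degree are discarded as
collinear (their frame would be numerically meaningless).

## Mining interaction patterns

Across a large structure library the same unit type recurs thousands of
times, and its local-frame positions concentrate around preferred
geometries. Each type's point cloud is modelled as a Gaussian mixture

$$p(x) = \sum_{k=1}^{K} \pi_k \, N(x \mid \mu_k, \Sigma_k), \qquad K \le 15.$$

The effective number of components is selected automatically:
`fit_gmm()` fits mixtures with 1 to 15 components by EM (mclust) and keeps
the one favoured by BIC, so unnecessary components are removed from the
model rather than carried along with near-zero weight. (A variational
treatment with a sparsifying weight prior would accomplish the same
pruning; BIC model selection was chosen because it is the established,
deterministic route in R and exposes no tuning beyond $K_{max}$.)
Components with weight below $10^{-3}$ are additionally flagged as pruned.
Covariances are regularized to an eigenvalue floor of $10^{-4}$ A^2 so
degenerate clouds cannot produce singular matrices.

A component is promoted to an **interaction pattern** iff its unit type
occurred at least 100 times, the component itself has more than 100
assigned units (hard assignment by maximum responsibility; expected soft
counts are available behind a flag), and its weight is at least 0.01.
These thresholds are calibrated for libraries of thousands of complexes;
they are configurable, and the package's synthetic test libraries reach
them by jittered replication of their unit clouds (`replicate_units()`)
rather than by lowering them.

## Fingerprints and their comparison

To represent one complex, its binding pocket is defined as all residues
within 4.5 A of the ligand, pocket units are extracted, and each unit is
compared against the pattern library of its type with the Mahalanobis
distance

$$D(x, g) = \sqrt{(x - \mu_g)^\top \Sigma_g^{-1} (x - \mu_g)};$$

$D < 2.5$ is a match, and one unit may match several components. Every
matched pattern is then *degraded* into a pair of typed 3D nodes: one on
the residue's C-alpha carrying the residue type, one on the ligand atom
carrying its SYBYL type. Distinct patterns between the same residue and
ligand atom collapse to a single node pair (a multiplicity count is kept
as metadata but plays no role in scoring). The resulting node set is the
complex's **fingerprint**; pocket residues that contribute no pattern do
not appear in it.

Two fingerprints $P$ and $Q$ are compared geometrically:

1. Every same-kind, same-label node pair $(p, q)$ becomes a vertex of a
   correspondence graph; two vertices are joined iff neither node is
   reused and their intra-set distances agree within a ratio of 1.1
   (equal distances, including zero, are compatible by convention).
2. All maximum cliques are found (Bron-Kerbosch with pivoting, via
   igraph); each clique seeds a least-squares rigid superposition (Kabsch,
   proper rotations only; cliques smaller than 3 give an under-determined
   rotation and fall back to centroid translation).
3. After superposition, matched pairs closer than 1 A are counted as
   overlapped, one-to-one, resolving conflicts greedily by increasing
   distance. Every maximum clique is tried and the solution with the most
   overlapped pairs, $N_{pq}$, is retained — enumerating all maximum
   cliques (rather than an arbitrary one) is what makes the result
   independent of vertex order.
4. The similarity index is the Tanimoto coefficient
   $SI_{pq} = N_{pq} / (N_p + N_q - N_{pq})$.

Comparison runs internally in a canonical direction (the lexicographically
smaller complex id acts as $P$), so $SI(P,Q) = SI(Q,P)$ holds exactly. A
correspondence graph larger than 2000 vertices aborts with an explicit
"too large" condition rather than running an unbounded clique search.

A library complex qualifies as a reference only with at least **five**
overlapped node pairs and $SI$ at or above the selection cutoff (default
0.10, the permissive setting appropriate for pose re-ranking; higher
cutoffs trade applicability for accuracy). Ties are broken by $SI$, then
$N_{pq}$, then complex id. A `protein_only` comparison mode restricts both
node sets to pocket-residue nodes, reproducing the protein-structure-only
variant of the method for comparison studies.

## Scoring, evaluation, and pose re-ranking

`score_query()` glues the pipeline together: fingerprint the query, search
the reference library (always excluding the query's own id), and apply the
anchored adjustment, or the calibrated linear map when no reference
qualifies (the `fallback` flag records which happened).
`evaluate_set()` reports the Pearson correlation $R_p$ and, as the
size-independent accuracy measure, the residual standard deviation of the
regression of experimental on predicted values (raw RMSE is reported
alongside, since the two differ when predictions are biased).
`sweep_applicability()` recomputes a scored set at a grid of $SI$ cutoffs,
yielding the applicability/accuracy trade-off curves. For docking,
`rerank_poses()` scores each pose of a ligand independently and takes the
top adjusted score as the ligand's predicted affinity; when every pose
falls back, the ranking reduces to the raw-score ranking because the
linear map is monotone.

## The synthetic fixture generator

Real structure libraries are large, licensed, and slow to process, so the
package ships a generator of fully synthetic complexes with *planted*
ground truth (`make_complex()`, `make_library()`). Each toy complex is a
set of idealized glycine/alanine residues placed with random rotations at
mutually distant positions (>= 15 A), each hosting one ligand atom placed
just inside the contact limit of the backbone carbonyl oxygen — a geometry
chosen so each planted atom yields exactly one interaction unit of a known
type key, making every stage hand-checkable. Libraries are built as twin
pairs: twins share a residue layout (up to positional jitter and a random
global rigid motion), so each complex's nearest fingerprint neighbour is
its twin by construction; distinct pairs get independent layouts and stay
dissimilar. Raw scores follow a linear model whose error has a component
shared within each twin pair — the generative form of the error
cancellation the anchored score relies on — plus the reference-affinity
noise `sigma_ref`; `simulate_anchoring()` isolates that error model
numerically.

What these fixtures do *not* emulate: real protein chemistry (the toy
ligand is a typed point set chained by formal single bonds), crowded
pockets with overlapping contacts, structural waters and metal ions,
protonation variability, or the scale of real libraries. Passing tests
therefore demonstrate the correctness of the algorithms and their
contracts, not predictive performance on experimental data.

Problem sizes used by the test suite were chosen to keep the full run
under a minute while leaving no stage untested: 12 twin pairs (24
complexes) for pipeline closure, unit clouds inflated 5x by jittered
replication for pattern mining at the default thresholds, 1000-point
clouds for mixture recovery, 200 simulated queries for the Monte-Carlo
error comparison, and 100 random rigid motions for invariance checks.

## Degenerate inputs and numerical conventions

* Alternate locations in PDB files: highest occupancy wins, ties go to the
  first conformer encountered.
* Nonstandard residues are parsed but excluded from unit extraction (their
  type keys could never reach the occurrence threshold).
* Unknown elements get the 1.70 A default radius with a warning; unknown
  ligand atom types are recorded as `"Any"`.
* Residues lacking a C-alpha cannot host fingerprint nodes; their patterns
  are dropped with a warning.
* An empty pocket, an empty fingerprint, or an empty reference library are
  all valid states that propagate to a fallback prediction rather than an
  error; a reference *found* but missing its raw score is an error, since
  the anchored formula cannot be evaluated.
* All affinities are handled in logKa units (-log Kd/Ki/IC50,
  interchangeably); coordinates are in Angstrom throughout.

## Known limitations

The method is only as good as its reference library: a query from a novel
target family may find no qualified reference and silently degrade to the
calibrated linear map (watch the `fallback` column). Bridging waters and
metal ions are not part of the unit definition, so pockets dominated by
them are represented poorly. All matched patterns contribute equally to
the similarity index — a hydrogen bond counts as much as a hydrophobic
contact. And the geometric comparison assumes rigid pockets; large induced
fit between query and reference defeats the anchoring premise.
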