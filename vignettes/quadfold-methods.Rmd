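---
title: "quadfold: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadfold: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfold)
```

This vignette records the scientific models behind `quadfold`, the numeric
conventions and defaults that matter, what the synthetic generator emulates,
and the design choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Sugar pseudorotation

Furanose pucker is described in the phase/amplitude formalism. The five
endocyclic torsions are indexed

    nu0 = C4'-O4'-C1'-C2'     nu1 = O4'-C1'-C2'-C3'
    nu2 = C1'-C2'-C3'-C4'     nu3 = C2'-C3'-C4'-O4'
    nu4 = C3'-C4'-O4'-C1'

and the inverse relation is

$$\tan P = \frac{(\nu_4+\nu_1)-(\nu_3+\nu_0)}{2\,\nu_2(\sin 36^\circ + \sin 72^\circ)},
\qquad \tau_m = \nu_2 / \cos P,$$

with $P$ shifted by 180° when $\nu_2 < 0$ and mapped to $[0^\circ, 360^\circ)$
(implemented with `atan2`, which absorbs the shift). The forward cosine model
is $\nu_j = \tau_m\cos(P + 144^\circ (j-2))$. On inputs that satisfy the
cosine model exactly, `pseudorotation(torsions_from_pucker(P, tau))` is an
identity to $10^{-9}$ degrees (property-tested over the whole wheel). The
index convention is stated prominently because an index or sign slip shifts
$P$ by multiples of 72°.

**Near-planar rings.** Below $\tau_m <$ 5° (default) the phase is flagged
undefined instead of erroring: $P$ is numerically unstable there, and an NMR
or modelling pipeline should see the amplitude, not a pseudo-precise phase.

**Classification.** Octants are 45° bins centered on north = 0°,
north-east = 45°, …; canonical labels are the twenty standard 18° envelope /
twist bins (C3′-endo at 18°, C4′-exo at 54°, C2′-endo at 162°, …). All bins
are left-closed, so classification is total and unambiguous. No "typical
north range" is hard-coded anywhere; octants and canonical bins are the only
vocabulary the package emits.

## 2. Glycosidic conformers

χ is O4′–C1′–N9–C4 (purines) / O4′–C1′–N1–C2 (pyrimidines), IUPAC-signed.
Default classes: *syn* for χ ∈ [0°, +90°], *high-anti* for χ ∈ [−90°, 0°),
*anti* otherwise (including the (+90°, 180°] wrap side). Rationale: syn
guanines in quadruplexes cluster near +60–80°, anti near −120°, and a
distinct high-anti band is needed to describe the far-high-anti V-loop
anchors reported for some bimolecular folds. The ranges are config-overridable
and boundary behaviour is covered by explicit tests.

## 3. Topology detection

* **Hoogsteen edges** use heavy-atom criteria by default — N1(i)–O6(j) ≤ 3.5 Å
  and N2(i)–N7(j) ≤ 3.5 Å plus an inter-base-plane angle ≤ 35° — because NMR
  depositions may lack or misplace hydrogens. A directed edge i→j is a
  donor→acceptor statement; tetrads are the simple directed 4-cycles of this
  graph, reported from their lowest residue index. A residue claimed by two
  4-cycles is an ambiguity error, not a silent choice.
* **Stack axis** is the principal axis of the tetrad centroids (robust to
  bent stacks; no external reference frame). Its sign is fixed so the
  5′-most core tract runs "up"; per-residue backbone direction is the sign of
  the C5′→C3′ projection on the axis. Layer 0 is the outer tetrad containing
  the lowest-numbered core guanine found in either outer tetrad.
* **Stacking polarity**: each tetrad's cycle sense is the sign of the
  projected signed area of its donor cycle; matching senses across an
  interface = homopolar, otherwise heteropolar. Only relative senses matter,
  so the global axis sign cannot flip this.
* **Columns** are extracted by optimal assignment (all 4! permutations) of
  residues between adjacent layers by base-centroid distance; ties are thus
  resolved by minimizing the total assignment distance. `broken` flags
  sequence-discontiguous columns; a strand inversion is an adjacent layer
  pair within a column whose residues run in opposite directions.
* **Loops** are classified from the anchors of every connector between
  consecutive core residues in different columns: same outer face + adjacent
  columns → lateral; same face + diagonal columns → diagonal; opposite faces
  + adjacent columns → propeller when the columns are parallel, V when they
  are antiparallel. A V connector may contain zero intervening residues.
* **V-loop records** carry anchor χ classes and puckers and a `turn_locus`:
  if the two anchors run in the same direction the backbone turn must sit
  between the 3′ anchor and its tract neighbour (`within_following_tract`,
  detected as an intra-column inversion there); anchors running in opposite
  directions put the turn between the linked residues themselves
  (`between_linked_residues`). Anchors not on opposite outer tetrads are a
  classification error with diagnostics.

**Cycle direction convention.** Whether the deposited Hoogsteen donor
direction corresponds to the package's edge direction could in principle be
globally reversed for an entry; `reverse_cycle_direction` in the topology
config flips it without touching anything else.

## 4. Grooves

For each cyclically adjacent column pair the mean same-layer P–P distance is
mapped to labels with defaults **narrow < 14 Å ≤ medium < 18 Å ≤ wide**
(C1′–C1′ fallback with 13/16.5 Å when phosphates are absent). The source
literature uses qualitative labels only; these numbers were calibrated once
on the synthetic templates — the canonical parallel fold must read
medium/medium/medium/medium and the V-loop fold medium/medium/wide/narrow
with the narrow groove spanned by the V-loop — and are exposed in the
configuration and echoed in reports. They are a package decision, not a
community standard.

## 5. Karplus inversion

Each coupling path is governed by one ring torsion through a linear map
θ = a·ν_k + b (H1′ paths → ν₁, H2′/H3′ paths → ν₂, H3′–H4′ → ν₃) and a
three-term Karplus relation. `fit_pseudorotation` evaluates the forward
model on a (P, τ_m) lattice — default P step 1°, τ_m 25–45° step 1°,
matching the tens-of-degrees precision at which pseudorotamer intervals are
quoted in the field — and reports:

* the χ² surface (diagnostics),
* the best node,
* the **compatible set**: nodes where every observed path is reproduced
  within k·σ. A box criterion rather than a χ² threshold was chosen because
  pseudorotamer results are quoted as hard P intervals; multimodal
  compatible sets are reported as separate intervals and never merged
  (a single coupling is genuinely periodic in P — the tests construct such a
  two-lobe case at P = 54°/234°).

σ values are floored at 10⁻⁶ Hz so zero-noise synthetic sets remain usable;
with k = 0 on noisy data the compatible set is empty and flagged, while the
best node is still reported.

**Parameter provenance.** The package ships
`inst/extdata/karplus_synthetic.tsv`, an explicitly labelled synthetic
stand-in: the quantitative ¹H–¹⁹F relation for 2′-fluoro sugars used in the
primary literature could not be transcribed and verified offline, and
hard-coding unsourced coefficients would be worse than shipping none. The
stand-in uses magnitudes typical of furanose ³J(H,H) (~10 Hz ceiling) and
³J(H,F) (~30–45 Hz ceiling) couplings so simulation/recovery behaves
realistically; every test constructs its own explicit parameter table, and
users doing quantitative work must supply a literature set (same columns,
provenance in the header).

## 6. Ensemble metrics

Superposition is closed-form least squares via SVD with the determinant
correction (reflections excluded); collinear point sets are a degeneracy
error. `ensemble_rmsd` implements both conventions — all-pairs mean and
iterative superposition to the running mean (convergence ΔRMSD < 10⁻⁶ Å) —
because published ensemble RMSDs often leave the convention unstated; the
convention in use is echoed in the result, and the property
to-mean ≤ pairwise is tested on synthetic perturbations. The "core"
selection is the heavy atoms of the twelve tetrad guanines detected on
model 1. Missing named protons are rebuilt from heavy-atom geometry
(standard bond lengths, tetrahedral/planar slots) only for explicit proton
queries, and flagged per value.

## 7. The synthetic generator: what it emulates, what it does not

`build_quadruplex` realizes a declarative topology specification: an
idealized Hoogsteen tetrad template (N1–O6 = N2–N7 ≈ 2.9 Å, coplanar bases,
donor H pointing at the acceptor — comfortably inside the detector cutoffs),
stacked with a 3.3 Å rise and 30° twist; per-layer cycle senses are realized
by face-flipping whole layers about an in-plane axis chosen to keep the four
base positions vertically aligned. Sugars are attached at the exact
requested χ by rigid rotation about the glycosidic bond, with ring geometry
from `build_sugar_ring` (Cartesian refinement against standard bond lengths
and the target torsions; achieved P within 2°, bonds within 0.02 Å).

A chemically meaningful coupling **emerges** rather than being wired in:
given a layer's cycle sense, *anti* residues run one way along the stack and
*syn* residues the other — exactly the relation that links glycosidic
patterns to strand directionality in real quadruplexes. The generator's
realizability check rejects specifications that violate it (wiring errors).

Deliberate non-goals of the generator:

* **Loop stereochemistry is schematic** — loop nucleotides are placed on an
  outward Bézier arc; detectors read base/phosphate geometry and sequence
  connectivity, not loop internal coordinates.
* **No ions, no energetics** — the K⁺ channel is omitted; nothing is
  minimized.
* **Ensemble noise is i.i.d. Cartesian** (`perturb_ensemble`), which is much
  harsher on sugar puckers than a refined NMR ensemble would be: at τ_m = 36°
  the out-of-plane amplitudes are only ~0.4 Å, so σ = 0.1–0.15 Å of
  uncorrelated noise scatters P by tens of degrees, and σ ≈ 0.3 Å starts to
  break Hoogsteen edge detection. Green tests on noisy ensembles therefore
  establish robustness of the *pipeline mechanics*, not the P precision one
  would obtain from real refined coordinates.
* **Syn backbone rotamer.** The short 5′ arm (γ, β) of syn core residues
  uses a rotamer (γ = 190°, β = 20°; anti residues: γ = 54°, β = 180°)
  calibrated once, together with χ_syn = +75°, so that the canonical
  templates reproduce the documented groove classes under the 14/18 Å
  thresholds. This is a stated-world choice, made once and frozen; it is not
  adjusted per test.

The central property — every generator output, passed through the full
analysis chain, reproduces its generating specification (tetrad cycles,
interfaces, orientations, broken columns, inversion points, groove labels,
loop classes, V-loop records) — is the package's primary acceptance surface
and is asserted in `test-acceptance.R` over all four presets
(`parallel`, `hybrid-ODN`, `vloop-ODN1415`, `vloop-typeB`).

## 8. Nomenclature

Primed atom names are canonical internally (star forms normalized on read,
O1′ → O4′); modified guanosines are recognized by an editable alias table
shipped as data (`inst/extdata/residue_aliases.tsv`), defaulting to common
codes for 2′-F-ribo, 2′-F-arabino, ribo and LNA guanosine. Component naming
for 2′-modified analogues varies between depositions and the shipped table
has not been validated against the live chemical component dictionary —
unknown names pass through as (other, unknown) with a warning rather than
failing the run.

## 9. Known limitations

* Multi-chain (bimolecular) folds are only handled through the chain filter;
  column extraction across chains is untested territory.
* Groove thresholds and pseudo-hydrogen-bond cutoffs (2.7 Å / 110°,
  heavy-atom fallback 3.5 Å) are package decisions surfaced in output
  metadata, not community standards.
* The single-conformer grid inversion deliberately does not fit two-state
  north/south population mixtures; it answers "which single pseudorotamer is
  compatible", nothing more.
* mmCIF support covers the standard `_atom_site` loop of wwPDB files, not
  arbitrary CIF dialects.
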