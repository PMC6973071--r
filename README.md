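# quadfold

Topology and sugar-pucker analysis of G-quadruplex (G4) structure ensembles.

## The problem

G-quadruplexes are four-stranded nucleic-acid folds built from stacked
guanine tetrads — cyclic arrangements of four guanines hydrogen-bonded along
their Hoogsteen edges (N1–H→O6, N2–H→N7), which makes each tetrad a
*directed* 4-cycle. A fold is characterized by how its four G-columns run
(parallel/antiparallel), how the tetrads stack (homopolar vs heteropolar
interfaces), how wide the four grooves are (narrow/medium/wide), and how the
connecting loops wire the columns together (lateral, diagonal, propeller,
and the rarer V-shaped loop, which may contain **zero** intervening
nucleotides and links two adjacent antiparallel columns through residues on
opposite outer faces of the core).

Two per-residue conformational coordinates drive all of this:

* the **glycosidic torsion** χ (O4′–C1′–N9–C4 in purines), classified
  *syn* (χ ∈ [0°, 90°]), *anti*, or *high-anti*;
* the **sugar pucker**, summarized by the pseudorotation phase angle P and
  amplitude τ_m of the furanose ring. With ν₀…ν₄ the endocyclic torsions,

      tan P = ((ν₄ + ν₁) − (ν₃ + ν₀)) / (2 ν₂ (sin 36° + sin 72°)),
      τ_m  = ν₂ / cos P,

  and the forward (cosine) model is ν_j = τ_m·cos(P + 144°·(j − 2)).
  P ≈ 18° is C3′-endo ("north"), P ≈ 162° is C2′-endo ("south").

Sugar pucker can also be inferred without coordinates, from vicinal scalar
couplings via Karplus relations J(θ) = A·cos²θ + B·cosθ + C with θ a linear
function of the governing ring torsion; `quadfold` inverts coupling sets on a
(P, τ_m) grid and reports the compatible pseudorotamer region(s).

`quadfold` is for structural-NMR and modelling people who want reproducible,
scriptable annotation of deposited or simulated G4 ensembles — including
2′-modified guanosine analogues (2′-F-ribo, ribo, 2′-F-arabino, LNA) — plus a
synthetic-structure generator so every detector is testable offline.

## Worked example

```r
library(quadfold)

# a three-layer fold with two lateral loops, a 0-nt V-loop and a propeller
ens  <- build_quadruplex(g4_preset("vloop-ODN1415"))
topo <- analyze_topology(ens)
print(topo)
#> G4 topology (model 1): 3 tetrad(s)
#>   cycle:  2>6>20>15
#>   cycle:  1>16>21>7
#>   cycle:  8>14>17>22
#>   interfaces: heteropolar, homopolar
#>   grooves: medium, medium, wide, narrow
#>   loops: lateral(2-6), lateral(8-14), V(14-15), propeller(17-20)
#>   V-loops: 1
```

The three directed cycles are the per-layer Hoogsteen donor→acceptor rings;
mismatched cycle senses between stacked layers give the heteropolar
interface. The V-loop record carries the anchor conformations:

```r
v <- topo$vloops[[1]]
#> anchor5 = 14 (syn,  P = 55.4 deg, north-east)
#> anchor3 = 15 (anti, P = 55.4 deg, north-east)
#> turn_locus = "within_following_tract"
```

i.e. the 5′ anchor is forced *syn* while both anchors keep a north-east
(C4′-exo) pucker, and the backbone turn sits between the 3′ anchor and its
tract neighbour (the strand inversion is flagged between residues 15 and 16
in the column report).

Ensemble statistics on a noisy 10-model replica:

```r
nm <- perturb_ensemble(ens, n_models = 10, noise_sd = 0.15, seed = 1)
ensemble_rmsd(nm, "core", "pairwise")$rmsd_mean
#> [1] 0.37        # A, heavy atoms of the 12 tetrad guanines, 240 atoms
```

Coupling inversion (here with the shipped synthetic Karplus stand-in set;
substitute a literature parameter file for quantitative work):

```r
obs <- simulate_couplings(P = 55, tau_m = 35, noise_sd = 0.3, seed = 1)
fit_pseudorotation(obs, k = 2)
#> pseudorotation fit: best (P, tau_m) = (52, 33), chisq = 2.55
#> compatible P: [46, 58]
```

The generating phase (55°) is recovered within the grid step plus noise; the
compatible interval is the set of P values whose predicted couplings all sit
within k·σ of the observations.

## Command line

```sh
Rscript inst/cli/quadfold.R synth   --preset vloop-ODN1415 --out g4.pdb \
                                    --models 10 --noise 0.1 --seed 1
Rscript inst/cli/quadfold.R analyze --input g4.pdb --outdir report/
Rscript inst/cli/quadfold.R survey  --input g4.pdb other.pdb --outdir report/
Rscript inst/cli/quadfold.R couplings --input couplings.tsv --outdir report/
```

Exit codes: 0 success, 1 usage/I-O error, 2 input parsed but no tetrads
found. Reports are JSON/TSV with angles in degrees, distances in Å,
couplings in Hz; the effective configuration is echoed into every report.

## Scope notes

Quantitative reproduction of published deposition-specific numbers (ensemble
RMSDs, per-entry distances, the published ¹H–¹⁹F Karplus coefficients)
requires the deposited coordinates and supplementary tables, which are not
bundled; see `vignettes/quadfold-methods.Rmd` for what the synthetic
generator does and does not emulate.
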