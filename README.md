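# allostate

Conformational-landscape and kinetic signatures of allostery in the
LDH/MalDH superfamily.

## What this package is for

Lactate dehydrogenases (LDHs) and malate dehydrogenases (MalDHs) share a
fold, but most bacterial LDHs are allosteric — sigmoid substrate
saturation, a tense/relaxed (T/R) conformational equilibrium — while
MalDHs are not. A few catalytic-site positions in the family's normalized
(Eventoff-style) numbering (68, 102, 199, 246, 250) carry the sequence
signature separating the phenotypes, and one or two substitutions there
can make a nonallosteric dimeric MalDH transiently sample T-like,
catalytically incompetent conformers: an "allosterized" enzyme.

`allostate` implements the computational pipeline for studying that
transition, for structural bioinformaticians and enzymologists:

* **Numbering/signatures** — map any family sequence onto the normalized
  numbering by global alignment (BLOSUM62, affine gaps), classify the
  signature residues (102 Q/R, 246 T vs A/S, 250 I/P, 68 H vs D/Q, 199
  acidic or not), and export iTOL-style tree annotations.
* **Ensemble geometry** — multi-model PDB in/out; Kabsch superposition
  `min Σ‖R xᵢ + t − yᵢ‖²` with det(R) = +1; inter-atom distance series
  (cross-chain pairs supported); the α2F helix orientation angle θ:
  reference helix Cα167→Cα181 aligned with +X, each monomer fitted on all
  common Cα, θ = signed angle of the frame helix's X–Z-plane projection
  from +X.
* **Landscape** — distance distributions (Gaussian KDE, bw 0.3 Å) with
  prominence-filtered peaks; (θ, d(R171-Cγ–P141-Cα)) landscapes with
  R-like / T-like / intermediate calls (T iff d ≥ 18 Å and |θ| ≥ 8°;
  R iff d ≤ 16 Å and |θ| ≤ 4°); position-250 (χ1, χ2) rotamer substates
  clustered on the torus with silhouette-selected k, labelled Cs1…Csk by
  occupancy; mobile-loop open/closed state from L167–102/109 distances.
* **Kinetics** — Michaelis–Menten `v = V·S/(Km+S)`, allosteric sigmoidal
  `v = V·S^h/(S₀.₅^h+S^h)`, substrate inhibition `v = V·S/(Km+S(1+S/Ki))`;
  multi-start nonlinear least squares, AICc model selection with a
  Δ < 2 parsimony rule, efficiency kcat/Km in M⁻¹s⁻¹.
* **Synthetic generators** — dimeric conformer ensembles with planted
  state fractions, distances, helix angles, loop states and rotamer
  modes; saturation curves with multiplicative noise; sequence families
  with planted signatures. Seeded, byte-reproducible, truth in sidecar
  JSON.

## Worked example

Simulate a sigmoid (homotropically activated) saturation experiment with
the half-saturation constant S₀.₅ = 100 mM, kcat = 21 s⁻¹ and Hill
coefficient 2, then let the fitter choose the rate law:

```r
library(allostate)
sim <- make_saturation(kinetics_spec(model = "allosteric_sigmoidal",
                                     params = c(Vmax = 21, S05 = 100, h = 2),
                                     span = c(0.2, 5), seed = 42))
fit_kinetics(sim$dataset, "auto", seed = 42)
#> <kinetic_fit> allosteric_sigmoidal (n = 36)
#>   Vmax  21.03 +/- 0.46
#>   S05   101.3 +/- 3.7
#>   h     1.977 +/- 0.1
#>   kcat 21 s^-1; kcat/Km 210 M^-1 s^-1; AICc -15.6
```

The sigmoid law is selected over the hyperbola and the
substrate-inhibition law, the three generating parameters come back
within their standard errors, and the catalytic efficiency
kcat/S₀.₅ = 21/0.1 M = 210 M⁻¹s⁻¹ — the hallmark numbers of a weakly
efficient, homotropically activated enzyme.

Now a structural ensemble: 500 conformers of a dimer whose chain A spends
30% of its time in a planted T-like state (R171 out at ~21 Å, helix
rotated "under" by ~12°):

```r
out <- make_ensemble(ensemble_spec(n_frames = 500, seed = 42))
lp <- landscape(out$ensemble, "A", out$reference)
round(table(lp$label) / nrow(lp), 3)
#> intermediate       R_like       T_like
#>        0.008        0.696        0.296

make_distribution(distance_series(out$ensemble, atom_ref("A", 171, "CG"),
                                  atom_ref("A", 141, "CA")))
#> <distance_distribution> grid [11.9, 23.4] A, bw 0.3, 2 peak(s) at 14.5/20.9 A

sidechain_substates(out$ensemble, "A", 250, seed = 1)
#> <substate_assignment> k = 3; occupancies: Cs1 0.50, Cs2 0.30, Cs3 0.20
```

The landscape recovers the planted 0.30 T-like fraction, the
R171–P141 distance distribution shows the in/out double peak, and the
isoleucine-250 side chain's three planted rotamer substates come back
with their occupancies.

## Command line

```sh
Rscript -e 'allostate::allostate_main()' simulate kinetics --seed 7 --out sim/
Rscript -e 'allostate::allostate_main()' kinetics-fit --csv sim/saturation.csv \
    --model auto --seed 7 --out fit/
```

Subcommands: `number`, `signatures`, `distances`, `helix-angle`,
`landscape`, `substates`, `loopstate`, `kinetics-fit`, `simulate`. Every
run writes a JSON manifest (config snapshot, input checksums, version,
timestamp) next to its outputs.

## Scope notes

The package analyzes ensembles; it does not run molecular dynamics, build
homology models, or infer phylogenies. Microsecond-trajectory results are
represented at desk scale by the synthetic generators' planted-truth
recovery, not re-simulated. See `vignettes/allostery-landscapes.Rmd` for
the methods account, parameter defaults and limitations.
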