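---
title: "Methods: conformational landscapes and kinetics of an allosterized MalDH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational landscapes and kinetics of an allosterized MalDH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostate)
```

## The scientific question

Lactate dehydrogenases (LDHs) and malate dehydrogenases (MalDHs) share a
scaffold but differ sharply in regulation: most bacterial LDHs are
allosteric (sigmoid substrate saturation, T/R conformational equilibrium in
the MWC sense), while MalDHs of type 3 and the "intermediate" group are
not. A handful of catalytic-site positions — in the family's normalized
(Eventoff-style) numbering, 68, 102, 199, 246 and 250 — carry the sequence
signature separating the two phenotypes, and a small number of
substitutions at these positions can push a nonallosteric dimeric MalDH
into transiently sampling T-like (catalytically incompetent) conformers.

`allostate` packages the computational side of that analysis as a reusable
pipeline: normalized numbering and signature classification across the
superfamily, geometry of structural conformer ensembles, landscape
summaries (distance distributions, angle–distance state calls, side-chain
substates, mobile-loop state), rate-law fitting for saturation kinetics,
and synthetic generators that stand in for microsecond MD trajectories and
raw assay data with known ground truth.

## Normalized numbering and signatures

Queries are mapped by global pairwise alignment (BLOSUM62, gap open 10,
extend 0.5 — standard within-superfamily settings, configurable) onto a
packaged reference profile. Every aligned column yields one
`(query_index, normalized_number)` pair; insertions relative to the
reference are reported as unmapped rather than given suffix codes, since
no downstream operation needs them. Alignment identity below a 15% floor
flags the map rather than failing: a doubtful family membership should be
visible, not fatal.

**The packaged reference is a synthetic stand-in.** The published
correspondence table between a real LDH and the normalized numbering lives
in supplementary material we do not redistribute; instead the reference is
a constructed LDH-like sequence whose normalized number equals its index,
with the family's conserved residues planted at their canonical positions
(H68, Q102, R109, P141, L167, D168, R171, N181, H195, D199, T246, I250).
Mappings of real sequences through it are alignment-based approximations;
any disagreement with a published table should be flagged, not silently
overridden.

Signature classification is a pure positional rule set (102: Q vs R;
246: T vs A/S; 250: I vs P; 68: H vs D/Q; 199: only the acidic D/E marks
the LDH class — the typical MalDH methionine is reported as `other` with
the raw residue kept, so "acidic vs not" remains reproducible). The
default position set includes 199, matching the five-circle figure
convention rather than the four-position methods listing. Tree annotations
are iTOL-style DATASET_BINARY text, one file per position; leaf matching
is exact after whitespace trimming — a reported orphan beats a silent
fuzzy mislabel.

## Ensemble geometry

Multi-model PDB is the interchange format: a crystal structure is a
1-frame ensemble, an exported MD trajectory an n-frame one. The reader
keeps ATOM records, resolves alternate locations to the highest-occupancy
conformer, and rejects insertion-coded residues. "Cγ" is addressed as PDB
atom name `CG`, with `CG1` accepted for isoleucine, matching the field's
loose usage; a residue genuinely lacking the atom (glycine) raises an
explicit missing-atom error rather than substituting Cβ.

Superposition is the closed-form least-squares rigid fit (Kabsch with the
determinant correction, so chirally flipped inputs still return a proper
rotation). The helix orientation angle θ follows the trajectory-analysis
recipe: align the reference so its Cα167→Cα181 helix vector lies along
+X; superpose each frame's monomer on the reference using all common Cα
atoms; θ is the signed angle between the X–Z-plane projection of the
frame's helix vector and +X.

Numerical choices worth knowing:

* **Sign convention.** Positive θ means positive Z-component of the
  projected vector (the "under" direction of the T-like helix motion in
  our frames). The underlying study never defines a sign; `z_sign = -1`
  flips it.
* **`fit = FALSE`.** The projection-angle computation can be tested and
  used without the per-monomer fit; exactness tests (planted 15° in-plane
  rotations recovered to 1e-6) use this mode, because with the fit on, a
  rotation applied to part of a monomer is partially absorbed by the fit
  itself. With the fit on, θ is invariant to any global rigid motion of
  the frame — that is the property the fit exists to provide.
* Distances are stored at full precision and displayed to 0.1 Å, matching
  the field's reporting precision.

## Landscape summaries

Distance distributions are Gaussian KDEs (bandwidth 0.3 Å, grid 0.05 Å by
default; the trajectory study never states its binning, so these are
declared package defaults tuned so that an 11/13 Å doublet resolves).
Densities are renormalized on the grid so they integrate to 1 within
1e-6. Peaks are local maxima filtered by topographic prominence (≥ 5% of
the maximum density) and mutual separation (≥ 1 Å, higher peak wins).

The 2D landscape pairs θ with the same-chain R171(Cγ)–P141(Cα) distance.
State calls are deliberately banded: T-like iff d ≥ 18 Å **and** |θ| ≥ 8°;
R-like iff d ≤ 16 Å **and** |θ| ≤ 4°; everything else intermediate. The
source study classified conformers visually; these thresholds are
heuristics anchored to the printed out-state peaks (17 and 20 Å) versus
in-state geometry, and they are embedded in every output's metadata so a
reclassification is always attributable. A reclassification of real
trajectories with these defaults is a comparison, not a ground truth.

Side-chain substates of position 250 are clustered on (χ1, χ2) dihedrals
— a declared choice; Cartesian clustering would also have been defensible
— embedded on the torus as (cos, sin) pairs so modes straddling ±180°
merge. k is chosen by average silhouette width over the requested range,
with k = 1 selected when no split reaches a mean silhouette of 0.5 (tight
unimodal clouds force-split by k-means rarely exceed ~0.4). Clusters are
labelled Cs1…Csk by descending occupancy. Proline at 250 has no χ2 and is
refused explicitly.

Mobile-loop state uses L167(Cα) to 102(Cγ)/109(Cγ) distances with bands
anchored to the printed exemplars: closed iff d102 ≤ 15 and d109 ≤ 12 Å
(closed crystal exemplar 13.1/9.6 Å), open iff d102 ≥ 20 and d109 ≥ 15 Å
(Apo exemplar > 20 Å); the midband is reported as intermediate rather
than forced binary.

## Kinetics

Three rate laws: Michaelis–Menten `v = Vmax·S/(Km+S)`, allosteric
sigmoidal `v = Vmax·S^h/(S0.5^h + S^h)`, substrate inhibition
`v = Vmax·S/(Km + S(1+S/Ki))` (interior maximum at √(Km·Ki)). Fitting is
unweighted nonlinear least squares by default (mirroring the common
Prism-style analysis; 1/v² weighting optional) with multi-start
initialization (Vmax at 1.1×max v, half-saturation at the S nearest half
of that, h ∈ {1.5, 2.5}, Ki at 10×Km estimate, seeded jitter to 8 starts),
Nelder–Mead on log-parameters polished by Gauss–Newton (`nls` port).

`model = "auto"` fits all three laws and selects by AICc **with a
parsimony rule**: among models within 2 AICc units of the best, the one
with fewest parameters wins. The sigmoid law nests the hyperbola at
h = 1, so raw AICc alone promotes a spurious Hill coefficient on roughly
one in ten hyperbolic datasets at realistic noise; Δ < 2 is the
conventional "substantial support" band, not a tuned constant.
Efficiency is kcat/(Km·10⁻³) in M⁻¹s⁻¹, with S0.5 standing in for Km on
sigmoid fits exactly as kinetics tables in this field do; printed values
use 2 significant figures, JSON keeps full precision. "Not detectable"
datasets are represented as absent records, never fitted to zeros.

## The synthetic world — what a green test establishes

The generators plant every quantity the pipeline measures:

* a dimer of pseudo-residues on an idealized backbone (CA everywhere;
  side-chain atoms only where analyses touch them), with the α2F helix
  built exactly along +X in the reference state;
* R171's Cγ placed on the P141→N181 axis at the scheduled distance, which
  produces the in/out mirror anti-correlation by construction
  (|CA141–CA181| ≈ 30.5 Å, so out-distances of 17/20 Å mirror to ~13/11 Å);
* helix rotations, loop distances and (χ1, χ2) rotamers drawn from the
  scheduled state mixture (default 70% R-like / 30% T-like; in-state
  distance 14.5 ± 0.5 Å, out-state 21 ± 0.5 Å or the 17/20 Å doublet;
  T-state angle 12 ± 1.5°; closed loop at the 13.1/9.6 Å exemplar; three
  χ modes at 0.5/0.3/0.2 occupancy), exact state counts by largest
  remainder, plus isotropic 0.1 Å coordinate noise;
* saturation curves `v = rate(S)·exp(ε)`, ε ~ N(0, CV²), CV 5%, 12
  log-spaced concentrations spanning 0.2–10× (hyperbolic) or 0.2–5×
  (sigmoid) the half-saturation truth, 3 replicates, parameters from the
  published kinetics table rows.

What this does **not** emulate: force-field physics, solvent, correlated
backbone motion, inter-monomer communication dynamics, or the time
ordering of a trajectory. A green recovery test therefore establishes
that the estimators are correct on data realizing the stated geometry and
noise model — it does not re-derive the microsecond-MD results, which the
build treats as out of desk-scale scope by design. Same seed means
byte-identical output files; truth is written to sidecar JSON and tests
read planted values only from there.

## Known limitations

* The packaged reference numbering is synthetic (above); mappings of real
  sequences are approximations to the published correspondence table.
* Crystal-structure checks against real PDB entries require downloads and
  are covered here by synthetic stand-ins planted at the printed exemplar
  distances.
* The R/T thresholds and loop bands are declared heuristics; there is no
  quantitative boundary in the source material.
* mmCIF, compressed trajectory formats and PBC unwrapping are out of
  scope; inputs are assumed whole molecules in multi-model PDB.
* CLI configuration is flag-based with a JSON run manifest; there is no
  TOML config layer (no TOML parser in the supported dependency set).
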