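---
title: "Predicting HDX-MS uptake from structures and ensembles with hdxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HDX-MS uptake from structures and ensembles with hdxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxkin)
```

# The model

Hydrogen–deuterium exchange detected by mass spectrometry (HDX-MS) reports,
for each proteolytic peptide, the fraction of backbone amide hydrogens that
have exchanged for deuterium after a given incubation time. `hdxkin`
predicts those fragment uptake curves from atomic structures.

## Two-state exchange and the EX1/EX2 limits

Exchange of a structured amide requires a local opening event:

$$\mathrm{NH_{cl}} \underset{k_{cl}}{\overset{k_{op}}{\rightleftharpoons}}
  \mathrm{NH_{op}} \xrightarrow{k_{int}} \mathrm{ND_{op}}$$

with observed rate
$k_{obs} = k_{int}k_{op}/(k_{int}+k_{op}+k_{cl})$ (`k_obs()`). Under native
conditions ($k_{cl}\gg k_{op}$) two limits exist: EX1
($k_{int}\gg k_{cl}$, $k_{obs}\to k_{op}$) and EX2
($k_{cl}\gg k_{int}$, $k_{obs}\to k_{int}/P$ with protection factor
$P = k_{cl}/k_{op}$). `classify_regime()` uses a configurable fold-ratio
threshold (default 10); the threshold is a convention, not a physical
constant, since only the asymptotic limits are defined.

## Phenomenological protection factors

In the EX2 regime the protection factor of residue $i$ in conformation $X$
is approximated from its local environment:

$$\ln P_i(X) = \beta_c\,N_i^c(X) + \beta_h\,N_i^h(X)$$

where $N_i^c$ counts heavy (non-hydrogen) atoms strictly within 6.5 Å of
the amide nitrogen and $N_i^h$ counts acceptor oxygens strictly within
2.4 Å of the amide hydrogen. The weights default to $\beta_c = 0.35$ and
$\beta_h = 2$, the values established on residue-resolved reference data
for this class of predictor. Both counts run across *all* chains, so
subunit interfaces protect buried amides.

Choices the counting rule does not fix by itself, each exposed in
`protection_params()`:

* **Neighbour exclusion.** Atoms of residues $i-1, i, i+1$ on the same
  chain are excluded from $N^c$ by default; bonded atoms would otherwise
  add a constant offset. Setting `contact_exclusion = 0` excludes residue
  $i$ only.
* **Acceptor set.** Protein oxygens only (backbone and side chain, any
  chain, including the residue's own carbonyl where geometry permits).
  Water oxygens are excluded by default — counting transient water
  H-bonds would spuriously "protect" exposed amides; `all_oxygen`
  restores them when frames retain solvent. Nitrogen/sulfur acceptors are
  never counted.
* **Strict inequalities** at both cutoffs, and hard cutoffs (no switching
  functions).

Crystal structures carry no hydrogens, so `build_amide_hydrogens()` places
any missing amide H at 1.01 Å from N, in the plane of the preceding
peptide group, anti (trans) to the preceding carbonyl oxygen, with a
C–N–H angle of 119°. Existing hydrogens (MD frames) are never moved, and
heavy atoms are never touched, making the operation idempotent. Prolines
and chain-initial residues never receive an amide H, and residues with
missing backbone context are flagged and excluded from exchange sums.

## Intrinsic rates

The fully exposed ("intrinsic") rate of an amide depends on temperature,
pH, and the side chains flanking the peptide bond. `k_int()` evaluates the
standard reference model: acid-, base- and water-catalysed terms for
poly-DL-alanine, modified by per-side-chain log-factors for the residue's
own side chain and its left neighbour, terminal-group corrections, and
Arrhenius scaling from 293 K (activation energies 14/17/19 kcal/mol). The
parameter tables are vendored as commented CSV files under
`inst/extdata/` (provenance in the file headers) and are swappable via
`kint_table()`.

Details worth knowing:

* Rates are in 1/min (the unit of the source tables); `units = "per_s"`
  converts, and the uptake layer works in seconds throughout.
* Ionizable side chains (Asp, Glu, His) blend their protonated and
  deprotonated factors by the Henderson–Hasselbalch fraction at the given
  pD (side-chain pKa values in the constants file).
* The glass-electrode correction pD = pH + 0.4 is **off** by default: the
  conditions are used exactly as stated (`pD_correction = TRUE` enables
  it). The default experimental conditions are pH 7.9 and 298 K.
* $\log_{10} k_{int}$ is piecewise linear in pH with slopes $-1$ (acid
  limb) and $+1$ (base limb); near the rate minimum (pH ~2.5–3) the water
  term contributes a few percent, which the tests account for.
* The D2O autoionization constant is held at pKD = 15.05; all temperature
  dependence is carried by the Arrhenius factors.

## Uptake curves and ensemble averaging

With $P_i = e^{\ln P_i}$, residue uptake is
$D_i(t) = 1 - e^{-(k_{int}^i/P_i)\,t}$ and a fragment's curve is the
*unweighted mean over its exchange-competent amides* (no proline, not
chain-initial; an option to drop fragment-N-terminal fast exchangers
exists but defaults to 0).

Conformational heterogeneity enters through two averaging modes:

* `mean_lnP` (default): average $\ln P_i$ over frames (and chains), then
  compute $D$. This is the protection-factor-as-ensemble-average reading.
* `mean_D`: compute the fragment $D(t)$ per (frame, chain) from the
  instantaneous $\ln P$, then average with the ensemble weights — the
  per-frame time-series view provided by `perframe_uptake_series()`.

The two agree exactly on single-frame, single-chain input. On
heterogeneous ensembles they differ: $D$ is convex decreasing in
$\ln P$ while $u = k_{int}t/P < 1$, so on that branch `mean_D` ≥
`mean_lnP` curves (Jensen); at long times ($u > 1$) the curvature — and
hence the inequality — reverses. Both modes are first-class because
published analyses have used both readings; for rigid "crystal-only"
predictions they coincide. Homo-oligomer fragments are averaged over
chains by default; per-chain values remain available in the profile
object.

# Fragment assignment by monoisotopic mass

Misassigned peptides are a real failure mode of HDX-MS on large
assemblies. `monoisotopic_mass()` computes neutral, unmodified peptide
masses (residue monoisotopic masses + water; no adducts — identities are
compared, not m/z), and `reassign()` scans *all* contiguous subsequences
within length bounds, ranking candidates inside a ppm tolerance by
absolute error (ties by length, then start). `validate_fragment_table()`
applies this to a whole fragment table and reports the top alternatives
for mismatches. Note that exactly isobaric alternatives (sequence
permutations, Ile/Leu) are indistinguishable by mass in principle and tie
at rank 1. The default 50 ppm tolerance is deliberately generous and
configurable.

# Structural descriptors

* `sasa()`: Shrake–Rupley numerical SASA, probe 1.4 Å, 960 deterministic
  golden-spiral points per atom, Bondi van der Waals radii (vendored CSV).
  Hydrogens are ignored. Quadrature accuracy is ~1% per sphere; the point
  set is not rotation-invariant, so symmetric subunits agree to ~1 Å²
  rather than machine precision.
* `buried_surface()`: SASA(chain alone) − SASA(chain in oligomer), the
  interface footprint; non-negative up to quadrature noise.
* `rmsf()`: per-residue fluctuation about the ensemble-average structure
  after closed-form (Kabsch/SVD) superposition — one pass onto the first
  frame to form the mean, then onto that mean. Default selection is the
  backbone heavy atoms; Cα-only or all-atom selections are one argument
  away.

# The synthetic-data generators

`make_structure()` builds idealized backbones from internal coordinates
(standard bond lengths/angles; helix $\varphi,\psi = -57°,-47°$; extended
$-120°,+120°$). The ideal helix reproduces the textbook $i \to i-4$
H-bond pattern exactly (interior amides have $N^h = 1$); the extended
chain has none; `ring_oligomer` arranges $n$ copies in $C_n$ symmetry and
shrinks the ring radius until neighbouring subunits touch (closest
approach ≈ 4 Å), producing a genuine interface. `make_ensemble()` adds
i.i.d. Gaussian coordinate jitter (seeded, byte-reproducible), optionally
mixing in "open" frames with all chains displaced radially — a minimal
two-state closed/open model of ring opening. `make_uptake_table()` turns
planted per-residue $\ln P$/$k_{int}$ into a synthetic experimental table
with truncated Gaussian noise and keeps the ground truth alongside.

What these fixtures emulate is the *pipeline mathematics* — counting
rules, averaging, kinetics — under controlled truth. They are not
physical: jitter is isotropic and uncorrelated (no force field, no
solvent, no correlated breathing motions), backbones carry no side chains
beyond what you plant, and the open/closed mixture is binary. Passing
tests therefore validate the computation, not the phenomenological
model's accuracy on real proteins; the latter depends on the realism of
the input ensemble.

# Comparison with experiment

`pair_predictions()` joins predicted and experimental tables on fragment
id and time (1% relative time tolerance), reporting unmatched rows;
`fragment_rmsd()` gives per-fragment and global RMSDs in D units.
`apparent_rate()` fits $D(t) = A(1-e^{-k_{app}t})$ with $A\in(0,1]$ by
Levenberg–Marquardt, initialized deterministically from the half-rise
time; a root-mean-square residual above 0.03 D units flags a poor fit
(e.g. biphasic kinetics from two sub-populations), and degenerate curves
return a non-convergence flag instead of numbers. The single-exponential
form is the simplest defensible reading of "apparent rate"; where a
legacy study used a different summary, refit accordingly. Redundant or
unreliable fragments can be excluded by id at table-reading time.

# Worked example

```{r example}
hex <- make_structure("ring_oligomer", 20, n_chains = 6, first_resno = 210)
ens <- make_ensemble(hex, n_frames = 10, jitter_sigma = 0.35, seed = 1)
frg <- data.frame(id = "iface", start = 215, end = 224)

crystal <- predict_hdx(hex, frg, times = 480)
dynamic <- predict_hdx(ens, frg, times = 480, mode = "mean_D")
c(crystal = crystal$uptake$D_pred, ensemble = dynamic$uptake$D_pred)
```

The rigid crystal systematically under-predicts exchange relative to the
fluctuating ensemble — fluctuations transiently break contacts and
H-bonds, and the exponential averaging rewards the open excursions.

# Numerical choices and limitations

* Problem sizes: the test-suite and acceptance script use hexamers of
  6 × 20 residues, ensembles of ≤ 10 frames, 100 randomized count
  fixtures (≤ ~600 atoms) and 100 assignment/rate replicates — small
  enough to run in a couple of minutes while exercising every code path;
  real proteins simply take proportionally longer (counting is the
  dominant cost, linear in amides × atoms per frame).
* Minimum-image wrapping is applied to distance evaluations when a
  CRYST1 box is present (orthorhombic only); otherwise distances are
  plain Euclidean.
* Altloc conformers: highest occupancy wins, ties go to the first
  encountered. HETATM amino acids are excluded with a warning.
* Degenerate amide-H geometry (collinear carbonyl) falls back to a
  CA-based in-plane direction; numbering gaps break the preceding-residue
  context and leave the amide unbuilt (warned, excluded).
* Out of scope by design: running MD itself, loop modelling, EX1
  bimodal-envelope deconvolution, back-exchange correction of raw MS
  data, mmCIF input, D-to-H back-exchange tables.
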