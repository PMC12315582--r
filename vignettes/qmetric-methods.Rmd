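---
title: "Q-score statistics: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-score statistics: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmetric)
```

This vignette is the package's account of its methods: what is computed,
which parameters matter, and why the open design choices were settled the
way they were. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The per-atom Q-score

The Q-score asks, for each atom of a coordinate model, whether the map
around that atom looks like a resolved atom. Map values are sampled at
the atom center and on concentric spherical shells, and the sampled
values $u$ are correlated (Pearson, about the mean) with a reference
Gaussian profile evaluated at the same radii,

$$v(r) = \exp\left(-\tfrac{1}{2}\,(r/\sigma_{\mathrm{ref}})^2\right),
\qquad Q = \mathrm{corr}(u, v) .$$

Because Pearson correlation is invariant to positive affine rescaling of
either argument, the profile's amplitude and offset are fixed at $(1, 0)$
with no loss of generality (the suite asserts this invariance to
$10^{-9}$ on rendered maps), and Q is insensitive to the map's overall
scale and offset — a property that makes scores comparable across
differently normalized reconstructions.

### Sampling protocol

| parameter | default | meaning |
|---|---|---|
| `sigma_ref` | 0.6 Å | reference Gaussian width; Q = 1 for an atom rendered at this width |
| `r_max` | 2.0 Å | outermost shell |
| `r_step` | 0.1 Å | shell spacing (21 radii including r = 0) |
| `pts_per_shell` | 8 | quasi-uniform points per shell |
| `max_attempts` | 8 | shell rotations tried under neighbor rejection |
| `seed` | 1 | seeds the per-shell rotations |

Points are placed by a golden-spiral spherical design, rotated per shell
by a deterministic rotation derived by hashing (seed, atom serial, shell,
attempt) — no global RNG state is touched, so scoring is bit-reproducible
regardless of evaluation order. A candidate point strictly closer to a
neighboring atom than to the target atom is rejected (the *ownership
rule*); this stops a well-resolved neighbor's density from inflating the
score of a misplaced atom. Rejected points are not replaced: among
`max_attempts` rotations the one keeping the most points wins, so crowded
atoms are scored from fewer points rather than from contaminated ones.

Map values are obtained by trilinear interpolation of the eight
surrounding voxels. Atoms whose sample points leave the grid are scored
from the in-grid points only and flagged `low_support` when fewer than
half of the nominal points survive; atoms with fewer than two distinct
radii, or with zero sample variance (featureless density), are unscored:
they carry `NA`, are excluded from the model mean, and are listed in the
result. Hydrogens are parsed but never scored; zero-occupancy atoms are
kept in the model but excluded from scoring; altloc duplicates default to
the highest-occupancy conformer. Waters and ligands count toward the
model mean (everything non-H with occupancy > 0) — filters are exposed
for stricter selections.

## 2. Group aggregation

Per-atom scores average into chemically meaningful groups: amino-acid
backbone {N, CA, C, O, OXT} vs side chain; nucleotide phosphate {P,
OP1–OP3, O5′}, ribose {C1′–C5′, O2′–O4′} and base (the rest); each
non-polymer component (ligand, saccharide unit) as one group. O2′ simply
does not occur in DNA, so the same table serves both nucleic acids; OXT
goes to the backbone. The partition is total for the 20 amino acids and 8
canonical nucleotides (asserted in the suite), and the n-weighted mean of
group means reproduces the model mean exactly — aggregation loses
nothing.

## 3. The archive model: cubic mean curve plus offsets

Across an archive of entries $(d_i, q_i)$ (reported resolution, mean
model Q), `qstat_fit()` fits

$$Q_{\mathrm{mean}}(d) = c_0 + c_1 d + c_2 d^2 + c_3 d^3$$

by least squares (`lm` on a raw polynomial basis; degree 3 by default —
on archive-like data the cubic improves clearly on degrees 1–2 while a
quartic adds almost nothing, an ordering the acceptance suite verifies on
synthetic archives). Fitting is restricted to d in 1–10 Å by default.
Three vertical offsets of the fitted curve are then derived from the
residuals $r_i = q_i - Q_{\mathrm{mean}}(d_i)$:

* **peak** — the modal offset: the center of the window of total width
  0.01 containing the most residuals, searched on a 0.001 grid over the
  residual range, ties resolved toward the smaller offset. The residual
  distribution is left-skewed (poorly fitted models can only lose Q), so
  the mode sits above the mean; this is why Q_peak, not Q_mean, is the
  "commonly observed" reference.
* **low / high 95% bounds** — read *per side*: the 5th percentile of the
  below-peak residuals and the 95th percentile of the above-peak
  residuals (type-7 quantiles, stated because percentile conventions
  differ). An alternative overall-percentile reading (plain 5th/95th
  percentiles of all residuals) is available via `per_side = FALSE`; the
  per-side form is the primary one because it makes the two bounds
  enclose 95% of each tail relative to the peak rather than to the
  whole distribution.

Degenerate inputs are handled explicitly: identical residuals collapse
all three offsets to that value; fewer distinct resolutions than
coefficients raise a singular-fit error rather than returning NA
coefficients. The fitted curve is checked for monotone decrease over the
fitted domain and *warns* (not fails) when violated — the cubic is
unconstrained, and non-monotone fits do occur at degree 4 or on small
samples.

`rolling_percentiles()` provides the regression-free cross-check: at each
grid resolution, empirical percentiles among entries within a 0.5 Å
window (gaps where a window holds fewer than 20 entries). On synthetic
archives the two routes agree to ~0.02–0.03 RMS; the regression route is
preferred for its smoothness, and the comparison tolerance in the suite
is set at 0.04 RMS because the skewed lower tail makes the empirical
5th-percentile curve distinctly noisier than the 95th.

## 4. Relative percentiles

`q_relative_all` is the fraction (as a percent) of archive entries with
*strictly* lower Q; ties do not count, and an entry present in the table
stays in its own denominator (it deflates all entries symmetrically).
`q_relative_resolution` applies the same count within a resolution window
$|d_i - d| \le w/2$ — total width $w$, the reading consistent with
published per-window entry counts; the $\le w$ alternative is selectable.
The default $w = 0.5$ Å balances comparator-set size against the
correlation of the percentile with resolution itself, which grows with
window size in the poorly-populated d ≥ 5 Å stratum
(`window_correlation_scan()` reproduces this trade-off).

One subtlety the report surfaces: because the residual distribution is
skewed, an entry sitting exactly on Q_peak ranks *above* 50% in its
window (the mode exceeds the median). "Close to 50%" remains the right
reading for "commonly observed", but mode-valued entries land nearer
55–75% depending on the local skew.

## 5. Q-derived B factors

Atomic B factors are derived from Q-scores by the linear map
$B = f (1 - Q)$ — Q = 1 gives B = 0, and the conversion is clamped at
zero. The transform is pluggable (`transform` argument) so alternative
forms can be swapped without touching the optimizer. The scaling factor
$f$ is chosen per model by scanning $f = 0, 10, \ldots, 300$: at each $f$
the model is rendered as a sum of isotropic Gaussians with variance
$\sigma_0^2 + B/(8\pi^2)$ (the standard isotropic-displacement
convention; $\sigma_0$ = 0.6 Å, matching the Q-score reference width),
equal integral per atom scaled by occupancy, and compared with the
experimental map by CC-mean over voxels within 3 Å of any model atom.
The masked form is the default because on padded grids the empty
background otherwise dominates the correlation; whole-grid mode is
available. The argmax (ties toward the smaller $f$) is $f_{\mathrm{opt}}$.

Rendering uses no element-specific scattering factors — a deliberate
simplification: the Q-score is affine-invariant and CC-mean nearly so,
and per-element amplitudes would cancel in both to first order.
Contributions are truncated at 4σ; mass conservation of the rendering is
asserted to 1% in the suite.

## 6. The synthetic-data generator

The generator defines the conditions all desk-scale statistics are
computed under.

* **Toy models** (`make_toy_model`): helix/strand chains of alternating
  ALA/LEU, G nucleotides with full phosphate/ribose/base atom sets, and
  NAG saccharide units, at idealized ~1.5 Å bonded spacings with a small
  seeded jitter. The geometry is chemically labeled but not
  stereochemically refined — sufficient for classification, sampling and
  rendering, not for torsion-space realism.
* **Maps** (`simulate_map`): rendered Gaussians plus white Gaussian noise
  scaled to a fraction of the signal RMS. Real maps differ in ways that
  matter and are not emulated: colored noise spectra, CTF artifacts,
  local resolution variation, solvent background. Passing tests on these
  maps validate the estimators' arithmetic and invariances, not their
  behavior on experimental reconstructions.
* **Archives** (`simulate_archive`, n = 10,000 by default): resolutions
  from a scaled Beta(2.5, 4.5) on 1–10 Å (unimodal, mode near 3.7 Å,
  emulating the archive's resolution histogram); Q as a decreasing cubic
  mean curve plus mirrored-Gumbel residuals (scale 0.05, SD ≈ 0.064,
  skewness ≈ −1.14) — mean-zero with a long lower tail, the skew
  direction archive residuals show. The default mean curve is the cubic
  through Q(1) = 0.95, Q(3) = 0.52, Q(5) = 0.30, Q(10) = 0.10: a fast
  1–5 Å decline and a slow 5–10 Å tail. These anchors are a synthetic
  calibration chosen once for realism, not fitted archive coefficients.
  Simulated Q values escaping [−0.1, 1.05] trigger a warning and are
  *not* clipped, so tail behavior stays honest.

All randomness flows through explicit seeds; repeated runs are
bit-identical.

## 7. Numerical choices and degenerate inputs

* MRC origin: the ORIGIN header fields win when nonzero, else
  nstart × voxel size; an explicit `origin` argument overrides both
  (dialects differ across producers). Axis permutations other than
  (1,2,3) are rejected, not silently normalized.
* Voxel centers sit at `origin + index × voxel_size` (0-based indices);
  all interpolation happens in this frame, and the Å↔index maps are
  exact inverses (property-tested).
* Zero-variance correlation inputs are detected with a relative
  tolerance (1e-12 of the mean) because a constant map interpolates to
  values with rounding-level spread.
* Unscored atoms written to annotated models receive the sentinel
  B = 0.00 plus a sidecar listing (`<path>.unscored`) — files stay
  standards-valid while the sentinel remains identifiable.
* Problem sizes in the suite and acceptance script — 10,000-row
  archives, ≤ 48³ rendering grids, ≤ 8-residue toy models — were chosen
  as the smallest sizes at which the statistics stabilize (percentile
  sampling error ≲ 0.5%, grid discretization ≲ 1%).

## 8. Known limitations

* Q-scores saturate and lose resolution sensitivity beyond ~5 Å (the
  mean curve flattens); they remain useful there mainly for flagging
  gross misfit (Q near 0) or under-reported resolution (far above
  Q_high).
* The archive statistics shipped here are computed on synthetic
  archives; fitting a real archive table through `read_archive()` +
  `qstat_fit()` is supported but no real-data coefficients are bundled.
* No stereochemistry checking, no local-resolution correlation, no
  half-map/FSC machinery — out of scope by design.
* B-factor estimates inherit Q-score failure modes: misfitted atoms get
  large B whether the density is absent or merely elsewhere.
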