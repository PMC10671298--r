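---
title: "Quantifying LBD dimer arrangement and relating it to modulator activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LBD dimer arrangement and relating it to modulator activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdgeo)
library(dplyr)
```

## The problem

Allosteric modulators of AMPA receptors bind in a pocket at the interface
between the two subunits of the dimeric ligand-binding domain (LBD). Closely
related compounds can be strong positive modulators (PAMs), negative
modulators (NAMs), or inactive — activity cliffs that the binding pose and
binding free energy alone often fail to explain. One productive hypothesis is
that modulators act by biasing the *mutual arrangement dynamics* of the two
LBD subunits, which couples to receptor gating and desensitization. Testing
that hypothesis requires reducing each trajectory snapshot of the dimer to a
small set of interpretable geometric descriptors of subunit arrangement, and
then correlating their time averages with activity.

`lbdgeo` implements that reduction and the downstream correlation analysis:

1. **Interface planes.** In each subunit, three secondary-structure elements
   flank the modulator site: a small helix (S, residues 606–610), a large
   helix (L, 742–756), and the central β-sheet (C, 617–622 and 727–732;
   GluA2 author numbering). The centroid of each element's Cα atoms is
   computed, and the three centroids define that subunit's *interface plane*.
   The *face center* is the mean of the three centroids — the natural anchor
   point of the plane. Each plane's unit normal is oriented toward the
   partner subunit.
2. **Eight descriptors per frame** (units: degrees and Å):

   | name | meaning |
   |---|---|
   | `angleAB` | angle between the two planes (0 = parallel; folded to [0°, 90°]) |
   | `heightFaceAB` | mean height of each face center over the other plane |
   | `distFace` | distance between the face centers |
   | `shiftFaceAB` | mean lateral (in-plane) shift between each face center and the projection of the other |
   | `heightS_AB`, `heightL_AB` | mean heights of the S (resp. L) centroids over the other plane |
   | `shiftSL_AB` | mean lateral shift between the projection of one subunit's S centroid and the other subunit's L centroid |
   | `shiftLS_AB` | the L-projection-versus-S analogue |

3. **Time averaging** over the stable portion of a trajectory — by default
   the last 20 ns sampled at 200 ps, i.e. exactly 101 frames.
4. **Correlation**: the averaged descriptors are combined with supplied
   MM/GBSA binding energies into a compounds × 9 feature matrix,
   standardized, and decomposed by PCA; an activity-annotated score plot and
   a PC1 separation readout summarise whether potent modulators cluster.

## Conventions and numerical choices

**Signed heights.** Whether "height over the other plane" is signed or
absolute is ambiguous in informal usage; `lbdgeo` uses *signed* heights along
each plane's toward-partner normal, then averages the A-over-B and B-over-A
values. Signs preserve information about elements crossing the partner plane;
the averaging matches the "mean … AB" naming. Shifts, in contrast, are
unsigned in-plane distances. The convention is recorded here and in the
function documentation; absolute-height users can take `abs()` of the
per-frame series.

**Angle folding.** The inter-plane angle uses the absolute value of the
normals' dot product, so the result is in [0°, 90°] and independent of either
normal's orientation. Only "0 = parallel" is inherent to the definition.

**Face center.** Defined as the arithmetic mean of the three element
centroids. Any fixed affine combination would do; the mean is the natural
choice and makes the face center computable before the plane normals, which
resolves the mutual "orient toward the partner" dependency between the two
subunits.

**Degeneracy.** Collinear S/L/C centroids leave the plane undefined; the
builder rejects triangles with area below 10⁻⁶ Å², far below any physical
arrangement but catching exact degeneracies.

**Selections.** Author (PDB-file) residue numbering is used verbatim because
element definitions are quoted in the deposited structure's numbering.
Residues missing inside a range shrink the selection *with a warning*; an
empty selection is an error — silent shrinkage to nothing would invalidate
centroids invisibly. Alternate locations keep the first conformer;
insertion-coded residues are excluded, making selections deterministic.

**Windowing.** With time stamps, the window is `[t_end − 20 ns, t_end]`;
without them, the last 101 frames by index. No equilibration detection is
attempted — the stable portion is the user's statement, not an inference.
Whether the source trajectory stored more frames than the 200 ps stride is
immaterial to the package: averaging is over whatever frames fall in the
window, and a count different from the expected 101 warns.

**RMSD.** Quality-control traces superpose every frame onto the first by
least squares (Kabsch, with a reflection guard), fitting on Cα atoms by
default and reporting heavy-atom RMSD per named group.

**PCA.** Standardization (correlation-matrix PCA) is the default because the
features mix degrees, Å and kcal/mol; it is implemented as `prcomp()` on the
scaled matrix, which is the eigen-decomposition of the correlation matrix.
Each component's sign is fixed so its largest-magnitude loading is positive,
making score plots reproducible across platforms. All components are
computed; plots show the first two.

**Exact masses.** Monoisotopic masses use lightest-isotope constants (C = 12
exactly, H = 1.00782503, …) and adduct ions subtract one electron mass per
positive charge — the standard HRMS-ESI convention, reported to 4 decimal
places. The packaged registry flags published "calculated" values that are
inconsistent with their own formulas (wrong ion formula printed, a
copy-paste duplicate, or an off-by-one-mass-unit entry); those entries are
excluded from identity checks rather than silently "matched" at a loose
tolerance.

## What the synthetic generator emulates — and what it does not

`make_dimer()` builds a Cα-only dimer whose element *centroids* realise a
prescribed plane geometry exactly: the two planes tilted symmetrically by the
requested angle about an in-plane axis, face centers separated by the
requested gap along the mean normal and sheared laterally, with per-residue
pseudo-atoms placed on rings around each centroid (so centroids are exact by
construction) and optional per-frame isotropic Gaussian jitter from a seeded
generator. The returned ground truth comes from closed-form trigonometry and
explicit projection algebra on the analytic centroids — an independent code
path from the measurement pipeline, which goes atoms → selection → centroids
→ planes → descriptors.

Defaults state a plausible world rather than tune one: a 10 Å face gap and
a few degrees to tens of degrees of tilt are the physical scale of an LBD
dimer interface; 0.05 Å per-coordinate jitter mimics the residual backbone
motion of a well-equilibrated trajectory; 101 frames at 200 ps reproduce the
standard stable-window sampling; feature tables default to 20 compounds
(two groups of 10).

The generator does **not** mimic real helix geometry, side chains, solvent,
or correlated collective motion. A green geometry test therefore establishes
that the *measurement* is correct — selections, centroids, plane
construction, signed heights, projections, averaging — not that any
biological claim about AMPA receptor gating is true. Conclusions about real
modulators require real trajectories, which the package consumes but does
not produce.

## A limitation worth stating: the point-biserial ceiling

The PCA clustering readout is validated on feature tables with a planted
two-group separation. One natural bar — "PC1 should correlate with the
grouping at point-biserial |r| > 0.8 when the planted shift is 3 within-group
SDs" — turns out to be unattainable *in the typical case*, for a reason
worth recording: with a total planted displacement of $d$ within-group SDs,
the point-biserial correlation between *any* linear score and a balanced
group indicator has population ceiling

$$ r_{\max} \;=\; \frac{d}{2\sqrt{1 + d^2/4}}, $$

which is 0.832 at $d = 3$ (and 0.707 at $d = 2$). Even an oracle that
recovers the planted direction perfectly sits essentially at the 0.8 bar,
and sampling spread puts the median over seeds just below it (≈ 0.78–0.80
measured over 100 seeds). The package keeps the strict assertion in its
acceptance suite as a documented red flag rather than quietly widening the
band; the mechanism itself is validated at a 5-SD shift, where recovery is
essentially certain, and by the reconstruction identity
(scores × loadingsᵀ = standardized matrix, exact to 10⁻⁸).

A related subtlety: whether the potent group lands at *positive* PC1 depends
on the deterministic sign convention, not on the data. The separation
readout therefore reports the class means and a flag for whether the potent
group's mean PC1 exceeds the rest's; users should read the flag together
with the score plot, not as a one-sided hypothesis test.

## Activity encoding

Concentration–response rows store amplitude as percent of the control
kainate-evoked current with an SD, per concentration (decade steps,
10⁻¹²–10⁻⁶ M). The potency summary is the point of largest departure from
100% — appropriate because these modulators show bell-shaped concentration
dependences that no sigmoid (EC₅₀/Hill) fit would represent; accordingly no
curve fitting is offered. Classification is a simple trichotomy: PAM at
max effect ≥ +10%, NAM at ≤ −10%, otherwise "NA" (no activity). The 10%
default separates the weakest potentiator in the packaged series (+22%) from
the flat profiles; it is configurable, and no finer "weak PAM" boundary is
defined because none is established in the field. SDs are stored but unused
by classification — a stated limitation, since no significance test
accompanies the underlying recordings.

## Worked example

```{r pipeline}
# a synthetic "trajectory": 15 degrees of inter-plane tilt, 10 A gap,
# thermal jitter, 101 frames at 200 ps
dim <- make_dimer(dimer_geometry(
  angle_deg = 15, face_gap = 10, lateral_shear = 2,
  jitter_sd = 0.05, n_frames = 101, seed = 42
))
series <- descriptor_series(dim$atoms, selection_spec())
avg <- window_average(series)
round(as.numeric(avg), 3)
as.numeric(dim$truth)
```

```{r activity}
act <- load_table3()
profiles <- classify_modulators(act)
profiles |> filter(!is_reference) |> arrange(desc(max_effect_pct))
```

```{r pca}
sim <- make_feature_table(group_shift = 3, seed = 1)
fit <- pca_features(sim$features)
glance(fit)
```

```{r hrms}
validate_hrms() |>
  filter(!known_discrepant) |>
  select(compound_id, adduct, mz_calc_printed, mz_calc, matches_printed) |>
  mutate(mz_calc = round(mz_calc, 4))
```
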