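---
title: "Scoring chromosome paint territories in 3D: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosome paint territories in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromterr)
```

## The problem

Whole-chromosome paint FISH in whole-mount *C. elegans* gonads shows each
chromosome as a contiguous nuclear territory. During early meiotic
prophase these territories reorganize dramatically: compact premeiotic
ovoids about 0.67 µm wide elongate into threads, homologs find each other,
associate first at the pairing-center (PC) end, and finally align along
their entire lengths, at which point a homolog pair appears as a single
territory. Historically these features were scored by eye in 3D volume
renderings. `chromterr` turns that visual scoring into a reproducible
computational pipeline and pairs it with a ground-truthed synthetic image
generator, so that every estimator and classifier can be validated against
known geometry.

The package scores four things:

* **Morphometry** — territory width $D$, length $L$, the slenderness ratio
  $S = L/D$ with the *highly extended* call $S > 6$ (strict), and the
  painted-segment count $k$ (the beads-on-a-string measure of elongation).
* **Proximity** — the shortest edge-to-edge distance $d$ between two
  territories, classified in units of the width: touching, close
  ($0 < d \le D$), intermediate ($D < d \le 2D$) or far ($d > 2D$).
* **Pairing topology** — a per-coordinate association profile between
  homologs, the alignment state (unaligned / partial / full), and the
  association configuration taxonomy: V-PC, Y-PC, V-NPC, Y-NPC, X, O,
  full, no alignment, no contact.
* **Gonad zoning** — premeiotic / transition / pachytene zones from
  chromatin clustering and chromosome-I alignment, the five-zone N/5
  subdivision of the meiotic region, and the nonparametric category
  statistics (two-tailed chi-square, Mann-Whitney, Fisher exact).

## The synthetic generator

No raw microscopy data are available for this assay, so the generator *is*
the study system: it defines the conditions under which the scoring
pipeline is validated.

A territory is a flat-capped tube: a centerline curve with a constant tube
radius, the diameter being the territory width $D$. Widths are drawn from
a normal distribution with mean 0.67 µm and SD 0.05 µm, the measured
premeiotic values. The analytic slenderness is the centerline arclength
divided by $D$; flat caps (rather than hemispherical ones) make the
rendered tip-to-tip extent equal the centerline length, so the analytic
and measured slenderness refer to the same quantity.

Centerline families, chosen by feasibility rather than by stage label:

* near-straight persistent random walks when the length fits the allowed
  extent (compact ovoids, gently curved threads);
* helices with a pitch of $2r + 1.1$ µm when a long thread must pack
  into the nucleus — the pitch keeps successive turns from fusing in the
  rendered mask even after blur;
* planar arcs on a peripheral shell (radius about $0.8R$ for a nuclear
  radius $R = 2$ µm) for extended territories that are planted *apart*
  from their homolog: two long curves can only maintain a large
  edge-to-edge distance inside a 2 µm nucleus by running along opposite
  sides of the periphery, which is also where transition-zone chromosomes
  actually live.

Homolog pairs are planted by construction: homolog B is homolog A
displaced along a guaranteed-clear direction (the shell axis) by a smooth
magnitude profile — 0.35 D over planted paired runs, 2.2 D elsewhere, with
0.03-coordinate cosine ramps. The 2.2 D separation keeps unpaired
stretches unambiguously apart (they must exceed the pairing threshold
$\epsilon = 1D$ *and* the skeleton cover radius used in decomposition).
Non-homologous contact ("no alignment") is planted as a T-contact: one
homolog's end resting on the other's middle, built from two great arcs on
the shell that cross exactly once. Fully aligned pairs coincide within
0.3 tube radii. The planted truth (association profile, edge distance,
proximity, alignment state, analytic morphometry) is recorded with the
geometry and can be re-derived by brute-force discretization, which the
test suite does.

Beads-on-a-string intensity modulation uses $|\cos(\pi (k-1) u)|^{1/2}$
bumps (peaks at both chromosome ends, narrow troughs flooring at 10% of
peak). The exponent keeps bead plateaus wide and inter-bead gaps short, so
a segmented territory fragments at most into pieces the assembly step can
re-merge; bead contrast and spacing have no published quantification for
this assay, so these are the package's own choices. Rendering adds a DAPI channel covering all
chromatin (including six unpainted background chromatin blobs that give
clustered transition-zone nuclei their asymmetric chromatin crescent),
then optional Gaussian PSF blur (defaults 0.1 µm lateral / 0.2 µm axial
sigma), a constant background (5 counts) and Poisson noise at
`photon_scale = 200`. Voxels default to 0.1 µm isotropic (the z step is
the published acquisition increment; the xy pixel size is not reported
anywhere, so isotropic sampling is assumed).

## Segmentation

Channels are thresholded with a robust background rule: median plus four
(scaled) MADs of the *whole field*. The field is dominated by
non-territory voxels, so this tracks the background mode regardless of how
the foreground is tiered — bead troughs, and the doubled intensity where
two homolog tubes overlap, both defeat Otsu's bimodality assumption (an
in-region Otsu lands inside the foreground and amputates dim structures;
this is why Otsu is available as an alternative policy rather than the
default). On noise-free renders the rule reduces to "every positive
voxel", which reproduces the analytic tube exactly. Components smaller
than 10 voxels are removed; components of one chromosome's channels closer
than `merge_gap = 0.3` µm (safely below the 0.67 µm width) are merged and
bridged, so bead gaps rejoin while distinct homologs stay apart.

## Morphometry estimators

The centerline is the longest geodesic path through the 26-connected voxel
graph of the mask, found by two farthest-point sweeps from the deepest
(maximal distance transform) voxel, then traced with edge weights
penalized away from the medial axis. Three numerical details matter at
0.1 µm voxels:

* **Tips.** Farthest-point tips land on end-face *corner* voxels, which
  inflates tip-to-tip length along a diagonal. Each endpoint is therefore
  recentered to its end-slab centroid transversally, with the axial reach
  set to the slab's 95th percentile — the sub-voxel estimate of the end
  face.
* **Smoothing.** The voxel path zig-zags on the lattice, which inflates
  arclength by several percent. An adaptive smoothing spline (degrees of
  freedom grown until 95% of residuals are below 0.8 voxel) removes the
  zig-zag while following genuine curvature; a U-shaped tube of arc length
  $\pi$ µm measures within a few percent of $\pi$, not of its chord.
* **Width.** $D$ is twice the median of the Euclidean distance transform
  sampled (trilinearly) along the interior of the centerline — interior
  meaning more than one radius away from either tip, since end caps thin
  the transform without carrying width information — plus a 0.8-voxel
  boundary calibration determined once on analytic rasterized cylinders
  across radii, grid phases and orientations. The median makes the
  estimate robust to bead troughs.

With these choices both $L$ and $D$ are unbiased to well under half a
voxel on straight tubes. Random curled territories still carry a few
percent of shape-dependent spread, which is why the slenderness decision
boundary is probed with canonical straight tubes: sweeping analytic
$S = 1 \dots 12$ in steps of 0.5 at width 0.67 µm, every $S \le 6$ tube is
called compact and every $S \ge 6.5$ tube highly extended, placing the
empirical boundary exactly at the strict $>6$ threshold.

Painted segments are counted on the summed-channel intensity profile along
the centerline: local maxima are merged below a minimum separation
(0.3 µm), and a split is declared where the trough between two peaks falls
below half the lower peak (`gap_fraction = 0.5`), or where the dominant
fluorophore changes between stable blocks (spatially resolved color
boundaries); $k$ is the number of resulting blocks. Both thresholds are
exposed; they stand in for the "distinctly segmented by eye" judgment.

## Pair topology

When segmentation yields two territories for a chromosome, each gets a
centerline, oriented by matching terminal channel signatures against the
paint scheme (double-labeled ends are disambiguated by a second sample
further inward; unorientable centerlines are scored under both
orientations, keeping the one maximizing the paired fraction, flagged).
A coordinate bin is *paired* when the same-coordinate points of the two
centerlines lie within $\epsilon = 1D$.

When the homologs touch they segment as a single mask, and the association
pattern must be read from that merged object — the genuinely hard part of
the assay. The package decomposes the mask through its curve skeleton:

* the diameter path (length $P$) plus residual branches give the total
  skeleton length $T$;
* each path end and branch tip is assigned a chromosome end (left/right)
  from the paint colors around it;
* a residual component whose attachments cluster at two far-apart path
  positions closes a *ring* (the O configuration); a robust 10-90% span of
  the attachment positions separates such closures from unpaired arms that
  merely graze the path;
* two path ends with the *same* end color mean a pair folded at the
  opposite end: the single-chromosome length is $\hat L = T - P/2$ and the
  paired fraction $f = \mathrm{stub}/(P/2 + \mathrm{stub})$, giving V
  versus Y by the 15% terminal cutoff;
* left- and right-colored residual arms attaching mid-path are the hidden
  arms of an X; arms re-emerging at both path ends are an O traversal;
* a single residual arm whose length matches its attachment point means
  the path ran through one whole homolog and the arm is the partner's
  unpaired side (Y-type fold-through).

Two intensity checks guard the fold interpretations against non-homologous
T-contacts, which can mimic them geometrically: a genuine merged stretch
carries about *twice* the paint intensity of a single tube — read per
channel (the maximum across channels, since double-*labeled* chromosome
ends emit one-fold into two channels without being doubly occupied) — so
the brightest point along a candidate stub, sampled at several positions
because beads modulate both strands, must clearly exceed the bright
single-occupancy level of the path's terminal arms (ratio thresholds 1.3
for stubs, 1.4 for fold-through runs, both below the blur-attenuated
doubling of about 1.6-1.9 and above the 1.0-1.1 of single tubes). Finally, a dominant-color *coordinate sequence*
along the path that resets (jumps back toward the left end) identifies
non-homologous contact; a monotone sequence with no residual structure is
full alignment. The synthesized paired runs then go through the same pure
`classify_configuration()` cascade as the two-territory route.

Configuration scoring is most reliable with the three-color,
double-labeled-ends chromosome II paint — the same design used for the
published configuration counts — and that is what the recovery analyses
use; two-color half paints orient centerlines but cannot always
distinguish a T-contact from partial alignment.

## Zoning and statistics

The transition zone is defined quantitatively as the maximal contiguous
run of rows (after the premeiotic rows) in which at least half the nuclei
have clustered chromatin and fewer than 90% have fully aligned chromosome
I territories; both thresholds are exposed in `zone_scheme()`. The
premeiotic zone is the first 10 rows by default (15 for the wider
premeiotic window of the proximity analysis — the two published
definitions are both supported and deliberately not merged). Pachytene is
a 15-row window (configurable 15–20) beginning 5 rows past the transition
zone end. The `syp1_six_zone` scheme divides the meiotic region of $N$
rows into five zones of widths $(n, n, n, n, N - 4n)$ with $n$ the
half-away-from-zero rounding of $N/5$.

The statistics are thin wrappers with pinned conventions: chi-square
without continuity correction (errors on zero margins), Fisher exact
(verified against exhaustive hypergeometric enumeration for all 2×2
tables with total ≤ 20), and Mann-Whitney using the exact distribution for
combined $n \le 20$ without ties and the tie-corrected normal
approximation otherwise (verified against brute-force rank enumeration).
No multiple-testing correction is applied, matching the reporting
convention of the original analyses. The boundary overlap in the printed
proximity bounds — "intermediate ($D < d \le 2D$)" versus "far
($2D \le d$)" — is resolved to intermediate at exactly $d = 2D$, with
`boundary_2d = "far"` to flip.

## What the synthetic validation does and does not show

Passing recovery on this generator shows the estimators and classifiers
are correct for tube-like territories with the stated widths, noise and
blur. Real gonad stacks differ in ways the generator deliberately does not
model: depth-dependent and non-Gaussian PSFs, chromatic registration
error, hybridization inhomogeneity beyond the bead model, touching
neighboring nuclei (the package scores single-nucleus fields; the
published analyses excluded poorly separated nuclei by eye), and true
chromatin texture. Absolute-scale fidelity is also unverifiable because
the original xy pixel size was never reported. The biological
quantifications (premeiotic proximity fractions, the 50% / 25–30%
highly-extended rates, per-genotype p-values) require the original
microscopy data, which were not deposited; the gonad scenarios plant
distributions of that character so the *machinery* can be exercised
end-to-end, not to reproduce those numbers.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen to exercise every
code path with comfortable statistics: width panels of 100 territories,
20 nuclei per configuration label per noise condition, gonads of 2–3
nuclei per row, and 200 simulated premeiotic gonads of 15 nuclei for the
null calibration (scored analytically from the planted geometry, which is
exactly what a rendered-and-segmented run estimates, without the rendering
cost).
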