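---
title: "Quantifying nuclear architecture remodelling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear architecture remodelling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucarch)
```

## The biological problem

During mammalian preimplantation development, nuclei undergo a drastic
reorganisation around the onset of embryonic genome activation. Before
activation, chromatin lies peripherally against only part of the
nuclear lamina, nuclear pore complexes (NPCs, marked by the nucleoporin
NUP153) are restricted to the chromatin-contacted envelope, the nuclear
interior is largely DNA-void, and large NUP153-positive clusters sit
dispersed in the cytoplasm. After activation, chromatin contacts the
whole lamina, NPCs distribute uniformly, nuclear volumes shrink
sharply, and the envelope develops invaginations and sheds
lamina-derived vesicles. `nucarch` turns the quantitative arguments
behind these observations — voxel intensity classification, marker
enrichment statistics, envelope topology censuses, and an
intron-coverage statistic for nascent transcription — into tested,
reusable code that runs end-to-end on ground-truthed synthetic data.

## Seven-class equal-variance intensity classification

DNA-stain (DAPI) voxel intensities within an analysis region are
partitioned into `k = 7` contiguous classes whose within-class
intensity variances are equal: class 1 holds voxels near background
(cytoplasm / interchromatin space), class 7 the densest chromatin.
This is threshold-independent: no background cutoff is chosen; the
class system adapts to each cell's intensity distribution. Boundaries
are fitted per region (per nucleus or per mitotic cell), not per
dataset, matching per-cell analyses.

`fit_class_boundaries()` works on the sorted sample with prefix sums,
so every candidate partition is scored in constant time:

1. cuts start at equal quantiles;
2. Gauss–Seidel sweeps move each interior cut to the admissible
   position (ties are never split) that best balances the population
   variances of its two flanking classes;
3. if the sweeps reach a fixed point or a non-improving limit cycle
   above tolerance, a *waterline* reinitialisation — binary search on a
   target variance with greedy left-to-right packing — provides a
   global restart, after which the sweeps resume.

Convergence is declared when the coefficient of variation (CV) of the
per-class variances drops below `tol` (default `1e-3`). A fit that
stalls at a coordinate-wise discrete optimum above `tol` is *accepted
and reported as such* (`convergence = "discrete optimum"`, with a
warning when the CV exceeds ten times the tolerance): on samples with
sparse extreme tails, moving any cut by a single admissible position
overshoots, so the tolerance is unattainable by any contiguous-class
algorithm. A quantitative example: the equal-variance partition of an
Exp(1) sample has, in the continuous limit, equally spaced boundaries
(a consequence of memorylessness), which leaves only a handful of
sample points in the top class even at one million values; its
variance then jumps by tens of percent per point, and the best
achievable CV is of order 0.1–0.5, not 0.001. Uniform-like intensity
distributions, by contrast, converge below `1e-3` easily. The
implication for real images is that the *fit quality metric* depends
on the intensity histogram's tails, while class assignments themselves
remain stable; `classify_voxels()` records the achieved CV with every
map. An error is raised only on true non-termination within
`max_iter`.

Interval convention: classes `1..k-1` use half-open intervals
`[b[i-1], b[i])`, the top class is closed. Boundaries are midpoints
between distinct adjacent sample values, making the fit equivariant
under positive affine intensity rescaling. For plateaus of tied values
the two-point degenerate case returns the midpoint (e.g. 0.5 for
`{0,0,1,1}` with `k = 2`).

An alternative — 1-D k-means (Jenks) — was considered and rejected:
k-means minimises pooled within-class sums of squares and therefore
equalises nothing about per-class variances.

## Marker enrichment across intensity classes

For marker-positive voxels, `enrichment_profile()` tabulates per class the
region voxel count `D_c` and marker count `M_c`, the expected fraction
`e_c = D_c / sum(D)` under random placement, the observed fraction
`o_c`, and the relative enrichment `r_c = o_c / e_c - 1`.

The null hypothesis "markers distribute proportionally to class
voxel counts" is tested with the Pearson goodness-of-fit statistic
(`gof_test()`), `df = #classes - 1`; p-values are computed on the log
scale so extreme significance (the mitotic analyses yield bounds such
as p below 1e-15) never underflows silently — values below 1e-300 are
labelled as that bound with the statistic retained. Expected counts
below 5 set a `small_expected` flag. Pairwise class comparisons
(`pairwise_class_test()`) collapse to a 2x2 table of marker densities
`M/D` and use Fisher's exact test for small expected counts, a
continuity-corrected chi-square otherwise.

Marker positivity (`marker_mask()`) defaults to the robust background
rule `median + 8 * MAD` of the region's intensities. Otsu's threshold
was considered and rejected as the default for this step: in punctate
channels the positive voxels are far below one percent of the region,
and a histogram-split criterion then maximises between-class variance
by splitting the dominant background mode — the threshold lands inside
the background, or above isolated puncta once bright punctum overlaps
stretch the intensity range. Otsu (computed on log intensities) and a
fixed recorded threshold remain available, and the threshold actually
used is always stored with the mask.

Voxels are treated as independent observations, as in the source
analyses; no spatial autocorrelation correction is applied. The
calibration study in the test suite (2000 simulated small mitotic
stacks with proportional placement, 5000 marker draws each) shows the
test holds its nominal 5% level within Monte-Carlo error.

## Synthetic data: what it emulates, and what it does not

The generators provide exact ground truth for every downstream stage.
Master seed plus parameters give bit-identical output; each stochastic
component draws from its own substream (nucleus: chromatin texture,
pore puncta, invaginations, vesicles, clusters, noise — in that
order), so adding a component never perturbs the others.

**Nucleus stacks** (`gen_nucleus_stack()`): an ellipsoidal nucleus
(default semi-axes 2.5 x 2.2 x 2.0 µm, a scale at which native-voxel
stacks stay tractable) rendered into DAPI / lamin B / NUP153 channels
at default voxel size 39.5 x 39.5 x 125 nm. The pre-activation
phenotype restricts the chromatin rim (400 nm thick, textured by a
thresholded smoothed Gaussian random field — no generative description
of chromatin texture exists, so this is a free modelling choice) to a
polar cap covering `chromatin_contact_fraction` of the surface and
leaves an interior lacuna; pore puncta (8 per µm² of contacted
surface, area-weighted sampling on the ellipsoid) are placed only on
the contacted cap when `npc_conditional = TRUE`. The post-activation
phenotype has a closed rim and unconditional puncta. Envelope
invaginations are rendered as inward capsules (radius 150 nm) in the
channel combination of their immunophenotype; lamin-positive tubes use
twice the lamina rim amplitude, reflecting the apposed double fold of
an infolding (and keeping thin, blur-attenuated tubes above the
detection threshold). The generator guarantees the truth-count
invariant — structures never merge — by enforcing pairwise clearance
between whole tube segments and between vesicles and tubes during
placement; scene parameters must leave enough interior room or
placement fails loudly. The lamina band is never rendered thinner than
one voxel on the coarsest axis so the envelope stays topologically
closed at any grid. Optics: anisotropic Gaussian point-spread blur,
FWHM 130 nm lateral / 300 nm axial (3D-SIM-like; values rounded for
stable kernels), then Poisson noise on the signal and additive
Gaussian read noise — the standard fluorescence noise model. The
default photon scale is 30 counts per intensity unit (roughly 3000
photons at signal peaks, ~2% shot noise), reflecting the high
signal-to-noise of reconstructed 16-bit 3D-SIM data; a lower budget
turns the top intensity class into an artifact of extreme noise
outliers.

Not emulated: structured-illumination raw frames and reconstruction
artifacts, depth-dependent aberrations, chromatic shifts, real
chromatin texture statistics. Passing tests therefore demonstrate
correctness of the *measurement operators* under a known geometry, not
robustness to every real-world imaging nuisance.

**Mitotic stacks** (`gen_mitotic_stack()`): a metaphase-plate ellipsoid
with a radial intensity profile `bg + A(1 - rho^2)^gamma`, azimuthal
chromatid-lobe modulation, multiplicative texture and a smooth
cytoplasmic autofluorescence haze (the haze keeps the background class
from being a degenerate constant plateau). The truth class map is the
package's own equal-variance fit of the noise-free rendered channel;
marker puncta are then drawn *multinomially* over classes with
probability proportional to `class_weights[c] * D_c` — so the all-ones
weight vector is exactly the proportional null, and
`n_marker_voxels` counts punctum draws (a voxel can be drawn twice;
truth records per-class draw counts). `enrichment_profile()` accepts
either truth counts or a rendered-image marker mask; the million-draw
recovery analyses use the counts path because collapsing a million
draws into a voxel mask would bias density ratios through collisions.

**Read alignments** (`gen_reads()`): each read is unspliced with
probability `u` (uniform start over the gene span, fully matched
CIGAR) or spliced (uniform start over the exonic transcript, `N` skip
segments over introns). With `u = 0` no aligned base ever falls in an
intron — the exact zero of the RINP statistic below. Records round-trip
through SAM via `write_sam()` / `read_alignments()` (Rsamtools).

## Nucleus segmentation and volumes

`segment_nucleus()`: Gaussian smoothing (sigma one lateral voxel,
scaled by the axial anisotropy), Otsu threshold, morphological closing
(ball radius two lateral voxels), 3-D hole filling, largest
26-connected component. Hole filling keeps the DNA-void lacuna of
pre-activation nuclei inside the mask, so volume means
envelope-enclosed volume. The DNA channel suffices for closed-rim
nuclei; for pre-activation nuclei whose chromatin rim is open, the
pipeline segments the lamin B channel — the contiguous envelope
marker — by default. All morphology is built on an exact anisotropic
Euclidean distance transform (compiled), so radii and thicknesses are
physical (nm) regardless of voxel anisotropy.

Volume is voxel count times voxel volume, reported in µm³. Group
comparisons use two-sided Welch tests with Bonferroni adjustment
capped at 1; the underlying studies report family-wise values like
"p = 1" for indistinguishable stages, which this scheme reproduces.
The choice of test is a documented default — the original reports do
not name their statistic.

## Envelope topology

`lamina_shell()` extracts the band within `thickness_nm` (default
200 nm) of the mask boundary and flags, per voxel, chromatin contact
(a DNA-positive interior voxel within `d_c` = 200 nm) and NPC presence
(a marker-positive voxel within `r_n` = 150 nm, the scale of the NPC
outer diameter of roughly 105–145 nm). Concordance statistics
(`npc_chromatin_concordance()`) are evaluated on the one-voxel
boundary layer — the discrete surface — rather than the full band:
within the band, distance to interior chromatin varies with depth, and
mixing depths would manufacture a spurious contact-pore association
even under uniform placement (the post-activation null). The 2x2
contact-by-pore table yields an odds ratio (Haldane-corrected on empty
cells) and a two-sided Fisher p; fully contacted surfaces are flagged
degenerate, with fractions still reported.

`detect_structures()` classifies connected components of
lamin-or-marker-positive voxels outside an exclusion band (shell
thickness + 150 nm, so the blurred lamina rim itself is never called a
structure) by 3-D topology: envelope-connected and inside means
invagination; inside and disconnected, interior vesicle;
outside-connected, extrusion; outside-disconnected, extranuclear
segment. Components under 5 voxels are discarded. Immunophenotype
(`classify_positivity()`) calls a channel positive when at least
`f_pos = 0.25` of the structure's voxels exceed its threshold. The
original typing was visual; these operators are the package's explicit,
configurable formalisation, and the well-known 69/18/13% partition of
invagination immunophenotypes is reproduced as a census over detected
structures with true counts 62/16/12 of 90. `extranuclear_clusters()`
profiles marker clusters beyond a 250 nm exclusion band (wide enough
that envelope pore signal bleeding outward is not mistaken for a
cluster) and classifies scenes by the median centroid distance against
`D_prox` = 0.5 µm.

## RINP: reads in intronic regions per not-covered intronic position

For each gene, introns are the span minus the exons
(`derive_introns()`). A read counts as intronic when at least one
aligned base (CIGAR `M/=/X`; `N` skips and `D` deletions excluded)
falls in an intron — the source describes counting "reads mapped to
intronic positions" without an overlap fraction, so the 1-base rule is
the default and a majority rule sits behind a flag. Covered intronic
positions are intronic bases under at least one aligned base, and

```
RINP = intronic_read_count / (uncovered_intronic_positions + 1)
```

with the pseudocount guarding the fully-covered denominator (the
source formula's behaviour at full coverage is unstated). RINP is 0
exactly when no read touches an intron; it rises with the unspliced
fraction and with depth. Strand is ignored (library strandedness
unstated); duplicate, secondary and supplementary alignments are
excluded. Aggregation pools counts over a gene set per replicate
(`sum(reads) / (sum(uncovered) + 1)`), then averages replicates per
stage — the shape of the published stage profiles for the combined
nucleoporin and lamin gene sets, which use three replicates per stage.
No published RINP magnitude is available as a numeric target, so the
statistic is validated through its exact zero, a worked
interval-arithmetic example, and monotonicity in the unspliced
fraction.

## Pipelines

`run_image_pipeline()` chains simulation, segmentation,
classification, enrichment, shell, concordance, structure detection
and census per configured nucleus; `run_rinp_pipeline()` chains read
simulation and RINP aggregation over stages and replicates.
Configurations are plain lists or YAML/JSON files; outputs are plain
CSVs whose bytes reproduce exactly under the same config and seed, and
every report carries a provenance block (package version, config MD5,
seed). Nucleus `i` uses seed substream `i`; stage `i`, replicate `j`
uses substream `100 i + j`.

## Problem sizes and numerical choices

The test suite and the acceptance script use these study conditions,
chosen once: native 39.5 x 39.5 x 125 nm voxels wherever a criterion
concerns resolution (volume recovery, million-voxel mitotic
enrichment), and coarsened voxels (100–250 nm) with proportionally
smaller nuclei for topology and concordance replicates, where the
operators under test are resolution-robust; the null calibration runs
2000 independent 28 x 28 x 7 flat-core plates with 5000 marker draws
each, a design whose per-class expected counts sit above the Pearson
adequacy rule. Seeds are fixed
in tests and derived from `--seed` in the acceptance script.
Tolerances reflect the dominant error source: voxelisation for
geometry (3–10%), Monte-Carlo error for calibration (±0.01), machine
precision for arithmetic identities.

## Known limitations

* Structure detection assumes structures are spatially separated at
  the imaging resolution; overlapping invaginations merge into one
  component (the generator enforces separation, real images may not).
* Concordance treats boundary voxels as independent surface elements;
  curvature-weighted mesh elements would be resolution-independent but
  are deliberately out of scope.
* The equal-variance fit's tolerance is unattainable on heavy-tailed
  histograms (see above); consumers should read the reported CV rather
  than assume 1e-3.
* The read simulator models no sequencing errors or positional bias;
  RINP behaviour under real library artefacts is untested here.
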