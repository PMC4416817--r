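# nucarch

Quantitative analysis of nuclear architecture remodelling in 3-D
structured-illumination (3D-SIM) image stacks of preimplantation embryo
nuclei, plus an intron-coverage statistic for detecting the onset of
embryonic transcription in RNA-seq data.

Around embryonic genome activation, embryo nuclei switch from an
unusual architecture — chromatin pressed against only part of the
nuclear lamina, nuclear pore complexes (NPCs, marked by NUP153)
confined to the chromatin-contacted envelope, a DNA-void interior, and
cytoplasmic NUP153 deposits — to a conventional one with a uniformly
contacted lamina, uniformly distributed pores, shrinking volumes, and a
transient wave of envelope invaginations and lamina-derived vesicles.
`nucarch` implements the measurements behind such observations as
tested, reusable R functions, together with ground-truthed simulators
of image stacks and read alignments so every stage is verifiable
without external data.

For whom: microscopists and computational biologists quantifying
nuclear envelope organisation in 3-D fluorescence stacks, and anyone
needing a controlled testbed for voxel-class enrichment statistics.

## What it computes

* **Seven-class equal-variance DNA intensity classification**
  (`fit_class_boundaries()`, `classify_voxels()`): voxel intensities in
  a region are split into `k = 7` contiguous classes with equal
  within-class variance — class 1 ≈ background/cytoplasm, class 7 =
  densest chromatin. Threshold-independent, deterministic,
  affine-equivariant.
* **Marker enrichment across classes** (`enrichment_profile()`): with
  `D_c` region voxels and `M_c` marker voxels per class, expected
  fraction `e_c = D_c / ΣD`, observed `o_c = M_c / ΣM`, relative
  enrichment `r_c = o_c / e_c − 1`; Pearson goodness-of-fit test of the
  proportional null (`gof_test()`) and 2×2 marker-density comparisons
  between classes (`pairwise_class_test()`, Fisher or chi-square).
* **Nucleus segmentation and volumes** (`segment_nucleus()`,
  `nuclear_volume()`, `volume_comparison()`): smoothing–Otsu–closing–
  hole-fill–largest-component segmentation; volumes in µm³; Welch
  tests with Bonferroni capping across stage pairs.
* **Envelope topology** (`lamina_shell()`,
  `npc_chromatin_concordance()`, `detect_structures()`,
  `structure_census()`, `extranuclear_clusters()`): lamina shell
  extraction with per-voxel chromatin-contact and NPC flags; 2×2
  contact-by-pore concordance (odds ratio, Fisher p); detection and
  immunophenotyping (NUP+/lamin+, NUP−/lamin+, NUP+/lamin−) of
  invaginations, interior vesicles, extrusions and extranuclear
  segments; per-nucleus censuses and percentage partitions.
* **RINP** (`derive_introns()`, `intronic_coverage()`,
  `compute_rinp()`, `aggregate_rinp()`): reads in intronic regions per
  not-covered intronic position,
  `RINP = intronic reads / (uncovered intronic positions + 1)` — a
  proxy for unspliced, nascent transcription; per gene, pooled over
  gene sets, averaged over replicates per stage. Reads SAM/BAM
  (Rsamtools) and GTF (rtracklayer).
* **Simulators** (`gen_nucleus_stack()`, `gen_mitotic_stack()`,
  `gen_reads()`): ground-truthed pre/post-activation nuclei, mitotic
  plates with controlled per-class marker enrichment, and
  spliced/unspliced alignments at a controlled unspliced fraction.
  Bit-reproducible per seed.
* **Pipelines** (`run_image_pipeline()`, `run_rinp_pipeline()`):
  config-driven end-to-end runs with deterministic CSV outputs and
  provenance (version, config hash, seed).

## Worked example

Simulate a pre-activation nucleus (chromatin contacting half the
envelope, pores placed only on the contacted surface), segment it on
the lamin channel, and test pore–chromatin concordance:

```r
library(nucarch)

params <- nucleus_params(phenotype = "pre_mga",
                         semi_axes_um = c(2.2, 2.0, 1.8),
                         chromatin_contact_fraction = 0.5,
                         voxel_dims = c(100, 100, 200), seed = 42)
sim <- gen_nucleus_stack(params)
sim
#> Synthetic pre_mga nucleus: 84 x 80 x 38 voxels; 201 NPC puncta; 0 structure(s); true volume 33.3 um^3

mask <- segment_nucleus(sim$stack, channel = "laminB")
nuclear_volume(mask, sim$stack)      # um^3, truth is 33.3
#> [1] 38.7

npc_chromatin_concordance(lamina_shell(mask, sim$stack))
#> NPC-chromatin contact concordance over 4296 surface elements
#>        npc
#> contact  yes   no
#>     yes 1545  708
#>     no    28 2015
#>   odds ratio: 157 ; Fisher p: 0
#>   NPC-positive fraction | contacted: 0.686 | non-contacted: 0.0137
```

The concordance is the quantitative form of the pre-activation
phenotype: over two thirds of the chromatin-contacted surface carries
pore signal, almost none of the non-contacted surface does, and the
odds ratio is in the hundreds.

Marker enrichment on a mitotic plate, with the generator placing
puncta at twice the background density in intensity classes 2–3:

```r
m <- gen_mitotic_stack(mitotic_params(
  plate_semi_axes_um = c(1.8, 1.8, 0.9), margin_um = 1,
  voxel_dims = c(150, 150, 400),
  class_weights = c(1, 2, 2, 1, 1, 1, 1), n_marker_voxels = 10000,
  seed = 1))
prof <- enrichment_profile(m$truth$D, m$truth$marker_counts)
gof_test(prof)
#> Pearson chi-square goodness of fit
#>   marker distribution vs proportional null
#>   statistic = 178.212 , df = 6 , p = 8.134e-36
```

Classes 2–3 show relative enrichments of roughly +0.8 and +1.2
(accumulation), the remaining classes sit near or below zero, and the
proportional-placement null is rejected decisively — the same form of
analysis used to show pore-marker accumulation at chromatid peripheries
and relative depletion in chromatid interiors.

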