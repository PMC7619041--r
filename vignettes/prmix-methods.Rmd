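---
title: "Primary region mix: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary region mix: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dense whole-brain delineation assigns one of over a hundred anatomical
subregion labels to essentially every pixel of a high-resolution
dual-fluorescence section: the foreground-to-background pixel ratio of such
data is around 0.84, and subregion sizes span orders of magnitude. Data of
this kind is scarce — sections are enormous and slow to image — so offline
augmentation is how training sets are grown. Object-centric mixers (MixUp,
CutMix, CarveMix) were designed for sparse targets; applied to near-dense
label maps they either blur labels pixel-wise or paste regions with no regard
for global anatomy, piling foreign tissue onto unrelated regions and
destroying the topological cues a dense segmenter needs.

PRMix addresses this with three cooperating pieces:

1. **Hard-sample mining (HSM).** Mixing partners are chosen offline by a
   structural similarity, oversampling dissimilar ("hard") pairs.
2. **Primary region sampling (PRS).** The unit of exchange is not a pixel or
   a box but a *primary region* — one of `P = 11` coarse anatomical groups
   (CB, TH, MB, HB, Isocortex, HY, OLF, CTXsp, STR, PAL, HPF) that partition
   the subregions — so swaps preserve the brain's large-scale organization.
3. **Overlap-aware augmentation (OAA).** Each transplanted region is placed
   by a greedy affine search that keeps its spill onto foreign target
   territory below a tolerance.

## Mixing laws

With source `(Xs, Ys)` and target `(Xt, Yt)` on a common grid, the package
implements four laws. MixUp blends convexly,

    X = lam * Xs + (1 - lam) * Xt,   lam ~ U(0, 1),

with labels as per-class soft weight maps (hard labels are not well defined
under convex blending; `hard_labels()` exports the argmax). CutMix and
CarveMix share the binary-mask form

    X = Xs * M + Xt * (1 - M),

with `M` an axis-aligned rectangle (CutMix) or a semantic region mask
(CarveMix). The pairwise PRMix law replaces, for each selected primary region
`p`, the target's region with an overlap-mitigated copy of the source's:

    Xp = Xs_hat * Ms_hat + Xt * (1 - Mtp)

where `Msp = Ms1 ∪ ... ∪ Msk` is the union of the region's subregion masks,
`Ms_hat = OAA(Msp, Mtp)` is the placed source mask, and `Xs_hat` is the
source image under the identical geometric transform. The multi-source form
folds this pairwise operation over the sources, each iteration replacing its
assigned regions in the running target. Subregion label values travel
unchanged, so every pixel's annotation provenance is preserved and no label
value is ever invented.

## The placement search

`oaa()` draws one random affine — rotation and isotropic scale about the
region's foreground centroid, then translation, each uniform on its
configured range — and applies it to the source region's label patch by
nearest-neighbor resampling (the mask is its nonzero support, so mask and
labels can never disagree). The spill of a placement is

    o = |M & !Mtp|,

the count of placed pixels landing outside the target's own region; counting
against the full complement means spill onto *background* also counts, which
keeps pasted tissue inside the brain silhouette. A `foreground` overlap mode
restricts the count to other regions' territory instead.

If the unshifted placement already satisfies `o < tau`, it is used as is.
Otherwise integer shifts `(sx, sy)` are scanned over a square window (rows
outer, columns inner, ascending; ties keep the earliest-scanned shift),
tracking the best overlap, and by default the whole search stops at the first
shift below `tau`. Only the shift is re-optimized in the greedy phase;
rotation and scale stay at their sampled values (an optional multi-restart
resamples the affine and keeps the best placement). The winning shift is then
re-applied to the subregion labels and to *all* image channels under the one
shared transform — nearest-neighbor for labels, bilinear for intensities —
so the coupled fluorescence channels move as a unit and intra-region marker
co-localization is preserved exactly.

Because the unshifted placement is the first evaluated candidate, the
returned overlap never exceeds it; with early stopping disabled and stepsize
1, the result equals the exhaustive minimum over the full shift grid. The
test suite checks this equivalence against a brute-force per-shift oracle on
random instances, and the convergence flag is defined as exactly
`overlap < tau`.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| `tau` | `ceiling(0.02 * area)` of the transformed region | regions span orders of magnitude, so an absolute pixel tolerance cannot fit all of them; 2% of the placed area keeps tolerated spill proportional |
| rotation range | ±10° | parasagittal anatomy is orientation-stable; small rotations emulate sectioning variation without flipping structures |
| scale range | [0.9, 1.1] | inter-animal size variation is modest |
| translation range | ±5% of `min(H, W)` | local tissue shifting, not relocation |
| shift window | ±10% of `min(H, W)`, stepsize `max(1, floor(min(H, W)/64))` | wide enough to find a slot, coarse enough to stay cheap; grid-relative so behavior is size-invariant |
| `easy_fraction` | 0.2 | the top 20% most similar candidates are "easy"; the rest "hard" |
| `hard_fraction` | 0.8 | oversampling 80% hard gives the best challenge/learnability balance |
| `n_mix_images` | 3 | two gives minimal variation, four disrupts the target's global structure |
| `regions_per_mix` | [3, 9] | enough exchange for diversity while most of the target's anatomy stays intact |
| `opening_radius` | 1 | removes single-pixel mixing artifacts without eating real boundaries |

All are exposed through `search_config()`, `mix_config()`, and
`run_config()`.

## Similarity and mining

The "mask overlap score" between two samples is the mean, over primary
regions present in at least one of them, of the IoU of the two primary
masks. Rationale: primary regions are the unit being exchanged, and IoU
directly measures the structural (not photometric) variation that makes a
pair hard to mix; a region present in only one sample contributes IoU 0, so
missing-region patterns count toward hardness. The score is exposed as a
pluggable function (`score_fn`) since other structural metrics are
defensible. Mining is deterministic: ties at the easy/hard cut break by
ascending sample ID, and the matrix caches to CSV.

Source draws are independent Bernoulli(`hard_fraction`) choices between the
two sets, each followed by a uniform draw within the set; independent draws
may repeat a source, and an empty set falls back to the other with a warning.

## The phantom generator

Real sections cannot ship with the package, so every module is exercised on
synthetic phantoms that emulate the *structural statistics* of the data: an
elliptical foreground sized so the foreground:background ratio is 0.84 (with
per-sample aspect jitter that preserves area exactly, so the ratio is stable
up to discretization); 11 contiguous primary regions grown by Voronoi
assignment from random interior seeds — chosen over random polygons because
Voronoi cells are contiguous and adjacency-rich, stressing the overlap
machinery the way packed anatomy does; a second Voronoi pass subdividing
each primary region into its 2–12 taxonomy subregions (totals near 118);
per-subregion channel means drawn from a shared base level so the two
channels are correlated within a region, plus Gaussian texture noise; and
10% per-region dropout emulating structures lost to the sectioning plane.
One taxonomy is drawn per dataset and shared by all its samples.

What phantoms deliberately do **not** emulate: real synaptic texture,
stitching artifacts, tears and folds, intensity gradients across a section,
or anatomically realistic region shapes. Passing tests therefore demonstrate
the *algorithmic* contracts — placement optimality, composition exactness,
accounting, determinism — not segmentation benefit on real microscopy, which
requires training a segmenter on real annotated sections. One consequence of
the synthetic geometry is visible in the diagnostics: random Voronoi layouts
differ structurally far more than two real brains do, so placements converge
below `tau` less often than they would on anatomy, and occasionally a hard
paste covers a small region of the running target entirely, in which case
that region's own replacement is skipped with a logged diagnostic.

The default subregion-to-primary table shipped in
`inst/extdata/primary_regions_synthetic.json` is likewise synthetic: it has
the 11 standard primary-region names and 118 subregion labels with plausible
per-group counts, but the true assignment of atlas subregions is
annotation-specific and should be supplied by the user for real data.

## Numerical choices

- Coordinates are row-major, 1-based in R, origin top-left; geometry is
  computed in corner-based continuous coordinates (pixel `i` centred at
  `i - 0.5`), which makes a 180° rotation about a symmetric mask's centroid
  an exact involution.
- Masks and label maps are resampled nearest-neighbor (binary stays binary,
  label values stay exact); images bilinearly; one matrix serves all
  channels.
- Pairwise operations on unequal grids pad the smaller with background,
  anchored top-left.
- Vacated pixels (target-region territory not covered by the placement)
  become background by default — the literal composition algebra — with a
  `vacated = "retain"` alternative, since reasonable practitioners disagree
  on which is more realistic.
- The search scans `sx` outer / `sy` inner, ascending; the early-stop rule
  is interpreted globally (the first shift below `tau` ends the search).
- Morphological opening applies per label in ascending order with a disk
  brush of radius `opening_radius`; opening is anti-extensive, so opened
  labels never collide and pixels lost to no one become background. It is
  applied to label maps only, after the final composition — the artifacts it
  targets are boundary-delineation edges, not intensities.
- The pipeline derives each mix's seed from `(master seed, target ID, pass)`
  by a portable string hash, so fold runs are order-independent and reruns
  are bit-identical.
- Number of regions per mix: the 3–9 draw is made once per mix (total across
  sources), and each selected region is assigned to a uniformly chosen
  source containing it.
- The pipeline draws candidate regions from the full taxonomy `1..P` and
  skips (with a counted log entry) any mix that drew a region absent from
  the target or from every source — the offline exclusion rule — so output
  counts satisfy `outputs + skips = targets × fold`.

## Problem sizes used by the tests

Unit tests run on 48×80 to 64×128 phantoms with 4–8 primary regions; the
placement-oracle checks use 16×32 toy instances where exhaustive search is
exact and cheap; the generator-profile and region-count checks use the
default 256×512, 11-region configuration (200 samples / 200 mixes). These
sizes were chosen so the full suite completes in a few minutes on one core
while still exercising every contract at the defaults.

## Known limitations

- Placement optimizes shift only; a transform whose rotation/scale draw is
  unlucky may not converge even when some other affine would (mitigated by
  `restarts`).
- Overlap tolerance interacts with region size through `tau_rel`; very small
  regions get `tau` of a few pixels and may rarely converge on structurally
  dissimilar pairs.
- MixUp outputs carry soft labels; downstream consumers needing hard maps
  lose the blending information through `hard_labels()`.
- PNG label maps are 8-bit (255 labels); use TIFF for the full 16-bit range.
- The package augments; it does not train or evaluate a segmenter beyond
  per-class precision/recall/F1/mIoU utilities.
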