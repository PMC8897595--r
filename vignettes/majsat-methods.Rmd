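---
title: "Models and methods behind majsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind majsat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

majsat chains five analyses that together ask whether Argonaute-bound
miRNAs can engage mouse pericentromeric major-satellite transcripts,
and whether losing that engagement is visible as a redistribution of
heterochromatin marks over chromocenters. This vignette explains the
models, the tunable parameters, the synthetic data the tests rest on,
and the design choices that were genuinely open.

## Satellite regions and seed sites

Mouse major satellites are AT-rich tandem repeats with a ~234 bp unit,
stretching over kilobases at pericentromeres. The `repeats` functions
select analysis regions from RepeatMasker annotations: exact-name
filtering on the `GSAT_MM` label, then a length rule keeping merged
regions of at least 20 kb (`min_length = 20000`). Two details are
deliberate:

* Coordinates are 0-based half-open internally. RepeatMasker `.out`
  query coordinates are 1-based inclusive and converted on parse; UCSC
  `rmsk` rows pass through unchanged. Both dialects are tested to land
  on identical internal intervals. (Image pixel coordinates, by
  contrast, are R-native 1-based `(row, col)`.)
* Whether adjacent annotations should be merged before the 20 kb rule
  is not dictated by anything in the underlying biology; the default
  `merge_gap = 0` merges only bookended or overlapping annotations
  (pure per-annotation filtering for separated hits) and the gap is a
  parameter.

A miRNA's 8mer target site is the DNA reverse complement of its
positions 2–8 followed by `A` — the canonical definition, in which the
adenine opposite position 1 is part of the site regardless of the
miRNA's first base. 7mer-m8 and 7mer-A1 variants are provided for
sensitivity analyses. `count_sites` counts *overlapping* occurrences by
a sliding window ("scanned and counted" admits either convention;
overlap counting is the conservative-complete one, and the test oracle
counts the same way); `N` never matches. The default scans both strands
because major satellites are transcribed bidirectionally — per-strand
counts are reported, so an annotated-strand analysis is a column
selection. Ranking is by total count with lexicographic tie-breaks, so
results are deterministic; miRNAs with identical mature sequences (the
miR-30a/d/e-3p situation) provably get identical counts.

## AGO-loading classification

Loading calls compare a RIP library against its input on the
`log2(cpm + 1)` scale (pseudocount exactly +1). miRNAs must pass an
expression floor of `log2(cpm+1) >= 5` (~31 cpm); the scope of the
floor — input, RIP, either, or both — is ambiguous in principle, so it
is a parameter with `either` as the default. The eligible set is ranked
by `delta = x_rip - x_input` and the top and bottom
`floor(0.2 * n_eligible)` become `loaded_top` / `unloaded_bottom`
(at least one each when anything is eligible; ties break
lexicographically). A cpm-ratio ranking statistic is available behind
a flag.

One numerical point deserves care. CPM is compositional: if a planted
subset gains counts in RIP, *every* proportion shifts by the common
factor `log2(sum of weights)`, so "enriched at +2, neutral at 0" cannot
both hold under column-sum normalization. The count-table generator
therefore samples each miRNA independently at nominal library sizes and
records truth on the nominal scale; `cpm()` accepts explicit library
sizes so that truth is exactly recoverable, while the default
column-sum normalization is what the classifier uses — the common
compositional shift cancels in the delta ranking, leaving calls
unaffected. Recovery tests on the default synthetic table (500 miRNAs,
50 enriched at +2 log2, negative-binomial dispersion 0.05) reach
precision and recall ≥ 0.9 when the called fraction matches the planted
prevalence (top 10%); with the default top-20% cut the recall is the
meaningful number, since the call set is twice the planted set.

## qPCR arithmetic

All Ct math assumes perfect per-cycle doubling (amplification
efficiency 2, as the 2^−ΔΔCt estimator implies; no Pfaffl-style
efficiency correction). Percent input adjusts the input Ct for the
chromatin fraction it represents, `ct_input - log2(1/fraction)`, then
`100 * 2^(adjusted - ct_ip)`; the worked value (IP 25, input 28,
fraction 0.10) is 80%. Relative expression is
`2^-[(ΔCt_sample) - (ΔCt_control)]` with technical replicates averaged
on the Ct scale *before* the ΔΔCt (a convention; averaging folds
instead would bias upward by Jensen's inequality). Replicate summaries
use a two-sided unpaired t test, Student by default with Welch
selectable. The Ct generator encodes a fold `f` as a `log2(f)` cycle
shift of the treated-condition target, so a noiseless table
round-trips exactly and the round-trip is asserted to 1e-12 (`log2`
then `2^` of a non-dyadic fold is exact only to floating point).

## The imaging chain

`quantify_scene` re-implements a CellProfiler-style pipeline:

1. max-intensity z-projection per channel;
2. nuclei: Otsu threshold over a 256-bin histogram (ties to the lowest
   qualifying bin boundary), hole filling, 8-connected components, an
   area gate from the nucleus diameter range (default 40–200 px via
   circular equivalence), and border-object removal — the automated
   stand-in for manual nucleus editing;
3. foci: white top-hat speckle enhancement (image minus its grayscale
   opening with a disk element), one *global* RobustBackground
   threshold — drop the lowest and highest 5% of pixels, then
   trimmed mean + 2 SD, with the SD computed with denominator *n*, as
   the reference tool does — 4-connected components, and channel
   diameter gates of 5–35 px (DAPI) and 7–35 px (marker);
4. relations: each focus's parent is the nucleus (and, for marker foci,
   the DAPI focus) whose mask contains its centroid
   (`centroid_in_parent`, deterministic); a `max_overlap` rule with
   lower-id tie-breaks is available;
5. per-nucleus counts — DAPI foci, marker foci, and marker foci with a
   DAPI parent (the colocalized count) — compared between groups with a
   two-sided Mann–Whitney U test (exact null when `n1*n2 <= 400` with
   no ties, otherwise normal approximation with tie and continuity
   corrections) and median/quartile summaries (linear interpolation,
   R's type 7).

Intensities are measured on the projected, un-enhanced image.

Two parameters differ from the most literal reading of the source
settings, for reasons the implementation made unavoidable:

* **Top-hat element size** (default 15 px, not the 35 px gate maximum).
  The opening undershoots wherever the element overhangs the nuclear
  rim, turning the rim into a bright annulus roughly half the element
  wide; with a 35 px element that annulus swallows every peripheral
  focus. An element modestly larger than the foci it should pass
  (≤ ~10 px here) and much smaller than the nucleus suppresses the body
  equally well without the artifact.
* **Foci labeling connectivity** (4, not 8). A global threshold two SDs
  above the trimmed mean always passes a few percent of background
  pixels; under 8-connectivity, diagonal chains of those pixels bridge
  distinct foci. 4-connectivity — the labeling the reference tool's
  backend uses by default — severs the chains. Nucleus segmentation
  keeps 8-connectivity.

## The synthetic scenes

`gen_nuclear_images` renders what the quantification chain is meant to
measure: a 640×640 px field with five non-overlapping nuclei
(radius 45–55 px, soft logistic edge), around fifteen chromocenters per
nucleus (Gaussian blobs, σ 2 px, amplitude matching the nuclear body)
and around fifteen marker foci (Gaussian spots, σ 1.8 px — detected
extents sit comfortably inside the 7–35 px gate), additive Gaussian
read noise at SNR 10 (nucleus amplitude over noise SD), a 0.5 px
Gaussian optical blur (microscope images are band-limited;
pixel-independent noise would be unphysical), and 16-bit quantization.
Objects keep ≥ 16 px apart and ≥ 15 px inside the nuclear rim so that
every planted object is individually resolvable, as the discrete foci
in real micrographs are; when a nucleus fills up, the truth tables
record the objects actually placed. Each marker focus is colocalized
(centered on an unoccupied chromocenter) with probability `p_coloc`,
else placed in the nucleoplasm at least `2 × chromocenter radius` from
every chromocenter center.

In z, the nuclear body appears at full intensity in every slice — it is
thicker than the inter-slice spacing — while chromocenters and foci
live only in the focal slice. This matters twice over: it makes the
max projection a real step (an averaging projection would dim foci by
the slice count), and it keeps the noise statistics of the projected
nucleus interior identical to the background, which the global
2-SD threshold implicitly assumes. With an attenuated body the interior
of the projection carries single-slice noise while the background
carries a max-of-z envelope; the threshold, calibrated by the
background, then passes interior pixels at a high, SNR-independent
rate.

What the scenes do *not* emulate: shot noise, chromatic shift, uneven
illumination, touching or overlapping foci (no declumping is
implemented, matching the chain), partial z-occupancy of large
chromocenters, and autofluorescence. Passing tests therefore show the
chain is correct on resolvable, well-separated objects — they do not
certify performance on crowded real images.

## Test design and problem sizes

Every operation with a stated contract is checked against an
independent brute-force oracle sharing no code with the implementation:
sliding-window counting by explicit window comparison, interval
selection by a quadratic merge, Otsu by exhaustive search over all 256
candidates, the top-hat by composed neighborhood min/max loops,
labeling by flood fill, relations by per-pixel tabulation, and the
exact Mann–Whitney null by enumeration of all C(6,3) assignments for
the 3-vs-3 case. End-to-end checks run 500 random seed-scan cases, 200
random region-selection instances, ten default imaging scenes (nucleus
counts exact; colocalized counts within ±1 for ≥ 90% of nuclei), a
30-vs-30 nucleus effect detection at `p_coloc` 0.9 vs 0.2 through the
full image pipeline (expected p < 0.01), and a 200-pair null
calibration of the rank test at the count level of the scene model
(Poisson foci thinned binomially) — these sizes keep the whole suite in
a few minutes while leaving the Monte-Carlo margins comfortable.

## Known limitations

* The seed scanner is exact-match only: no wobble pairing, no
  thermodynamic or context scoring, no 3'-supplementary sites.
* Loading calls are rank-based; there is no dispersion modeling or
  hypothesis test behind the top/bottom cut.
* qPCR assumes efficiency 2 throughout.
* The imaging chain has no declumping, no 3D segmentation, and no
  illumination correction; group statistics pool nuclei across scenes
  without experiment-level blocking.
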