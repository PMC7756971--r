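---
title: "Herb-specificity statistics and marker selection in molecular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herb-specificity statistics and marker selection in molecular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formulanet)
library(dplyr)
```

## The problem

A multi-herb formula is a decoction of several herbal drugs mixed in fixed
w/w proportions. Each herb contributes hundreds of secondary metabolites,
and routine quality control needs markers that are both *specific* to one
herb and *abundant* enough to monitor. `formulanet` operationalizes a
data-driven selection of such markers from untargeted LC-MS metabolite
profiling of the formula and each single-herb extract, combined with ELSD
(evaporative light scattering) detection for semi-quantitative abundance.

The package assumes peak picking and alignment have already been done (by
MZmine or similar): its inputs are aligned feature quantification tables
(feature id, m/z, retention time, per-sample peak heights), MS/MS spectra in
MGF keyed to feature ids, integrated ELSD peak lists, and a sample manifest.

## Feature-based molecular networking

Each feature with a fragmentation spectrum becomes a node. Spectral
similarity is the **modified cosine**: intensities are square-rooted and
L2-normalized; candidate fragment pairs are those matching directly within
the fragment tolerance or after shifting by the precursor mass difference
(aligning fragments that retain a structural modification); a one-to-one
assignment of pairs is chosen greedily by descending weight product, and the
score is the sum of chosen products. The greedy assignment reproduces the
behavior of the reference networking tool and is O(p² log p) in the peak
count; on small spectra it is verified in the test suite against an
exhaustive maximum-weight assignment and agrees on all packaged fixtures.
Ties in the greedy ordering are broken by peak indices, and ranking ties in
the top-K rule by lower feature id, so network construction is fully
deterministic.

Edges require cosine ≥ 0.7 and ≥ 6 matched peaks (defaults; the strict
"more than 6" reading is available via `strict_matched`), and survive only
if each endpoint ranks within the other's top 50 surviving neighbors.
Connected components of size ≥ 2 are clusters, numbered by descending size
with ties broken by smallest member id; singletons carry the sentinel −1.
The fragment and precursor-shift tolerance is a single parameter (0.02 Da
default); no additional precursor-mass edge constraint is applied. No
maximum component size is enforced.

## Specificity percentages

For one aligned feature, the share of herb *i* is
$s_i = 100\, h_i / \sum_j h_j$ with the sum running over **herb samples
only** — formula and blank heights never enter the denominator. "Detected"
means height > 0 after alignment; no extra height floor is imposed beyond
what peak picking already applied. Features with an all-zero herb total get
undefined shares and are excluded from specific counts. Before counting,
the table is reduced to features detected in the formula and not
blank-derived. The blank rule is not prescribed by the upstream processing
convention, so the default is a ratio rule (maximum blank height ≥ 0.5 ×
maximum herb height), with a strict any-blank-detection mode available.

A feature is specific to its top herb when the maximum share reaches the
node threshold (default 90, **inclusive** — shares between 90 and 94% are
reported as specific). Cluster specificity is the unweighted arithmetic
mean of member shares per herb, with the dominant herb assigned at the
cluster threshold (default 75, inclusive; the tie convention is fixed by a
test where a two-node cluster averaging exactly 75% is dominant).
Whether the mean should run over all scored members or only
formula-detected ones is genuinely open; the default averages
formula-detected members (the quantity of interest is the formula's
composition), and `members = "all"` is available. Report rounding follows
printed-report precision: one decimal for feature-share percentages,
nearest integer for cluster-level summary percentages.

## ELSD integration and marker selection

MS response is not proportional to amount, so abundance ranking uses ELSD.
Peaks with area ≥ 0.004 μV/s (inclusive) are kept and labeled
`<herb><rank>` by descending area (ties by earlier RT). Each ELSD peak is
assigned to the candidate HRMS feature of the same herb's specific set
within an RT tolerance (default 0.1 min — the instruments share
chromatographic conditions but not a detector path, and the offset is not
calibrated here), taking the highest height in that herb; a nominal m/z
from an in-line quadrupole, when provided, vetoes candidates outside
±0.5 Da; a manual override table always wins, mirroring expert curation.
Unassigned peaks are reported as "not detected in the formula" rather than
erroring, since that is a scientifically meaningful outcome.

Positive- and negative-mode features are paired when RT agrees within
0.05 min and the implied neutral masses (precursor ∓ 1.007276 Da) within
10 ppm, one-to-one by smallest combined scaled distance; both tolerances
are package choices since cross-mode pairing is usually done by eye. A
marker is `specific` when its share for the source herb reaches the node
threshold in **every** mode where the feature is detected; single-mode
detections are judged on that mode and flagged rather than hidden. An
abundance override can retain the top-n non-specific peaks per herb under
an explicit `retained_by_abundance` flag — dominant components sometimes
deserve retention despite sub-threshold specificity, but never silently.

## Annotation

Molecular formulas are enumerated exhaustively over CHNO within bounds
(C ≤ 60, H ≤ 120, N ≤ 10, O ≤ 30 by default) at a ppm tolerance, requiring
RDBE in [0, 40] and integer-valued (the even-electron parity rule for
neutral molecules, needed to bound the search); candidates are ranked by
absolute mass error. Library matching restricts candidates to entries whose
adduct precursor matches within 0.005 Da, scores them with the same
modified cosine, and keeps the top 6 above cosine 0.2. Chemotaxonomic
re-ranking stably promotes species- over genus- over family-level matches
of the feature's specific herb, leaving cosines untouched. Within a cluster
containing an anchor point (a formally identified node), candidates of the
anchor's compound class are promoted for every member, and members receive
co-marker labels numbered by ascending RT (the labeling order is a package
convention). Cross-mode candidate consistency is exposed as report columns,
not enforced automatically. The packaged 40-entry library is synthetic
(real in-silico fragmentation databases are not redistributable): real
compound names, formulas, taxa and classes with computer-generated spectra,
suitable for exercising the matching logic, not for annotating real data.

## Signature categories

Clusters qualify for exactly one category: (1) dominant herb and ≥ 1
anchor — the ideal herb-specific analogue series; (2) an anchor but no
dominant herb — the member list is restricted to nodes specific to the
anchor's herb; (3) dominant herb, no anchor, but at least one
taxonomically consistent annotation. Bar-chromatogram extraction collapses
members whose RTs agree within 0.02 min (in-source fragments and adducts of
one compound), keeping the highest formula height per run of co-eluting
members.

## The synthetic generator

`generate_dataset()` emulates the structure the workflow assumes: each herb
carries analogue families (default 4 families of 5 members) whose spectra
share a fragment template — half the fragments fixed, half shifted with the
precursor — so within-family modified cosine is ≈ 1 and across families no
systematic matches exist; ubiquitous metabolites occur in every herb at
equal concentration; formula heights are the w/w-weighted sum of herb
signals; ELSD areas are concentration times a response factor, decoupled
from MS heights by per-metabolite lognormal ionization factors; blank
contaminants appear in blank and formula runs only. All intensities carry
multiplicative lognormal noise with mean 1 and configurable CV (default
0.1) — the standard noise model for LC-MS intensities; no replicate
structure is modeled. Default w/w proportions follow a typical 10-herb
decoction recipe (3.4–20.7%, normalized to sum 1).

Two deliberate idealizations matter for interpreting green tests. First,
retention times within one herb sit on jittered, well-separated slots
(minimum spacing above the ELSD RT tolerance), so ELSD assignment is
identifiable by construction; co-elution and assignment conflicts are
exercised by dedicated fixtures instead. Second, single-herb metabolites
have exactly zero height in other herbs by default, so their specificity is
exactly 100% at any noise level and planted-marker recovery is exact
(precision = recall = 1 on the default study). Real data exhibit
cross-herb occurrence of nominally specific components; the
`cross_herb_leakage` parameter plants that, and the test suite uses it to
verify that marker recall degrades, in expectation over seeds, as noise
grows. Passing tests therefore demonstrate correctness of the statistics
and selection logic under the generative model — not performance on real
chromatograms, where alignment error, adducts beyond protonation, isotope
patterns and peak-shape effects (all out of the generator's scope) add
failure modes.

Problem sizes used by the default validation study: 10 herbs × 20
metabolites + 6 ubiquitous + 5 contaminants = 211 metabolites, ≈ 200
spectra per mode (≈ 20,000 pairwise similarities), 10,000 random features
for the normalization property, 200 seeded spectrum pairs for the greedy
vs. exact assignment check.

## Numerical choices

Shares are computed as `(h / total) * 100` (divide first) so a
single-source feature is exactly 100 within floating point. The cosine is
clamped to [0, 1] against accumulation error. Greedy ties are resolved by
peak index, pairing ties by feature id, cluster numbering ties by smallest
member id — every pipeline stage is a pure function of its inputs, and two
runs on one bundle produce byte-identical reports. Degenerate inputs have
defined behavior: empty spectra are errors at normalization; an empty ELSD
file is an empty table; clusters with no scored member are excluded with a
warning; non-finite node attributes are serialized as empty GraphML strings
with a warning.

## Known limitations

Vendor raw files, mzML parsing and peak picking are out of scope (aligned
tables are consumed as-is). Adducts beyond [M+H]⁺/[M−H]⁻ are not modeled.
No uncertainty is attached to specificity shares (no replicates), and
cluster means are unweighted — an intensity-weighted mean would behave
differently for clusters mixing strong and weak members. Library annotation
quality is bounded by the supplied library; the packaged one is synthetic.
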