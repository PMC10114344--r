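---
title: "Tumor Area Positivity scoring: model, geometry and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor Area Positivity scoring: model, geometry and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapscore)
```

## The scoring problem

PD-L1 expression in gastric and gastroesophageal-junction (GEJ)
adenocarcinoma and esophageal squamous cell carcinoma is scored to select
patients for checkpoint-inhibitor therapy. Two families of manual scoring
methods exist: cell counting (the Combined Positive Score, CPS) and visual
area estimation (the Tumor Area Positivity score, TAP). TAP is defined as
the percentage of the *tumor area* covered by PD-L1-positive tumor cells
(TC) and tumor-associated immune cells (IC):

$$\mathrm{TAP} = \frac{\text{area of PD-L1 positive TC and tumor-associated IC}}
{\text{tumor area}} \times 100\%$$

CPS instead divides the *count* of positive TC, lymphocytes and macrophages
by the count of viable TC (times 100, capped at 100, and conventionally
requiring at least 100 viable TC to be reportable).

This package implements both scores as deterministic computations on
annotated digital slides — a cell table and a set of labeled region
polygons in micrometer coordinates — together with the agreement
statistics used to validate observer reproducibility, and a synthetic
slide/reader generator so the whole validation design can be exercised
without any slide material.

A human reader applies TAP by Gestalt; this engine is a *formalization* of
the published rule set on explicit annotations. It is not a model of the
visual estimation process itself.

## The tumor-area geometry

The denominator is the area occupied by viable tumor nests and the
tumor-associated stroma, with specific inclusions and exclusions:

* **10x field rule.** Nests separated by non-neoplastic tissue belong to
  one tumor area when both are visible within a single 10x microscope
  field; the intervening tissue is included. We operationalize this as a
  morphological closing of the nest union with a disk whose diameter is
  one 10x field (default 2000 µm — a 10x objective with an 18–22 mm
  field-number eyepiece shows a 1.8–2.2 mm field; the physical size is a
  configuration parameter, `field_diameter_10x`). Closing fills exactly
  the inter-nest corridors up to that separation, is rotation-invariant,
  and is idempotent. It is also transitive across chains of nests (A near
  B near C merges all three even if A and C are distant); whether the
  visual rule chains this way is genuinely underdetermined, so the
  behavior is documented here and the component ledger records every
  merged corridor. Setting `apply_field_rule = FALSE` disables merging.
* **Inclusions.** Mucin pools and glandular luminal spaces (with or
  without viable TC) that touch the running tumor area; tumor nests inside
  lymphovascular spaces; for gastric/GEJ indications only, lymphoid
  aggregates with germinal centers that touch the tumor area.
* **Exclusions.** Necrosis, crush artifact and cautery artifact are
  subtracted wherever they fall; no point of an artifact region is ever
  inside the final geometry.
* **Lymph nodes.** For nodal metastases the tumor area is the nest union
  (10x field rule applied within the node) plus a band of width
  `leading_edge_margin` (default 50 µm) around each nest boundary, clipped
  to the node: the zone of "immediately adjacent" immune cells. The rule
  source gives no physical distance for adjacency, so the band width is an
  explicit, configurable modeling choice.

Polygon booleans and the disk offsets behind the closing are performed in
exact-ish floating geometry (Clipper, via the polyclip package) with a
snap tolerance of $10^{-3}$ µm; circular arcs are approximated to a
sagitta of 0.25 µm. Areas are exact shoelace sums over the resulting
rings. Every region's fate — included, excluded, or merged intervening
tissue — is recorded with a reason code in the `components` ledger of the
`tumor_area` object, for audit.

### The independent raster oracle

Because the vector geometry is the riskiest part of the engine, the
package carries a second, fully independent implementation:
`rasterize_tap_oracle()` burns the polygons onto a 1 µm pixel grid with an
even-odd scanline fill and performs the closing with exact Euclidean
distance transforms (EBImage), then restates the cell-eligibility rules
from scratch. The two routes share no geometry code. The test suite and
the acceptance script compare them on 50 random synthetic slides
(including clustered-nest, mucin, lumen, artifact and germinal-center
scenarios) and require agreement within 0.5 absolute TAP points; observed
deviations are an order of magnitude smaller, dominated by cells whose
centroid falls within one pixel of a mask boundary.

## Cell-level rules

A cell record carries its class, viability, centroid, footprint area,
staining phenotype (membrane none/partial/circumferential, cytoplasmic,
punctate, intensity 0–3) and annotated context. The scoring rules:

* TC are positive with circumferential **or** partial membrane staining at
  *any* intensity; cytoplasmic staining of TC is disregarded. Intensity is
  recorded but never thresholded.
* IC (lymphocytes, macrophages, granulocytes, plasma cells) are positive
  with membranous, cytoplasmic or punctate staining at any intensity.
* Eligibility is decided by ordered rules, reporting the first failure:
  necrotic cells never count; the centroid must lie in the tumor area;
  off-target cell types (fibroblasts, endothelium, neuroendocrine cells,
  smooth muscle, nerve, other) never count regardless of staining;
  multinucleated giant cells, granuloma IC, and IC inside blood vessels or
  lymphatics are excluded; intraluminal macrophages count only when they
  completely fill the lumen and contact TC; germinal-center IC count for
  gastric/GEJ only. The published reason codes cover the inclusion
  branches; we add `germinal_center_excluded` for the ESCC branch, which
  the rule set implies but does not name.

**Footprints.** Visual TAP estimates area, but annotations carry cells as
points, so each positive cell contributes its `footprint_area`. When the
annotation provides none, class defaults apply (TC 200 µm², lymphocyte
50 µm², macrophage 120 µm², granulocyte 60 µm²) — order-of-magnitude
cross-sections, configurable, and explicitly a modeling convention: the
visual method has no formal footprint. Overlap between scalar footprints
is not resolved (a documented limitation; polygonal footprints would be
unioned).

**Cutoffs.** Positivity is `TAP >= cutoff` (5–9% is the *positive*
borderline band, so a score exactly at 5% is positive). Borderline
categories follow the 5% convention: negative borderline at TAP 2–4%,
positive borderline at 5–9%. CPS validity requires 100 viable TC by
default (`min_viable_tc`); a zero TC denominator yields a missing CPS,
never 0.

## Agreement statistics

Precision studies dichotomize scores at a cutoff and compare readers
pairwise. From the 2×2 counts $(a, b, c, d)$ the package computes the
chance-unadjusted statistics

$$\mathrm{OPA} = \frac{a+d}{n},\qquad
\mathrm{APA} = \frac{2a}{2a+b+c},\qquad
\mathrm{ANA} = \frac{2d}{2d+b+c},$$

and, against a designated reference (the second margin),
$\mathrm{PPA} = a/(a+c)$ and $\mathrm{NPA} = d/(d+b)$. Between-reader
analysis pools every unordered reader pair across samples (3 readers ×
100 samples gives 300 comparisons); within-reader analysis pairs the two
reading rounds per reader and pools across readers; multisite analysis
sums site-level counts before recomputing (pooled, never averaged —
the two differ whenever sites are imbalanced). Acceptance flags follow
the conventional thresholds: APA and ANA at least 85%, and within-reader
OPA at least 90%.

Two confidence-interval engines are provided. The Wilson score interval
is the default: it is closed-form, respects the [0, 100] range, and
reproduces, to one printed decimal, the published method-concordance and
background-acceptability intervals that motivated this choice (verified
against an independent implementation before the engine was built). The
reader-study tables in the source publication print intervals that match
no single closed form we tested, and the method is unstated there; for
such designs a cluster bootstrap (samples as resampling clusters,
percentile interval, seeded and deterministic) is selectable instead. No
claim is made about which method the original authors used.

Reported tables round half-up to one decimal, matching convention; raw
values are retained in all machine-readable output.

## The synthetic generator

`generate_slide()` emits a valid annotated slide plus analytic ground
truth. Design choices:

* **Geometry.** Nests are convex perturbed ellipses; each is wrapped in a
  stroma annulus scaled so that stroma occupies `stromal_fraction` of the
  unit (default 0.4, a typical desmoplastic fraction for gastric
  adenocarcinoma). By default units are placed farther apart than one 10x
  field, so the closing is the identity and the denominator is a closed
  form (shoelace areas, scaled annuli, and the Steiner formula
  $A + P\,m + \pi m^2$ for a leading-edge band of width $m$). The
  `clustered_nests` scenario places nests within one field to stress the
  merging geometry; there the ground-truth denominator is the rasterized
  closing at 1 µm, never the vector engine under test.
* **Cells.** Poisson counts at `tc_density` (default 5000/mm² of nest)
  and `ic_density` (default 1500/mm² of unit), placed uniformly by
  rejection sampling; the IC class mix defaults to lymphocyte 0.60,
  macrophage 0.25, granulocyte 0.10, plasma cell 0.05. Staining is
  assigned by per-class positive fractions; a `target_tap` calibration
  solves for those fractions against the analytic denominator (70% of
  positive area from TC where feasible). Poisson noise leaves roughly
  ±0.2 TAP points of slide-to-slide variation at single-digit targets.
* **Scenarios.** Flags add mucin pools (annotated as nest hole plus mucin
  region), glandular lumina with intraluminal macrophages (half filling
  the lumen, half not), germinal centers inside lymphoid aggregates in
  the stroma band, nodal metastases with leading-edge and distant nodal
  IC, artifacts, and granulocyte-only positivity (the scenario in which
  TAP and CPS diverge by construction, since granulocytes never enter the
  CPS numerator).
* **Cohorts.** `generate_study_cohort()` reproduces the published study
  compositions exactly (e.g. 100 samples, 50 positive / 50 negative at
  the 5% cutoff, 10% borderline, 10% biopsies): per-slide TAP targets are
  drawn per class and slides are regenerated with derived sub-seeds
  (bounded retries) until the realized analytic TAP lands in its class.
* **Readers.** `simulate_reader_scores()` perturbs the latent continuous
  TAP on the logit scale and adds a near-cutoff flip mechanism with
  probability decaying as $e^{-|t - \text{cutoff}|/s}$, reproducing the
  qualitative observation that disagreement concentrates on borderline
  samples. Zero noise reproduces the truth exactly. All randomness flows
  from one master seed through derived sub-seeds; nothing touches the
  global RNG state.

**What the generator does not emulate.** Real slides have non-convex,
fragmented nests, spatially correlated staining, heterogeneous cell
morphology, annotation error, and readers who disagree for reasons other
than cutoff proximity. Passing tests on synthetic material therefore
demonstrates that the *rule engine and statistics are implemented
correctly*, not that the scoring method performs equivalently on real
tissue.

## Numerical choices and problem sizes

* Geometry snap tolerance $10^{-3}$ µm; arc sagitta 0.25 µm; these keep
  closing idempotence and rigid-motion invariance below $10^{-4}$
  relative error in the tests.
* The oracle-equivalence suite uses 50 slides of 1–2 nests at 110–150 µm
  mean radius at 1 µm oracle pixels; the distance-transform closing
  dominates the cost (a few seconds per slide). Halving the pixel size
  changes oracle areas by under 0.2%.
* The stroma-concordance experiment compares two 200-slide cohorts that
  share identical positive-fraction draws and differ only in stromal
  fraction (0.1 vs 0.6): the paired design isolates the dilution effect
  of stroma on TAP, which is the mechanism behind TAP/CPS discordance at
  matched cutoffs.
* Degenerate inputs: a slide without a tumor nest raises a typed
  `UNSCORABLE_NO_TUMOR` condition; an empty TAP denominator is an error
  rather than a 0 or 100 score; zero-denominator agreement statistics are
  reported as undefined rather than failing.

## Known limitations

* Scalar footprints ignore overlap between positive cells; dense sheets
  of positive IC can overstate the positive area slightly.
* The 10x field rule is implemented transitively (closing); a reader
  applying the rule pair-at-a-time on a microscope might merge less.
* CPS eligibility reuses the TAP notion of "tumor-associated" for its
  mononuclear IC; the counting method's own conventions differ subtly in
  practice (e.g. 20x-field heuristics), which we do not model.
* The package scores annotations as given; it does not detect necrosis,
  segment cells, or read whole-slide images.
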