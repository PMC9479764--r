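---
title: "Methods: correlative analyses for a neoadjuvant immunotherapy cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative analyses for a neoadjuvant immunotherapy cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neocorr` implements the correlative-analysis computations that accompany a
neoadjuvant immunotherapy trial in HPV-unrelated head and neck squamous cell
carcinoma: pathologic and radiographic response scoring, multiplex
immunofluorescence (MIF) quantification, T cell/Treg spatial proximity
analysis, ensemble somatic-variant consensus, neoepitope candidate selection,
ELISpot response calling, and cohort-level association testing. Because the
underlying patient data are controlled-access, the package ships a
synthetic-cohort generator that reproduces the statistical structure every
downstream stage assumes, so the entire pipeline runs and can be validated
without any external data.

## Pathologic and radiographic response

Pathologic tumor response (pTR) is reported as percent regression of the
tumor bed:

$$\mathrm{pTR} = 100 \times \left(1 - \frac{\sum_i v_i}{\sum_i b_i}\right),$$

where $v_i$ and $b_i$ are the viable-tumor and tumor-bed surface areas of
slide $i$. Summing areas before dividing makes the per-slide weighting by bed
area implicit, and the result is rounded to the nearest integer percent with
ties away from zero (the convention that reproduces printed rates such as
5/14 = 36%). Note the deliberate orientation: the source clinical convention
describes "% residual viable tumor", but every cutoff (complete response =
100, major = 90-99, partial = 50-89, none < 50; PR for correlative purposes
= pTR $\ge$ 50) treats pTR as regression, so the package defines pTR = 100 -
% viable throughout. Primary tumors and lymph nodes are scored separately; a
primary/LN pair is *discordant* when the two responses differ by more than 20
points, with a "possible LN CR" (suspicious node pre-treatment,
pathologically negative after) counted as 100. Radiographic lesion "volume"
is the product of the longest perpendicular bidimensional measurements (mm^2,
lesions summed within a site); the reported quantity is its percent change.

Patients with a possible LN CR enter the any-site response tally only under
the speculative flag, which is why the report carries both a confirmed and a
speculative any-site rate (the 43% / 71% pair in a 14-patient cohort with 6
confirmed and 4 speculative any-site responses).

## MIF quantification

Cells arrive as a segmented table (coordinates in um, compartment, marker
booleans, intensity bin 0-3, diameter, roundness). Phenotypes are gated by
required-positive / required-negative marker sets (e.g. CD8 T cell =
CD3+CD8+CD4-FoxP3-CK-; Treg = CD3+CD4+FoxP3+). The panel is validated for
pairwise satisfiability: two definitions may not be simultaneously
satisfiable by any marker vector, which makes per-cell labels unique by
construction. Cytokeratin-positive cells matching no immune definition are
tumor cells; the remainder are "other".

Densities are exact count/area quotients per compartment (tumor parenchyma,
stroma, or whole slide). The H-score is
$1\,\%_{1+} + 2\,\%_{2+} + 3\,\%_{3+}$, range 0-300. The stromal immune
fraction is the fraction of stromal cells that are cytokeratin-negative,
rounded and at most 15 um in diameter; "rounded" is qualitative in the
source convention, so the roundness threshold defaults to 0.8 and is
configurable.

Fold changes are `log2((post + eps) / (pre + eps))`. The pseudocount
`eps = 1` (in the metric's own units) engages only when either value is
zero; strictly positive pairs are untransformed. The same rule guards the
CD8/Treg density ratio. This is a package choice: the source analyses plot
finite log2 fold changes without stating their zero handling.

## Spatial proximity

The proximity stage measures distances between FoxP3- conventional T cells
(split by Ki67 status into Ki67+/- CD8 and CD4 classes) and FoxP3+CD4+
Tregs, within a 100 um radius (the radius is a length; a molar reading of
the figure legend's "100 uM" would be meaningless). Two summary modes exist
because the source figures phrase two different quantities:

* **pairwise** - every (T cell, Treg) pair within the radius contributes its
  distance; used for mean-distance statistics and pre/post shifts.
* **nearest** - each T cell contributes its nearest-Treg distance if within
  the radius; used for the per-T-cell distance-probability curves.

Both modes are explicit configuration, never a silent default switch. The
neighbor search buckets Tregs on a grid of cell size equal to the radius and
scans the 3x3 neighborhood per T cell; candidate indices are sorted before
distance evaluation so results are *bit-identical* to the exhaustive O(nm)
double loop (this equivalence is asserted on 200 random instances in the test
suite). No edge correction is applied, matching whole-slide analysis; a
`drop_border` flag removes T cells within one radius of the field border for
simulation studies. Distance-probability curves are fixed-width histograms on
[0, radius] normalized to sum 1, optionally smoothed with a Gaussian kernel
over bin centers (renormalized; bandwidth configurable). Ties in
nearest-Treg distance take the minimum, which is value-identical. The
pre/post shift is `log2(post_mean / pre_mean)`; a timepoint with zero
contributing pairs yields an NA sentinel rather than an error.

## Variant consensus

Somatic SNVs are retained when detected by at least 3 of the 4 callers
(LoFreq, MuSE, Mutect2, Strelka2); indels by at least 2 of the 3 indel-capable
callers (LoFreq, Mutect2, Strelka2 - MuSE emits none). Variant identity is
the exact (chrom, pos, ref, alt) key after parsimony normalization (shared
suffix then prefix trimmed, position advanced), so padded indel spellings
from different callers vote together; full left-alignment against the
reference genome is out of scope, which means equivalent deletions anchored
at different positions of a homopolymer run would not be merged. Caller
annotation fields are ignored entirely. The consensus VAF is Mutect2's when
Mutect2 supports the variant, else the supporter mean (the source convention
does not say whose VAF feeds ranking). Ingest defaults to PASS-only records
with a flag to include everything. Expression is transformed as
log2(TPM + 1).

## Neoepitope candidates

For each nonsilent consensus variant the mutant protein context records which
residues are altered: the substituted residue (missense), inserted residues
plus both junctions (in-frame insertion), the junction (in-frame deletion),
or everything from the shift to the residue before the new stop (frameshift).
"All permutations of 9-mers" is read as all sliding 9-residue windows that
overlap at least one altered position - combinatorial rearrangement of
residues is biologically meaningless here. Windows whose peptide occurs
anywhere in the wild-type protein are removed, and duplicates are dropped
keeping leftmost-first order; an interior missense therefore yields at most 9
novel peptides.

Candidates are ranked by `log2(TPM + 1) x VAF` (the source states the two
ranking keys but not the combiner; the product is this package's default and
`score_fn` is configurable), descending, ties broken by ascending IC50 then
peptide. Each peptide is scored against every patient HLA class I allele via
a pluggable predictor (binding prediction itself is out of scope; a
file-backed lookup and a deterministic hash-seeded synthetic stand-in are
provided) and keeps its best (lowest) IC50. Selection applies three criteria:
source variant present in the pretreatment sample, IC50 $\le$ 200 nM, and
TPM $\ge$ 4 - raw TPM by default, with a flag to threshold on the log scale
since the source phrasing ("TPM count of 4 or higher") is ambiguous - then
truncates to `max_per_patient` (default 12; the per-patient synthesis count
is unstated, and 12 makes a 9-condition plate plus controls realistic).

## ELISpot calling

Conditions are assayed in technical duplicate and all rules operate on the
duplicate means: *detected* means a mean count greater than 0, *positive*
means a post-treatment mean of at least 5 spots, *increased* means the
post - pre difference in means exceeds 5. No background subtraction is
applied by default (raw means are reported); optional no-peptide subtraction
floors at zero. Per-patient aggregates count positive neoepitope wells and
sum post-treatment means over all neoepitope wells; the CEF viral-recall
pool is tracked separately and never counted as a neoepitope.

## Statistics

Correlate-vs-response comparisons use the two-sided Mann-Whitney U test
(exact when both groups have at most 8 tie-free observations, else the
normal approximation with continuity and tie correction); paired pre/post
comparisons use the Wilcoxon signed-rank test; fold-change-vs-zero uses the
one-sample t test; paired continuous correlations use ordinary least squares
with the slope F test. All of these delegate to `stats::wilcox.test`,
`stats::t.test` and `stats::lm` - they are standard machinery, not this
package's contribution - and the wrappers only fix conventions and
sentinels: an empty group yields NA, an all-zero difference vector is
undefined for the signed-rank test (NA), and an all-zero fold-change vector
returns t-test p = 1 by convention (the t statistic is 0/0; "no evidence of
change" is the only defensible reading). Significance is p < 0.05 and no
multiple-testing correction is applied, matching the source analyses; the
report annotates the number of tests performed.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults are the study conditions used by the validation
suite, chosen once:

* **Cohort**: 14 patients, 5 drawn as responders (PR rate 36%), 2 with
  pathologically positive LNs, 5 with suspicious-but-N0 LNs, recurrences
  planted so 12/14 are disease-free at 1 year, and a core TGF-beta pathway
  mutation planted in 13/14 patients.
* **Slides**: a 1 mm x 1 mm analyzed field per timepoint (a realistic
  region-of-interest size that keeps a 28-slide cohort fast to simulate; the
  source data are whole slides), 4 circular tumor nests of radius 120-220 um,
  tumor cells at 1200/mm^2 of nest area, and per-phenotype Poisson point
  patterns in each compartment (stroma: 120 CD8, 120 CD4, 50 Treg, 80 PMN,
  80 macrophage per mm^2 at baseline). Per-patient cell counts per slide are
  not stated by the source, so these densities are package choices of
  plausible magnitude, scaled per patient by a log-normal heterogeneity
  factor (sdlog 0.25).
* **Planted spatial structure**: Tregs are placed last and any Treg within
  the exclusion radius (40 um pre-treatment) of a Ki67+ conventional T cell
  is resampled within its compartment up to 100 times, then dropped - this
  approximately preserves marginal densities while guaranteeing the
  minimum-distance constraint. Radius 0 gives complete spatial randomness
  with respect to Ki67 status.
* **Planted response effects**: responders get a post-treatment intratumoral
  CD8 influx (x3.5), stromal Treg reduction (50 to 25/mm^2), collapse of the
  Treg exclusion radius to 0, roughly one-third the non-responder
  pre-treatment stromal myeloid density, and ELISpot positives drawn as
  3 + Binomial(5, 0.4) wells of 9 versus Binomial(9, 0.05) for
  non-responders, with positive-well post-treatment means drawn from a
  shifted negative binomial (6 + NB(mu = 10, size = 3)) - overdispersed
  counts are the realistic noise model for spot counts.
* **Caller noise**: per-caller sensitivities 0.88-0.95 and private
  false-call rates 0.02-0.05; pathology viable fractions are drawn inside
  class-specific ranges (responders 0.31-0.49, non-responders 0.56-0.96) so
  planted responders have pTR >= 50 *exactly* and recovery of the responder
  set is a sharp parameter-recovery check.

All randomness derives from a single seed via fixed per-patient,
per-component offsets, so any sub-object is reproducible in isolation and a
fixed seed yields a byte-identical cohort.

What the generator does **not** emulate - and hence what passing tests do
not show about real data: pixel-level image content, segmentation error,
spatially varying (non-Poisson) immune infiltration beyond the nest/stroma
dichotomy, read-level sequencing noise (caller errors are Bernoulli/Poisson
abstractions), linkage between the simulated ELISpot wells and specific
selected peptides, real HLA binding physics, and survival times.

## Numerical choices and degenerate inputs

* Rounding of printed percentages: half away from zero.
* Zero tumor-bed area, zero pre-treatment lesion volume, zero compartment
  area and an empty denominator group are degenerate-input errors; an empty
  stromal cell set, a slide without Tregs and a timepoint without pairs are
  NA/empty sentinels, not exceptions, because they occur in valid data.
* The tumor-compartment CD8/Treg ratio is computed but is
  denominator-limited at these study conditions (about 5 intratumoral Tregs
  per field), so its fold change is noisy across seeds; the whole-slide and
  stromal ratios carry the same planted effect with stable counts, and the
  validation suite asserts the association on those. Real whole-slide data
  with orders of magnitude more cells would not share this small-count
  artifact.
* The validation suite sizes its simulations to run on a single CPU in a few
  minutes: 100 seeds for the planted-exclusion recovery, 200 random
  instances for the spatial oracle equivalence, 10,000 variants for the
  consensus-recall closed form (P(>=3 of 4 at 0.9) = 0.9477), and 200 null
  cohorts (pathology + MIF components only) for type-I-error calibration of
  the Mann-Whitney comparison.

## Known limitations

Indel normalization is parsimony-only (no reference-genome left-alignment);
the intensity-bin thresholds behind H-scores are assumed already applied by
the upstream segmentation platform and are shared within a patient's
pre/post pair, not across patients; dual-pathologist adjudication of pTR is
not modeled (one score per slide); and the ELISpot plate is simulated
independently of the selected peptide list, so peptide-level concordance
between the neoepitope and ELISpot stages is not a testable property of the
synthetic cohort.
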