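# neocorr

Correlative analyses for neoadjuvant immunotherapy trials in head and neck
squamous cell carcinoma.

Neoadjuvant (pre-surgical) immunotherapy trials pair a short treatment window
with deep correlative profiling of matched pre- and post-treatment tumor
samples. `neocorr` implements, as one tested pipeline, the computations such
a trial's correlative analyses rest on:

* **Pathologic response scoring** — pathologic tumor response
  (pTR = 100 × (1 − Σviable/Σbed), area-weighted over slides, rounded to 1%),
  response classes (pCR = 100, MPR 90–99, pPR 50–89, NR < 50; PR ⇔ pTR ≥ 50),
  primary/lymph-node discordance (> 20 points), and radiographic volume
  change (product of the longest perpendicular bidimensional measurements).
* **MIF quantification** — marker-based phenotype gating (e.g. Treg =
  CD3⁺CD4⁺FoxP3⁺), per-compartment cell densities (cells/mm²), H-scores
  (1·%₁₊ + 2·%₂₊ + 3·%₃₊, range 0–300), stromal immune fraction, and
  pre/post log2 fold changes with a zero-guard pseudocount.
* **Spatial proximity** — distances between Ki67± CD8/CD4 T cells and Tregs
  within a 100 µm radius, in pairwise and nearest-neighbor modes, with
  distance-probability curves and pre/post shifts; the accelerated search is
  bit-identical to the exhaustive O(nm) computation.
* **Variant consensus** — ensemble voting over LoFreq, MuSE, Mutect2 and
  Strelka2 call sets (SNVs kept at ≥ 3 of 4, indels at ≥ 2 of 3), with
  parsimony key normalization and log2(TPM+1) expression transform.
* **Neoepitope selection** — novel mutant 9-mer enumeration, ranking by
  log2(TPM+1) × VAF, best-IC50 scoring over patient HLA alleles through a
  pluggable predictor interface, and the three selection criteria
  (pretreatment presence, IC50 ≤ 200 nM, TPM ≥ 4).
* **ELISpot calling** — duplicate-mean based detected / positive (≥ 5
  spots) / increased (difference > 5) flags and per-patient aggregates.
* **Cohort report** — waterfall-ordered patient summaries, printed-rate
  computations, and two-sided Mann-Whitney correlate-vs-response tests.

A synthetic-cohort generator (`generate_patient_cohort()`) reproduces the
statistical structure the analyses assume — including a planted Treg
exclusion zone around proliferating T cells and caller-specific
sensitivity/false-call noise — so every stage runs, and can be validated by
parameter recovery, without access to patient data.

## Worked example

```r
library(neocorr)

cohort <- generate_patient_cohort(cohort_params(seed = 42))
report <- run_pipeline(cohort)

head(report$patients[, c("patient_id", "ptr_primary", "class_primary",
                         "pr_flag", "log2fc_tumor_cd8",
                         "n_positive_neoepitopes")])
#>  patient_id ptr_primary class_primary pr_flag log2fc_tumor_cd8 n_positive_neoepitopes
#>         P01          63           pPR    TRUE            1.693                      4
#>         P09          61           pPR    TRUE            2.530                      7
#>         P05          60           pPR    TRUE            1.604                      6
#>         P14          56           pPR    TRUE            2.027                      4
#>         P10          55           pPR    TRUE            1.856                      5
#>         P02          41            NR   FALSE            0.649                      0

str(report$rates)
#> List of 6
#>  $ pr_rate_primary         : int 36
#>  $ any_site_ppr_confirmed  : int 36
#>  $ any_site_ppr_speculative: int 57
#>  $ rfs_1yr                 : int 86
#>  $ core_tgfb_mutated       : int 93
#>  $ cef_positive            : int 57

report$associations$p[report$associations$correlate == "log2fc_tumor_cd8"]
#> [1] 0.003353436
```

The table is waterfall-ordered by descending primary pTR. The five planted
responders (pTR ≥ 50) were recovered exactly, the primary PR rate is the
expected 36% (5/14), 86% of patients are disease-free at one year, 93% carry
a core TGF-β pathway mutation, and the planted post-treatment tumor CD8
influx separates responders from non-responders at p ≈ 0.003 (two-sided
Mann-Whitney U).

## Analysis workflow

The numbered drivers under `analysis/` run the whole study end to end,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # synthetic cohort -> results/cohort/
Rscript analysis/02_score_response.R       # pTR, classes, discordance, volumes
Rscript analysis/03_quantify_mif.R         # densities, H-scores, fold changes
Rscript analysis/04_spatial_proximity.R    # T cell/Treg distances and shifts
Rscript analysis/05_variant_consensus.R    # ensemble voting, consensus VCFs
Rscript analysis/06_neoepitopes.R          # 9-mer candidates and selection
Rscript analysis/07_elispot.R              # response flags and aggregates
Rscript analysis/08_cohort_report.R        # summary, rates, association tests
```

Each step reads the previous steps' plain-text outputs (CSV/TSV, minimal
VCF 4.2, FASTA, JSON manifest), so any stage can be re-run or swapped against
real data with the same schemas.

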