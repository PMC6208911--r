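# strat4concord

Concordance analysis for RT-qPCR breast-cancer biomarker calls against
IHC/FISH reference methods.

Breast-cancer treatment decisions rest on four biomarkers — ER, PR, HER2 and
Ki67 — conventionally assessed by immunohistochemistry (IHC), with FISH
resolving equivocal HER2 stains. The STRAT4 cartridge assay instead measures
the corresponding mRNAs (*ESR1*, *PGR*, *ERBB2*, *MKI67*) by multiplexed
RT-qPCR, normalised against the *CYFIP1* reference transcript:

```
dCt = Ct(CYFIP1) - Ct(target)        # higher dCt = more target mRNA
```

A sample is called POSITIVE at dCt ≥ cutoff (−1 for *ESR1*/*ERBB2*, −3.5 for
*PGR*, −4 for *MKI67*), INVALID when the reference fails (CYFIP1 Ct > 35 or
no amplification), and INDETERMINATE when a below-cutoff *PGR*/*MKI67*
result coincides with insufficient input (CYFIP1 Ct > 31). This package
implements that call algorithm, the reference-method scoring rules (ER/PR
1%/10% cutoffs, H-score, HER2 reflex FISH at HER2/CEP17 ratio ≥ 2.0, Ki67
10%/20% cutoffs and intermediate zones), and the agreement analysis between
the two:

- 2×2 tables with a full exclusion ledger (`build_table()`);
- PPA = a/(a+c), NPA = d/(b+d), OPA = (a+d)/n with Clopper–Pearson (or
  Wilson) 95% CIs (`agreement_stats()`);
- Cohen's kappa = (po − pe)/(1 − pe) with the Fleiss–Cohen–Everitt
  asymptotic SE (`cohen_kappa()`);
- ROC curves on dCt scores with trapezoidal AUC equal to the Mann–Whitney
  estimate (`roc_dct()`), and dCt cutoff optimisation by maximal overall
  agreement (`optimize_cutoff()`);
- a seeded synthetic cohort generator emulating a 523-specimen FFPE study
  (`simulate_cohort()`), so the entire pipeline is testable without
  patient data.

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Agreement statistics from a published-style 2×2 table (ER at the 1% IHC
cutoff: 407 concordant positives, 4 IHC−/PCR+, 7 IHC+/PCR−, 75 concordant
negatives):

```r
library(strat4concord)
agreement_stats(contingency_table(407, 4, 7, 75))
#> <concordance_report>  [n = 493, clopper_pearson 95% CI]
#>   counts: a=407 b=4 c=7 d=75, excluded=0
#>   PPA   98.3% (96.5%-99.3%)
#>   NPA   94.9% (87.5%-98.6%)
#>   OPA   97.8% (96.0%-98.9%)
#>   KAPPA 91.8% (87.1%-96.6%)
```

PPA 98.3% says the assay finds 98.3% of IHC-positive tumours; OPA 97.8% is
the overall agreement; kappa 91.8% is agreement corrected for chance given
the 84%/16% positive/negative margins.

The full pipeline on a synthetic cohort — generate paired Ct panels, IHC
and FISH observations, call the panel, score the references, and tabulate
all eleven standard analyses:

```r
cohort <- simulate_cohort(cohort_spec(n_samples = 523, seed = 1))
run <- run_concordance(cohort$panels, cohort$ihc, cohort$fish)
run
#> <concordance_run> 11 analyses, clopper_pearson 95% CIs
#>   ESR1 (ER), 1% IHC cutoff             a=398 b=  1 c= 18 d= 85 n=502 | PPA 95.7% NPA 98.8% kappa 87.6% OPA 96.2%
#>   ESR1 (ER), 10% IHC cutoff            a=381 b= 18 c=  0 d=103 n=502 | PPA 100.0% NPA 85.1% kappa 89.7% OPA 96.4%
#>   PGR (PR), 1% IHC cutoff              a=322 b= 39 c= 21 d=108 n=490 | PPA 93.9% NPA 73.5% kappa 69.8% OPA 87.8%
#>   ...
#>   MKI67 (Ki67), 20% IHC cutoff         a=181 b= 75 c= 53 d=172 n=481 | PPA 77.4% NPA 69.6% kappa 46.9% OPA 73.4%
tidy(run)        # one row per analysis, proportions + CIs + exclusion counts
```

Per-analysis exclusions (invalid cartridges, indeterminate calls, HER2 2+
equivocals without FISH, ...) are in `run$reports[[label]]$table$excluded`.
ROC and cutoff search run on the same tidy calls:

```r
scored <- dplyr::inner_join(
  dplyr::filter(run$calls, analyte == "ESR1", status != "INVALID", is.finite(dct)),
  dplyr::filter(run$reference, rule_id == "er_1pct"),
  by = "sample_id")
roc_dct(scored$dct, scored$status.y)
#> <strat4_roc> AUC = 0.999 (415 positive, 87 negative, 497 thresholds)
optimize_cutoff(scored$dct, scored$status.y)
#> # A tibble: 1 × 4
#>   cutoff   opa   ppa   npa
#>    <dbl> <dbl> <dbl> <dbl>
#> 1  -2.35 0.970 0.990 0.874
```

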