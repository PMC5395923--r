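# freekappa

Agreement beyond chance for free-response assessments.

## The problem

In many diagnostic settings — whole-body MRI, metastasis screening, plaque
counting — raters report only the **positive** findings they see.  Nobody
enumerates the negatives: the universe of anatomical sites that *could* have
held a lesion is effectively unbounded.  Cohen's kappa,

    K = (P_o − P_e) / (1 − P_e),

needs the full 2×2 table of two raters' calls, including the
double-negative cell `a`, so it cannot be computed for such *free-response*
data.  Substituting `a = 0` badly understates agreement, and collapsing the
image into a finite grid of regions of interest (ROIs) overstates it,
because disagreements finer than the grid vanish.

`freekappa` implements the statistic that resolves this: as `a → ∞`,
Cohen's kappa increases monotonically to a finite limit that depends only
on the observable counts — `b` and `c` discordant findings (seen by one
rater only) and `d` concordant positives:

    K_FR = 2d / (b + c + 2d),

the proportion of confirmed positive individual ratings among all positive
individual ratings made by the two raters.  It is also a monotone transform
`K_FR = 2p/(1+p)` of the binomial proportion `p = d/(b+c+d)` of congruent
pairs, which gives direct access to standard binomial interval methods.

The package provides:

- point estimation (`free_response_kappa`, `cohen_kappa`, `kappa_curve`)
  and the exact weighted decomposition of the pooled estimate over patients
  (`cluster_decomposition`, weights `ν_k = (b_k + c_k + 2d_k)/(b + c + 2d)`);
- confidence intervals for independent findings via the logit delta method
  (`Var(logit K_FR) = (b+c+d)/((b+c)d)`), Agresti–Coull and Clopper–Pearson
  (`logit_delta_ci`, `agresti_coull_ci`, `clopper_pearson_ci`), and a
  patient-resampling bootstrap for clustered data (`cluster_bootstrap_ci`);
- a Monte-Carlo engine for studying interval coverage (`run_cell`,
  `run_table`);
- a generative model of clustered rating studies (`study_model`,
  `generate_study`) and the embedded MRI case study
  (`case_study_fixtures`);
- CSV input/output (`read_findings`, `write_findings`) and a command-line
  interface (`inst/cli/freekappa`).

## Worked example

The embedded case study: 84 children underwent full-body MRI, two blinded
radiologists reported all lesions, and a third matched the reports,
yielding 249 distinct lesions (19 seen by rater 2 only, 57 by rater 1 only,
173 by both).

```r
library(freekappa)

counts <- positive_counts(b = 19, c = 57, d = 173)
free_response_kappa(counts)
#> [1] 0.8199052
logit_delta_ci(counts)
#> free-response kappa: 0.820  (95% CI 0.777 to 0.856, logit delta, n = 249)
clopper_pearson_ci(counts)
#> free-response kappa: 0.820  (95% CI 0.776 to 0.858, clopper pearson, n = 249)
```

0.820 means 82% of all positive ratings were confirmed by the other rater.
Had we instead *assumed* a finite number of potential lesion sites per
patient, Cohen's kappa would understate this:

```r
kappa_curve(counts, sites_per_patient = c(17, 95), n_patients = 84)
#>   sites_per_patient    a     kappa
#> 1                17 1179 0.7889776
#> 2                95 7731 0.8150547
```

and assuming no double negatives at all gives `cohen_kappa(
contingency_table(0, 19, 57, 173))` = −0.129, agreement seemingly *below*
chance.  Aggregating into ROIs biases the other way: the patient-level
table gives 0.919.

For clustered data (several findings per patient), the bootstrap resamples
whole patients:

```r
m  <- study_model(200, lesion_rate = 3, sens1 = 0.8, sens2 = 0.8, seed = 42)
cl <- generate_study(m)
cluster_bootstrap_ci(cl, replicates = 10000, seed = 42)
#> free-response kappa: 0.808  (95% CI 0.780 to 0.835, cluster bootstrap, n = 10000)
```

Both raters detect each true lesion with probability 0.8, and the interval
brackets that generative agreement level.

The same operations are available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "freekappa", package = "freekappa"))') \
  estimate --input inst/extdata/mri_pooled_counts.csv
#> free-response kappa: 0.820 (0.819905)
```

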