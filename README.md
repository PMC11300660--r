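# betaguide

Statistical signal-to-background discrimination for beta-probe
radioguided surgery.

During receptor-targeted radioguided surgery, a beta-particle probe
reports counts per second (CPS) while held against tissue; the surgeon
must decide, node by node, whether the reading indicates tracer-avid
(tumor-bearing) tissue. Tracer uptake varies so much between patients
and regions that the common practice — declare tissue positive when its
rate exceeds a fixed 1.5x or 2x multiple of a local background — has no
statistical footing. `betaguide` implements a background-referenced
alternative and the machinery to optimize and evaluate it.

## The method

Within a surgical *district* (a region sharing one background
definition), pooled background counts are summarised by a flat model of
their extremes, and the cutoff rate is

    R_cut = (R_max + R_min)/2 + N_sigma * (R_max - R_min)/sqrt(12)

A sample is probe-positive when any of its measurement acquisitions
satisfies either detection condition:

* **fraction**: at least a fraction `eps_frac` of its 1 s counts lies
  strictly above `R_cut`;
* **run**: at least `eps_num` consecutive counts lie above `R_cut`.

The triple `(N_sigma, eps_frac, eps_num)` is optimized by grid search
(18 x 4 x 7 = 504 configurations): for each of the 28
`(eps_frac, eps_num)` pairs a ROC curve is traced by varying `N_sigma`
over its 18 grid values on a training set of districts, and the point
nearest the ideal 100%/100% corner is selected, then evaluated on
held-out test districts and compared against fixed-SBR cutoffs of 1.5
and 2.0. All counts are decay-corrected (default: gallium-68,
half-life 4062.6 s) to each district's background start before any
comparison.

Because no public dataset of intraoperative count streams exists, the
package ships a seeded Poisson count-stream simulator
(`generate_cohort()`) that emulates the clinical data structure
(7 patients, 25 districts, 66 samples, 47% pathology-positive,
5-10 s backgrounds, 5-20 s measurements, 20-152 min post-injection
window with exponential decay).

## Worked example

```r
library(betaguide)
sim <- generate_cohort(cohort_params(seed = 7))
fit <- sbr_fit(sim$cohort, seed = 7)
summary(fit)
```

```
Signal-to-background cutoff algorithm — summary

District split (seed 7): 13 train districts (15 pos / 18 neg samples), 12 test districts (16 pos / 17 neg)
ROC family: 28 curves x 18 points; AUC median 0.986 (IQR 0.983-0.993)
Best configuration: n_sigma = 2.5, eps_frac = 50%, eps_num = 20 (distance to ideal 5.56)

            dataset sensitivity specificity
              train       100.0        94.4
               test       100.0        94.1
              whole       100.0        94.3
 whole (SBR >= 1.5)        96.8       100.0
 whole (SBR >= 2.0)        93.5       100.0

Test confusion: TP=16 TN=16 FP=1 FN=0
```

Reading the output: the 25 districts were split into balanced train and
test halves; on the train half all 504 configurations were scored
against pathology and the 28 ROC curves had median AUC 0.986; the
selected cutoff sits 2.5 flat-model sigmas above the background mean
and requires half of a measurement's counts (or a run of 20) above it;
on the 33 held-out samples it recovered every tumor (sensitivity 100%)
with one false positive (specificity 94.1%). On this synthetic cohort —
whose lesion uplift is generous — the statistical cutoff beats the
fixed SBR 2.0 rule on sensitivity (100% vs 93.5%) at a small cost in
specificity.

`coef(fit)` returns the chosen parameter triple, `predict(fit, newdata)`
classifies a new cohort with it, and `plot(fit)` draws the train ROC
family with the selected point circled.

A command-line wrapper (`inst/exec/betaguide`) exposes the same
pipeline as `simulate`, `classify`, `evaluate`, `optimize` and `report`
subcommands over CSV count/label tables; see `?cli_main`.

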