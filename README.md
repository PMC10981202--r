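# orphanmcda

Multi-criteria decision analysis (MCDA) for orphan-drug value assessment,
built for health-technology-assessment (HTA) committees that must decide
which rare-disease therapies to reimburse. Traditional cost-per-QALY
appraisal undervalues orphan drugs; an MCDA value framework scores each drug
on a broader set of explicit criteria — unmet need, disease rarity and
severity, magnitude of health gain, budget impact, and so on — and combines
them into a single 0–100 score.

The package is a config-driven engine for this class of tool. The
ten-criterion Emirates framework ships as the embedded default; any other
criteria set can be supplied as a YAML/JSON config.

## The model

Each criterion *i* has a **scoring function**: an ordered set of categorical
outcome levels mapped to fractions *x<sub>i</sub>* ∈ [0, 1] (100% for the
best outcome down to 0% for the worst). Criterion **weights** come from SMART
& Swing elicitation: the panel ranks the criteria (ties allowed), then votes
the percentage importance increase *d<sub>i</sub>* of each criterion over the
next-ranked one. Unnormalized weights follow the multiplicative chain upward
from an arbitrary base *b* at the lowest rank,

&nbsp;&nbsp;&nbsp;&nbsp;*w̃<sub>lowest</sub> = b*,&nbsp;&nbsp;
*w̃<sub>g</sub> = w̃<sub>g+1</sub> · (1 + d<sub>g</sub>/100)*,

and are normalized to Σ*w<sub>i</sub>* = 1 (the base cancels). A drug profile
— one selected level per criterion — scores

&nbsp;&nbsp;&nbsp;&nbsp;*S* = 100 · Σ<sub>i</sub> *w<sub>i</sub> x<sub>i</sub>* ∈ [0, 100].

A three-part **concordance validation** checks scored drugs against
predefined expert expectations: side of the 50-point threshold per drug,
rank order, and a minimum spread (default 40 points) between the highest and
lowest comparator, all on one-decimal reported precision.

## Worked example

```r
library(orphanmcda)

cs <- emirates_default()
cs
#> <criteria_set> emirates_orphan_mcda: 10 criteria
#>    1  cost_effectiveness            25.1%
#>    2  magnitude_of_health_gain      20.1%
#>    3  therapeutic_alternative       14.3%
#>    4  disease_severity              11.0%
#>    5  budget_impact                  7.9%
#>    6  disease_rarity                 5.6%
#>    6  clinical_evidence              5.6%
#>    7  household_burden               4.5%
#>    8  indication_uniqueness          3.2%
#>    9  patient_age                    2.6%
```

The printed percentages are the normalized swing weights: cost-effectiveness
carries a quarter of the total decision weight, and the two rank-6 criteria
share one weight. Scoring the four packaged archetype profiles (synthetic
reconstructions of the four validation therapy types — see
`?archetype_profiles`) and checking them against the qualitative
expectations:

```r
cmp <- compare_drugs(archetype_profiles(), cs)
cmp
#> <drug_comparison> 4 drugs
#>   1. genetic_curative         74.3
#>   2. highly_effective_chronic 63.0
#>   3. high_quality_symptomatic 40.0
#>   4. low_quality_symptomatic  12.9

exp <- read_expectations(system.file("extdata", "expectations.yaml",
                                     package = "orphanmcda"))
check_concordance(cmp, exp)
#> <concordance_report>
#>   threshold (50 points): PASS
#>   ...
#>   spread: PASS (observed 61.4, threshold 40.0)
#>   overall: CONCORDANT
```

The two disease-modifying therapies land above 50 points, the two
symptomatic ones below, in the expected rank order, with a 61.4-point spread
between best and worst.

The same steps run from a shell via the thin CLI installed at
`inst/scripts/emirates-mcda` (subcommands `score`, `compare`, `elicit`,
`validate`, `export-default`), e.g.

```sh
Rscript inst/scripts/emirates-mcda compare \
  --profiles inst/extdata/archetype_profiles.csv --report scores.csv
```

## Limitations

The tool emits a value score, not a reimbursement decision: no cutoff
threshold is defined, and rarity/severity classes are the assessor's
categorical selections, not derived from epidemiological data. See the
methods vignette (`vignettes/orphan-mcda-methods.Rmd`) for the model's
assumptions, numerical conventions and design choices.
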