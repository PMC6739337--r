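# repsig

Drug repurposing by compound–proteome interaction-signature similarity,
with consensus ranking, psychoactive-enrichment statistics, randomized
controls, and indication–indication association networks.

## The problem

Given a compound × protein matrix of interaction scores, every compound
owns a proteome-wide *interaction signature*. The working hypothesis of
signature-based ("shotgun") repurposing is that compounds with similar
signatures behave similarly: if an uncharacterized compound's signature
sits close to that of a drug approved for some indication, the compound
is a candidate therapy for that indication. `repsig` implements this
analysis for the question of whether psychoactive compounds
(phenethylamines, tryptamines, cannabinoids and relatives) preferentially
rank as candidates for mental-health indications — and whether that
preference survives comparison with randomized controls. The package is
aimed at computational drug-discovery researchers who have such a matrix
(or want to simulate one) and need the full statistical pipeline around
it.

## The statistics

Signatures are compared by RMSD over the full protein panel:
`RMSD(a,b) = sqrt(mean((a - b)^2))`, smaller = more similar. For an
indication with *k* approved drugs, the TopX nearest neighbours of each
drug are pooled; a candidate's **consensus count** is the number of
approved drugs whose TopX lists contain it (≤ *k*), and
**percent occurrence** = 100 · count / *k*. From the consensus table:

* **normalized indication rank** = 100 · (psychoactive consensus mass) /
  (total consensus mass), per indication;
* **normalized compound rank** = 100 · (consensus mass on mental-health
  indications) / (total consensus mass), per compound.

Observed distributions are contrasted against two Monte-Carlo nulls
(uniform injective relabelling of each indication's predicted compounds
with consistent replacement; permutation of mental-health labels) with
one-tailed Kolmogorov–Smirnov and paired t tests, and indication pairs
sharing ≥ 2 psychoactives above a per-TopX consensus threshold
(2/3/4/6 at Top10/25/40/100) form an association network.

## Worked example

The didactic two-indication fixture: ergoline (psychoactive) is predicted
7 times for Pica (a mental-health indication) and 3 times for Stomach
pain; aspirin (non-psychoactive) 4 and 6 times.

```r
library(repsig)
we <- worked_example()

compound_rank(we$table, we$indications, topx = 10)
#>   compound_id value
#> 1     aspirin    40
#> 2    ergoline    70

indication_rank(we$table, we$compounds, topx = 10)
#>   indication_id    value
#> 1          pica 63.63636
#> 2  stomach-pain 33.33333
```

Ergoline's consensus mass is 70% mental-health (7 of 10), aspirin's 40%;
Pica's candidate mass is 64% psychoactive (7 of 11, rounded half-up from
63.64), Stomach pain's 33%.

An end-to-end run on a synthetic cohort with planted enrichment:

```r
spec <- synthetic_spec(seed = 42)                 # 200 compounds, 40 indications
cfg  <- analysis_config(topx_values = c(10, 25),
                        association_thresholds = c("10" = 2, "25" = 3),
                        n_randomizations = 200, seed = 42)
summary <- run_pipeline(cfg, spec, quiet = TRUE)
summary
#> run_summary (seed 42)
#>   Top10   obs MH ind rank  40.40% (null  12.01%)  obs psy cmp rank  57.71% (null  24.23% /  25.07%)  edges 16
#>   Top25   obs MH ind rank  21.68% (null  12.10%)  obs psy cmp rank  38.98% (null  24.81% /  24.98%)  edges 3

summary$topx[["10"]]$ks_indication_rank
#> ks_one_tailed: statistic = 1, p = 4.54e-05 (n_obs = 10, n_null = 10)
#>   alternative: observed stochastically greater than null
```

Mental-health indications draw 40% of their Top10 consensus mass from
psychoactives versus 12% under compound randomization — the planted
preference, recovered and significant. Narrowing the list (Top10 vs
Top25) sharpens the contrast, as adding lower-ranked candidates dilutes
the psychoactive share.

Real data enter through `load_matrix()` (TSV or Matrix Market),
`load_metadata()` (compound and indication TSVs), and `read_config()`;
`classify_library()` assigns chemical classes from SMILES by scaffold
substructure matching.

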