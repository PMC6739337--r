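---
title: "Consensus signature repurposing: models, controls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus signature repurposing: models, controls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsig)
```

## The model

`repsig` implements a signature-similarity repurposing analysis for
psychoactive compounds. Its premise is the chemoproteomic homology
hypothesis: two compounds whose proteome-wide interaction signatures are
similar are expected to behave similarly in vivo. The signature of a
compound is the real-valued vector of its interaction scores against every
protein in a structural library, one row of the compound-by-protein
interaction matrix; how such a matrix is built (docking, knowledge-based
potentials) is out of scope here — the matrix is an input.

Similarity is the root mean squared deviation over the full protein panel,

$$\mathrm{RMSD}(a, b) \;=\; \sqrt{\tfrac{1}{P}\sum_{p=1}^{P}(a_p - b_p)^2},$$

with no per-protein weighting and no protein-class special-casing. Smaller
is more similar. For each indication with approved drugs
$d_1, \dots, d_k$, the TopX most similar compounds to each $d_i$ are
pooled; a candidate's **consensus count** is the number of approved drugs
whose TopX lists contain it (so at most $k$ — an indication with 65
approved drugs can nominate a candidate at most 65 times), and its
**percent occurrence** is the consensus count divided by $k$, times 100.
Psychoactive compounds never serve as queries — they are barred from
approved-treatment sets at load time — but always remain candidates, so
every psychoactive prediction is anchored to similarity with an approved
non-psychoactive drug.

Two consensus-weighted percentages summarise enrichment:

* **normalized indication rank** — per indication, the share of its total
  consensus mass contributed by psychoactive candidates;
* **normalized compound rank** — per compound, the share of its consensus
  mass falling on mental-health indications.

Both are weighted by consensus counts, not by distinct compounds; the
two-indication worked example (`worked_example()`: ergoline predicted 7
and 3 times for Pica and Stomach pain, aspirin 4 and 6 times) forces this
reading, giving 70%/40% compound ranks and 63.64%/33.33% indication ranks.
Values are carried at full precision and displayed with `round_half_up()`
so 63.64 prints as 64. Entities with zero total consensus mass are
omitted rather than scored 0, since a never-predicted entity carries no
evidence either way.

Mental-health flags arrive precomputed in the indication table (curated
from the MeSH Mental Disorders tree, F03, with the epilepsy subtree
conventionally pooled in); the package does not parse MeSH.

## Randomized controls

Both controls relabel the consensus table; they never re-run prediction,
so consensus-count structure is held fixed and only identities shuffle.

* **Compound shuffle** — per replicate and per indication, the
  indication's distinct predicted compounds are replaced by an injective
  uniform draw from the full library. Replacement is *consistent*: a
  compound's entire consensus count transfers to its single replacement.
  Injectivity (sampling without replacement within an indication) was
  chosen because it preserves the multiset of consensus counts exactly;
  whether the original procedure allowed replacement collisions is not
  documented, so the conservative reading that keeps the count structure
  intact is used.
* **Indication shuffle** — per replicate, the mental-health labels are
  permuted across indications (label counts preserved) and compound ranks
  recomputed.

The default is 1000 replicates. Per-replicate values are retained next to
the replicate-averaged per-entity means, because the two views answer
different questions (below).

Under the compound shuffle, each received slot is psychoactive with
probability equal to the library's psychoactive fraction $f$, so the
expected randomized indication rank is exactly $100f$ — a closed form the
test suite checks by exhaustive enumeration on a six-compound library.
Similarly, permuting labels gives every compound an expected randomized
compound rank of $100g$ for mental-health fraction $g$.

## Significance tests

The alternative hypothesis is directional — observed rank values are
stochastically **greater** than the null — so both tests are one-tailed:

* `ks_one_tailed()` uses $D^+ = \sup_x[\hat F_{\text{null}}(x) -
  \hat F_{\text{obs}}(x)]$ with the asymptotic bound
  $p = \exp(-2mnD^{+2}/(m+n))$. The asymptotic form was chosen because
  the production samples are hundreds of indications or compounds; an
  exact permutation enumeration exists in the test suite as an
  independent oracle only.
* `paired_t_one_tailed()` aligns observed and null values entity-wise by
  name and delegates to the Student t machinery
  (`stats::t.test(..., paired = TRUE, alternative = "greater")`).
  Identical pairs give zero-variance differences, which is reported as an
  error rather than a p-value — a degenerate comparison should be
  conspicuous, not silently "non-significant".

Two numerical facts about the asymptotic KS p, established by exhaustive
enumeration and encoded in the tests: for **equal** sample sizes up to 8
its 0.05-level decisions coincide with the exact permutation test for
every achievable value of $D^+$; for **unequal** sizes the bound is
conservative in the rejection tail, so there is a narrow band (exact
$p \le 0.05 <$ asymptotic $p$) where the two disagree. The package's own
comparisons are entity-aligned — the same entities appear in the observed
and mean-null vectors, so $m = n$ — which is why the equal-size regime is
the one verified exhaustively. No multiple-testing correction is applied
across TopX levels; raw p-values are reported.

**Which null values feed the KS test matters.** For *display* and for
effect-size summaries, observed values are compared with the
replicate-averaged null (the mean-null line a figure would show). For
*calibration* — deciding whether enrichment exceeds chance — the observed
sample is compared with the **pooled** per-replicate null values:
averaging over replicates shrinks the null's spread towards its mean, so
an observed-vs-averaged comparison is not distribution-matched even when
no effect exists. `null_values(null, pooled = TRUE)` exposes the pooled
view.

## Association network

Two indications are associated when at least two *distinct* psychoactive
compounds are predicted above the TopX-specific minimum consensus
threshold (2, 3, 4, 6 at Top10, Top25, Top40, Top100) for **both**
indications; the association count is the number of such shared
qualifying psychoactives. The threshold is applied per endpoint — each
indication's consensus count must clear it independently. An
"either-endpoint" reading would also reproduce the canonical
seizures/sleep-disorder example (counts 10/8 and 3/2 at threshold 2,
association count 2) but is strictly weaker and was rejected. Edges
default to mental-health indication pairs, with `mental_health_only =
FALSE` to widen; output is a plain edge list ordered canonically, from
which any chord-diagram tool can draw.

## Scaffold classification

Psychoactives are classified by parent-scaffold substructure matching
(SMARTS, via Open Babel through ChemmineR/ChemmineOB), highest-priority
rule first: cathinone (β-keto-phenethylamine) ≻ amphetamine
(α-methyl-phenethylamine) ≻ cannabinoid (two patterns: the gem-dimethyl
benzochromene core and the alkyl-resorcinol motif) ≻ tryptamine
(3-(2-aminoethyl)indole) ≻ phenethylamine; anything else is "other". The
nesting is deliberate — every cathinone also carries the amphetamine and
phenethylamine scaffolds, and priority resolves the overlap. These
patterns are reconstructions of the standard parent molecules, exposed as
an editable rule table (`default_scaffold_rules()`,
`read_scaffold_rules()`) rather than hard-coded, because scaffold
definitions are a curation choice. Classification operates on molecular
graphs, so it is invariant to how a SMILES is written; single-atom
molecules carry no scaffold and fall to "other"; unparseable strings are
errors naming the input.

## The synthetic cohort

`generate_cohort()` produces the only data the package's end-to-end
claims are tested on, so its construction is worth stating precisely.

* Compounds belong to one of `n_groups` latent groups (hard clustering).
  Group centroids sit at $g \cdot s \cdot \mathbf{b}$ for group index $g$,
  separation scale $s$, and a fixed random direction
  $\mathbf{b} \in [0.8, 1.2]^P$; signatures add i.i.d. Gaussian noise of
  scale `noise_sd`. The default $s = 12.5 \times$ `noise_sd` guarantees a
  minimal between-centroid RMSD of at least $10\times$ the noise scale,
  so "nearest signature ⇒ same group" holds by construction.
* Psychoactive flags concentrate in a subset of groups: groups are
  designated psychoactive-bearing in random order, flagging at most half
  of each (never all members), until the target `psychoactive_fraction`
  is met. Every bearing group thus retains non-psychoactive members — the
  donors through which an indication can "point at" a psychoactive
  neighbourhood. A fraction too high to satisfy this (e.g. 1.0) is an
  infeasibility error, since approved-drug lists must stay
  psychoactive-free. Chemical classes are assigned per bearing group,
  cycling through the six labels.
* Each approved drug of a mental-health indication comes from the
  bearing-group donor pool with probability `enrichment`, otherwise from
  the non-bearing pool; other indications draw uniformly from all
  donors. The non-enriched branch deliberately avoids bearing donors so
  that the probability of a bearing donor is *exactly* `enrichment`,
  making `enrichment = "base"` (the bearing share of the whole donor
  pool) the precise no-effect null rather than an approximation.
* `mh_drugs_per_indication` optionally gives mental-health indications
  larger approved-drug repertoires than the rest. This mirrors real
  drug–indication maps, where mental-health conditions are drug-rich
  (schizophrenia alone has dozens of approved treatments), and it is the
  lever that makes the two nulls genuinely different: both null means
  reduce to mental-health shares weighted by prediction slots
  (compound shuffle) versus by indications (label shuffle), so they
  separate exactly when mental-health indications carry a
  wider prediction footprint.
* All randomness flows from the single integer `seed` through one local
  Mersenne-Twister stream; the same spec is bit-reproducible, and
  `planted_truth()` re-derives the latent structure from the spec alone.

Defaults (200 compounds × 64 proteins, 20 groups, 12% psychoactive, 40
indications of which 25% mental-health, 5 drugs each, enrichment 0.8)
are a desk-scale rendering of the study conditions — the real analysis
ran 3,733 compounds against tens of thousands of proteins with 428
psychoactives (≈11.5%) — chosen so a full pipeline run takes seconds.

What the generator does **not** emulate: the marginal distribution of
real docking scores, soft/overlapping chemical neighbourhoods (real
chemistry is messier than hard clusters), correlated protein columns, and
hub compounds that are near-neighbours of much of the library. Passing
the recovery tests therefore shows the *pipeline arithmetic and
statistics* behave as designed, not that any particular real matrix
carries the enrichment.

## Verification scenarios and problem sizes

The acceptance-style tests in `tests/testthat/test-acceptance.R` run four
simulation studies, with sizes chosen as the package's own benchmark
scale:

* **Calibration.** 200 structureless cohorts (zero centroid separation,
  `enrichment = "base"`, 600 compounds, 24 indications): the one-tailed
  KS at α = 0.05 against the pooled compound-shuffle null should reject
  at the nominal rate (5% ± 4 points). The 600-compound library is
  essential: in small libraries each compound appears in many
  indications' candidate unions, so observed ranks are mutually
  correlated within a dataset and the KS over-rejects (≈14% at 120
  compounds) even though the marginal distributions match.
* **Planted recovery.** 20 default cohorts with `enrichment = 1`: the
  observed mean Top10 indication rank over mental-health indications
  must exceed the compound-shuffle null mean with KS p < 0.01 in ≥ 95%
  of seeds.
* **Two-null separation.** 10 cohorts with `mh_drugs_per_indication = 8`
  versus 3 elsewhere: the compound-shuffle null mean exceeds the
  indication-shuffle null mean, one-tailed paired t at α = 0.01,
  in every seed.
* **Oracle equivalence.** Neighbour ranking against an independent
  double-loop brute force on 200 random matrices up to 20 × 10 including
  tie order (ties broken by case-folded compound id — a reproducibility
  choice, since no canonical tie rule is documented); KS decisions
  against exact permutation enumeration as described above.

## Degenerate inputs and numerical conventions

Reported ranks are 1-based. Identifiers are whitespace-trimmed and
case-folded on ingest, and all joins use the normalized form. Missing
interaction scores are rejected, never imputed — signature distances on
silently imputed rows would be wrong in proportion to the imputation.
Indications with no usable approved drugs error individually and are
skipped with a warning in bulk runs. The query compound is excluded from
its own neighbour list. TSV and Matrix Market readers/writers round-trip
labels and values exactly; Matrix Market uses plain-text sidecar label
files because the format itself carries no row/column names.

## Known limitations

* RMSD is computed on raw scores; whether to centre or rescale
  signatures first is an open question inherited from the platform, and
  raw scores are used here.
* The asymptotic one-sided KS p disagrees with the exact test in a
  narrow band for unequal sample sizes (documented above).
* The default scaffold rules are reconstructions; counts on any real
  psychoactive library will depend on the curated patterns used.
* Benchmarking protocols that require the full deposited matrix
  (leave-one-out recovery of approved drugs across ~1400 indications)
  are not reproduced at desk scale.
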