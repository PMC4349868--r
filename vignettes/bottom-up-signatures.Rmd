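---
title: "Bottom-up discovery of prognostic gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up discovery of prognostic gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Most expression-based prognostic signatures for hepatocellular carcinoma
(HCC) are built *top-down*: genes differentially expressed between tumor
and adjacent non-tumor tissue are winnowed to a regression model. Such
signatures transfer poorly between cohorts. `progsig` implements the
*bottom-up* alternative: genes are first selected for direct association
with patient outcome — survival endpoints and clinical staging systems —
then prioritized by their position in a protein-interaction network and by
pathway membership, and only the small functional core is assembled into a
signature and put through survival evaluation. The same machinery runs on
the top-down differential-expression candidates as a comparator arm.

The pipeline operates on a paired design: tumor and adjacent non-tumor
expression from the same patients. Adjacent tissue carries its own
prognostic information (chronic inflammation, cirrhosis), so the bottom-up
selection runs separately in each tissue, producing two candidate sets
(`ProgGenes` in tumor, `ProgNGenes` in adjacent tissue) next to the DEG
set.

## Candidate selection

**Survival evidence (OS, RFS).** Each gene is tested twice against each
endpoint: a univariate Cox proportional-hazards model (Breslow tie
handling, two-sided Wald p) and supervised principal components (SPCA).
SPCA screens genes by Cox p below `screen_p` (default 0.05), takes the
first principal component of the standardized screened submatrix as a
per-sample score, and rates every gene by the absolute Pearson correlation
of its expression with that score; the top `spca_top` genes (default 2000)
form the SPCA list. A gene is survival evidence only if it is in both the
Cox-significant set and the SPCA list. The screening rule is exposed as an
argument because supervised PC variants differ here; the default reuses
the Cox screen at 0.05.

**Stage evidence (TNM, BCLC, CLIP).** Stage labels are kept as the
clinical strings (`I/II/III`, `0-A/B-C`, `0/1/2-5`) and mapped to ordinal
codes at analysis time. Three-level systems are tested by proportional-odds
logistic regression (the natural "logistic regression" for ordered
outcomes) and the Kruskal–Wallis test; binary BCLC by ordinary logistic
regression and a Welch t-test. A gene counts as stage evidence only when
*both* tests fall below `stage_p` (default 0.05) — the conjunction reading;
the cheap nonparametric test is evaluated first and the regression is only
fitted for genes that pass it, which is exact under the conjunction rule.

**The two-of-five rule.** Genes present in at least two of the five
evidence sets {OS, RFS, TNM, BCLC, CLIP} become candidates, with their
evidence provenance recorded.

**Top-down arm.** Paired differences (tumor − adjacent, log2 scale) are
tested per gene with an empirical-Bayes moderated t: gene variances are
shrunk toward a scaled inverse-chi-square prior estimated from the
log-variance distribution across genes, and the moderated t uses the
augmented degrees of freedom. Selection requires Benjamini–Hochberg
q < 0.05 *and* |mean log2 difference| ≥ 1 (fold change at least 2, the ≥
being inclusive).

## Network prioritization

Interaction edges (STRING-style, confidence in [0, 1]) are restricted to
candidate–candidate pairs with confidence strictly above 0.4, then
validated against the tissue-matched expression: only pairs whose
two-sided Pearson correlation test (t with n − 2 df) gives p < 0.05
survive. Isolated nodes are dropped. On the filtered network each node
gets degree, betweenness centrality (Brandes, normalized by
(n−1)(n−2)/2) and closeness centrality. Closeness uses the
within-component convention — (component size − 1) divided by the sum of
distances to same-component nodes, zero for singletons — matching the
common network-analysis tooling; harmonic closeness would handle
fragmented graphs more gracefully but is not the default convention here.
Each metric is ranked descending (average ranks on ties) and the composite
rank score is

> RS = (Rank_degree + Rank_BC + Rank_CC) / 3,

lower = more central. Any positive scaling of the rank sum gives the same
ordering, so top-fraction selection is insensitive to the "average"
reading. The core is the top 5% of nodes by RS (k = ⌈0.05 · N⌉, boundary
ties included, making selection deterministic and order-independent).

## Pathway integration

Candidates are tested for over-representation in each categorized gene set
by the exact hypergeometric upper tail against the measured gene universe
(not the genome — background choice matters and the array universe is the
defensible one), with BH correction across sets; a set is enriched at
q < 0.001. Each enriched pathway is then intersected with the network
core: a second hypergeometric asks whether the pathway's candidate members
are over-represented among core genes (background = candidates). Pathways
with p < 0.05 contribute their `pathway ∩ candidates ∩ core` genes — the
most restrictive reading of "significant genes"; the integration threshold
is a configurable default because no canonical value exists. Significant
genes from pathways of the same main category (six KEGG-style categories)
merge into one functional cluster; pathways tagged `immune` or `cancer`
additionally feed special clusters, mirroring the practice of singling out
immune- and cancer-related gene groups.

## Signature evaluation

Each cluster is evaluated by two independent patient classifiers against
overall survival:

* **LOOCV-Cox.** For each patient in turn, a multivariate Cox model
  (Breslow ties; per-gene standardization computed on the training fold
  only, to avoid leakage) is fitted to the rest; the left-out patient is
  "poor" iff their linear predictor exceeds the training mean (ties go to
  "good" — deterministic). If the unpenalized fit diverges the model is
  refit with a small ridge penalty (1e-3) by Newton–Raphson on the
  penalized Breslow partial likelihood. Folds without events are skipped;
  more than 10% skipped folds invalidates the evaluation.
* **Ward clustering.** Genes are z-scored, patients clustered by Ward's
  minimum-variance method (Ward.D2 on Euclidean distances) and the tree
  cut at two groups.

Both partitions are scored by the two-group log-rank test (two-sided). A
cluster is `significant` when both p-values are below 0.05, a `tendency`
when both are below 0.1, and `fail` otherwise — requiring agreement of the
supervised and unsupervised classifiers. Clusters that do not fail are
merged (deduplicated union) into the arm's combined signature, which is
re-evaluated with the same machinery. Validation cohorts are evaluated by
refitting the LOOCV within the cohort, not by transferring coefficients.

## Drug repositioning

Signature genes are flagged against a drug–target table (DrugBank/TTD
style). Enrichment of druggable targets is the hypergeometric upper tail
against a protein-coding genome background of 19027 genes with 3421
druggable targets (≈ 18%); both constants are version-dependent snapshots
and overridable. The packaged `drug_target_fixture()` carries the 41
approved-drug records (40 unique drugs, 11 targets) behind the two
bottom-up HCC signatures; `druggable_proximity()` reports, for each
non-druggable signature gene, adjacency to a druggable neighbour in the
signature subnetwork — deliberately no novel statistic.

## The synthetic cohort generator

`simulate_study()` produces every input the pipeline consumes, plus ground
truth. Key choices, with defaults:

* **Cohort scale.** 200 patients, 2000 genes — large enough for the
  pipeline's asymptotics, small enough that a full run takes seconds.
* **Expression.** log2 values = per-gene baseline N(7, 1.5²) + planted
  tumor shift (1.5 log2 units on 100 DEGs) + 1.0 × a standardized
  component. The standardized component carries *latent co-expression*:
  the 30 tumor-prognostic genes share a factor (correlation 0.3), the 30
  adjacent-prognostic genes another (in the adjacent matrix), the DEGs a
  tumor-intrinsic factor, and every other gene loads on one of three broad
  background programs (correlation 0.15). Co-expression of outcome genes
  is not cosmetic: supervised principal components can only concentrate
  importance on outcome genes if they share a component, and the
  correlation filter can only validate true interactions if interacting
  genes co-express. Fully independent genes would silently disable both
  stages.
* **Survival.** OS is exponential with rate 0.02/month ×
  exp(Σ β z) over the standardized planted genes (β = 0.3 per gene;
  adjacent-prognostic genes contribute through the adjacent matrix). RFS
  is the latent OS time scaled by Uniform(0.3, 1). Both endpoints censor
  at independent Uniform(0, 120) months. A consequence worth knowing: OS
  and RFS ranks are strongly coupled by construction, so their per-gene
  tests are nearly duplicated and the two-of-five rule admits a
  non-trivial fraction of null genes — candidate sets are enriched for
  truth but not pure, as in real cohorts.
* **Stages.** A latent score (standardized sum of 20 stage genes, half of
  them tumor-prognostic so stage- and survival-evidence overlap) plus a
  fresh N(0, 1) per staging system; TNM and CLIP cut at tertiles, BCLC at
  the median. The per-system noise keeps the three systems correlated but
  not identical.
* **Network.** Barabási–Albert backbone with 20 edges per arriving node,
  plus a clique over a random half of each planted group (the "modules",
  recorded as ground-truth hubs). The attachment density is chosen so that
  candidate-restricted, correlation-filtered subnetworks keep the majority
  of candidates connected, the regime the method expects of STRING-derived
  networks (whose average degree at confidence > 0.4 is far higher still);
  with a sparse backbone the filtered candidate graph collapses to a
  handful of nodes and topological prioritization has nothing to rank.
  Edge confidences are Uniform(0.2, 1), so a quarter fail the 0.4 filter.
* **Gene sets.** 50 sets, sizes 10–60, categories cycling through the six
  main categories; 20% are enriched, drawing half their members from a
  planted module (round-robin across the three groups) — pathways and
  interaction modules describe the same processes, so they are planted
  coherently. One enriched set is tagged `immune`, one `cancer`.
* **Druggability.** Each gene is annotated with probability 0.18,
  matching the druggable fraction of the coding genome; 1–3 fabricated
  approved-drug records with non-liver indications per druggable gene.
* **Reproducibility.** One global seed drives a fixed per-component seed
  sequence, so cohort, network, gene sets and drug table are each
  independently reproducible; `simulate_cohort(config, truth = ...)`
  redraws patients while keeping the planted structure — a held-out
  validation cohort.

**What the generator does not emulate:** probe-level noise, batch
effects, missing clinical covariates, copy-number or mutation structure,
and the heavy-tailed degree mixing of real PPI networks. Passing tests on
synthetic cohorts therefore demonstrate that the implementation recovers
planted structure under the model's own assumptions — not that the
biological conclusions of any particular cohort replicate.

## Numerical and degenerate-input choices

* Cox fits flag monotone-likelihood divergence (|β| > 20) as
  non-converged; such genes are excluded from evidence sets.
* Constant genes are excluded from all per-gene tests with a logged
  count; constant expression on an edge endpoint drops the edge (the
  correlation is undefined).
* A single screened gene is a legal SPCA input (PC1 is then that gene's
  standardized profile and its importance is 1); zero screened genes is an
  error.
* `NA` inside numeric matrices is rejected at parse time rather than
  coerced; missing values in clinical tables are empty strings.
* Patients whose predicted LOOCV risk ties the training mean go to
  "good"; Ward's "poor" label goes to the cluster with the higher event
  rate (labelling does not affect the log-rank statistic).
* Rank ties use average ranks; top-k boundary ties are included, so core
  selection never depends on sort order.

## Simulation sizes used by the test suite

The packaged checks run at the scale the defaults describe: calibration
suites use 1000 log-rank replicates at n = 100 per group and 100 null
cohorts of 80 patients × 40 genes (cluster evaluation only ever touches a
handful of genes, so the null behaviour is independent of the universe
size); recovery suites use ten full 200 × 2000 cohorts. These sizes are
the package's choice of a statistically informative yet routinely runnable
regime.

## Known limitations

* The composite rank score averages degree, betweenness and closeness
  ranks. In fragmented filtered networks, small components inflate
  within-component closeness (an isolated dyad has closeness 1), which can
  push globally peripheral nodes into the core; on densely planted
  synthetic modules the core is recovered reliably, but the statistic is
  known to be less selective when the filtered network breaks into many
  fragments.
* The two-of-five rule inherits the OS/RFS coupling noted above; its
  false-discovery proportion against planted truth is typically above one
  half even when recovery is complete. Downstream network and pathway
  stages are what purify the candidate pool.
* The moderated paired t assumes exchangeable gene variances around a
  common prior; strong variance structure (e.g. intensity dependence) is
  not modelled.
* Proportional-odds fits occasionally fail to converge for near-separable
  genes; such genes are dropped from that evidence set rather than
  imputed.
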