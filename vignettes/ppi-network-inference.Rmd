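---
title: "Predicting a protein interactome by naive Bayes evidence integration"
author: "ppibayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting a protein interactome by naive Bayes evidence integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppibayes)
```

## The problem

No single source of evidence identifies protein–protein interactions (PPI)
reliably at genome scale. High-throughput experiments disagree wildly between
platforms and labs, and each computational signal — interologs transferred
from model organisms, coexpression, shared protein domains, genome-context
patterns — has its own bias and limited coverage. The classical remedy,
applied to yeast, human, and plant interactomes alike, is probabilistic
integration: calibrate every evidence type against a common gold standard,
express each as a likelihood ratio, and combine the ratios under a naive
Bayes independence assumption.

`ppibayes` implements that framework end to end for a query proteome
(Arabidopsis-style AGI identifiers in the motivating use case, but the code
is organism-agnostic): gold-standard construction, seven evidence layers,
likelihood-ratio calibration, a two-stage gated combination, confidence
tiering, and downstream guilt-by-association annotation of function-unknown
proteins.

## The model

For a pair of proteins, let `pos` denote "the pair interacts". With prior
odds

$$O_\mathrm{prior} = \frac{P(\mathrm{pos})}{P(\mathrm{neg})},$$

each evidence value $f_i$ contributes a likelihood ratio
$LR_i = P(f_i \mid \mathrm{pos}) / P(f_i \mid \mathrm{neg})$, and under
conditional independence the posterior odds are

$$O_\mathrm{post} = O_\mathrm{prior} \prod_i LR_i .$$

The class-conditional distributions are estimated from a gold standard
positive set (GSP) and a gold standard negative set (GSN) by binned counting
with a per-bin pseudocount $c$ (default 0.5, a Jeffreys-style smoothing that
keeps every ratio finite and positive):

$$LR(\mathrm{bin}) =
  \frac{(n^+_\mathrm{bin} + c)/(N^+ + cB)}
       {(n^-_\mathrm{bin} + c)/(N^- + cB)}.$$

Setting `pseudocount = 0` recovers the raw counting ratio exactly;
zero-count bins then produce degenerate ratios and a warning.

### Gold standards

* **GSP** — curated interaction pairs (literature-curated and database
  exports are accepted as plain pair lists) united with a bounded
  *enzyme-complex expansion*: complexes with strictly fewer than 18 members
  contribute all their unordered member pairs, larger complexes contribute
  nothing. The bound reflects the observation that subunits of very large
  assemblies rarely all touch; it is a configuration parameter
  (`max_complex_size`, exclusive).
* **GSN** — pairs whose proteins have *disjoint subcellular localization*:
  both proteins must carry at least one cellular-component GO annotation
  with a high-confidence evidence code (default `IC`, `IDA`, `IPI`) and
  their CC term sets must not intersect. Disjointness is tested on the
  directly annotated terms by default. We deliberately do **not**
  ancestor-propagate here: after propagation every annotated protein shares
  the CC root, so a propagated test (available as `propagate = TRUE`, which
  excludes root terms) is far more conservative and can empty the GSN.
* **Reconciliation** — pairs appearing in both sets are removed from both
  and reported (`removed_overlap`), so training sets are disjoint by
  construction.

### The seven evidence layers

| layer | signal | type |
|---|---|---|
| `ortholog` | interolog transfer of a model-organism interactome through an ortholog map; one layer per source organism | flag |
| `coexpression` | Pearson correlation of expression profiles | score |
| `domain` | some domain pair across the two proteins is a known domain–domain interaction (homotypic pairs allowed) | gate |
| `ssbp` | smallest shared biological process: the propagated member count of the smallest GO BP term annotating both proteins | score |
| `gene_neighbor` | orthologs adjacent (gap ≤ 5 kb) on the same contig in ≥ 2 reference genomes | flag |
| `gene_fusion` | hits of both proteins on one target protein with interval overlap below 20% of the shorter hit | flag |
| `phylo_profile` | fraction of matching presence/absence bits across ≥ 4 reference genomes (mutual information available by flag) | score |

Scores for continuous layers are discretized against the gold standard by a
best-first entropy-gain splitter (`supervised_discretize`), a CART-style
stand-in for decision-tree discretization; exact reproduction of a
particular tree learner's pruning heuristics is out of scope. SSBP uses
ancestor-propagated annotation both for "shared term" and for term size —
unpropagated counts would make most specific terms size 1 and the score
degenerate. Pairs outside a layer's coverage are *evidence absent* and
contribute a factor of 1 at integration, never a score of 0.

### Two-stage combination

The four functional-linkage signals (gene neighbor, gene fusion,
phylogenetic profile, SSBP) all reflect shared function and partially shared
sequence information rather than physical contact, so they are not
multiplied. Instead:

1. `lr_functional` = the **maximum** LR among those present, admitted only
   when the pair has **domain support** (the domain gate); otherwise 1.
2. `lr_total` = (best ortholog LR across source organisms) ×
   (coexpression LR) × `lr_functional` — three groups treated as
   independent.

The domain layer is a boolean gate by default, not a multiplied LR, because
its information largely overlaps the functional-linkage group. Coexpression
is binned and calibrated like any other score; a compatibility flag
(`raw_r_as_lr`) uses the raw correlation directly as an LR (clamped below at
1e−6), which is statistically improper and off by default.

### Tiers

With posterior odds 1 as the generally accepted decision point, the
high-confidence cutoff is `1 / prior_odds`; the medium cutoff is the
smallest per-organism ortholog LR (interologs being the most trustworthy
single evidence), clamped to the high cutoff when it exceeds it. Tier
boundaries are inclusive at the lower edge. Pairs covered by no evidence
layer are excluded from the network entirely.

Two numerical points deserve mention. First, the prior odds is a required
input: with `prior_odds = "auto"` the pipeline uses
$|GSP| / (|\mathrm{universe}| - |GSP|)$, the definition above with the GSP
as the estimate of the interacting fraction. Second, the auto high cutoff is
computed as a *ulp-corrected reciprocal*: the floating-point reciprocal
`1/p` is adjusted by up to two units in the last place so that
`cutoff * prior_odds == 1` holds bit-exactly whenever any representable
double satisfies it (for a small fraction of doubles none does; the plain
reciprocal misses the identity for roughly one in seven).

## Guilt-by-association annotation

Function-unknown proteins are annotated over the high+medium network (the
tier set is configurable; the high and medium tiers are annotated jointly by
default). Each unknown carries one candidate term from the union of its
neighbors' known terms (global vocabulary for isolated unknowns). The energy
of an assignment is minus the number of network edges whose endpoints share
at least one term — the unweighted guilt-by-association form; an
edge-weighted variant is a natural extension but the unweighted form is the
default. Simulated annealing with Metropolis acceptance and geometric
cooling minimizes the energy; the best state seen is returned, so the final
energy never exceeds the initial one.

Schedule semantics: `steps_per_t` counts proposals per temperature **per
unknown protein** (sweeps). A raw-step budget would shrink per variable as
instances grow — with the defaults (`t0 = 1`, `alpha = 0.9`,
`steps_per_t = 100`, `t_min = 1e-3`) an 80-unknown instance would see only
~80 proposals per unknown over the entire run and recovery collapses toward
chance; per-sweep counting makes the same schedule meaningful at any size.
The inner loop is compiled (Rcpp) with its own seeded Mersenne-Twister
stream, so runs are reproducible from the seed alone.

Significance: for each (protein, term) call, the observed statistic is the
number of annotated neighbors carrying the term; the null permutes the known
protein→term labels network-wide; the add-one permutation p-value is
$(r+1)/(n+1)$. A call with zero observed support has p = 1 by construction.
The default significance threshold is 0.0517 — an unusual value preserved
deliberately as the framework's legacy default rather than rounded to 0.05.

## Validation analyses

* `map_conservation` — map predicted pairs into a reference organism
  through a reversed ortholog map and look the mapped pairs up in that
  organism's interactome, skipping pairs whose own prediction rests on
  orthology from that organism (no circular validation).
* `hub_degree_report` — compare the mean network degree of pathway hubs
  (proteins in strictly more than `hub_min_pathways` pathways, default 10)
  against all nodes.
* `neighborhood_enrichment` — hypergeometric upper-tail GO enrichment of
  the first-level neighbors of a seed set (seeds excluded by default),
  on ancestor-propagated annotations, with Benjamini–Hochberg q-values.

## The synthetic world

`generate_world()` produces a fully self-contained test bed with planted
ground truth: a planted-partition interactome (modules of functionally
related proteins; default 300 proteins in 10 modules, within-module edge
probability 0.25, between 0.003), and *raw input tables* for every layer, so
the very same readers and scoring functions that process real exports run on
synthetic data:

* boolean layers (ortholog sources, domain, fusion, neighbor) flag true
  pairs with probability `tpr` and non-pairs with `fpr`, conditionally
  independent given pair status — exactly the naive Bayes assumption, so
  the integration's statistical contract is testable in-model;
* expression vectors are module latent profiles plus Gaussian noise
  (sd 0.5 over 20 samples), phylogenetic profiles are module bit patterns
  with 10% per-bit flips — their signal is module-level, which realistically
  confounds coexpression with shared function rather than direct contact;
* GO annotations give each protein its module's BP term (withheld for a
  10% function-unknown fraction) and a compartment CC term, from which the
  GSN is built; small planted complexes are cliques in the truth, one
  oversized 20-member complex exercises the expansion bound;
* gold positives are a seeded sample of true pairs (50%), negatives a
  seeded sample of compartment-disjoint non-pairs (10 per positive).

What the world does **not** emulate: realistic GO DAG depth (two levels
only), Arabidopsis-scale protein counts and term distributions, dependent
evidence layers (a dependence switch would correlate two layers; the default
is independence), or assay-specific noise structure. Green tests therefore
demonstrate the statistical and algorithmic correctness of the machinery
under its own assumptions, not performance on any real proteome.

Default problem sizes were chosen so the full suite exercises genome-like
structure while staying interactive: the end-to-end world scores all 44,850
pairs of 300 proteins; calibration uses 10,000 pairs; annotation recovery
masks 30% of module annotations and tests 499 permutations; the annealing
battery covers ten connected graphs on ≤ 6 nodes with exhaustive
ground-state verification.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(workdir = "run1", seed = 42)
res <- run_pipeline(cfg)
res$network              # tiered pair table
res$report$integrate     # prior odds, cutoffs, per-organism LR tables
res$annotations          # guilt-by-association calls with permutation p
```

On real data, disable simulation and point the config at your exports:

```{r real, eval = FALSE}
cfg <- default_config(workdir = "run2", seed = 1, simulate = FALSE)
cfg$inputs <- list(
  curated = "curated_pairs.tsv", complexes = "complexes.tsv",
  annotations = "go_annotations.tsv", obo = "go.obo",
  expression = "expression.tsv", profiles = "phylo_profiles.tsv",
  domains = "protein_domains.tsv", ddi = "ddi.tsv",
  fusion_hits = "fusion_hits.tsv", context = "gene_context.tsv",
  organisms = list(
    yeast = list(ppi = "ppi_yeast.tsv", orthologs = "orth_yeast.tsv")))
run_pipeline(cfg)
```

## Known limitations

* The naive Bayes product is only calibrated when layers are conditionally
  independent given interaction status; correlated layers inflate posterior
  odds. The two-stage max-combination mitigates, but does not test,
  dependence among the functional-linkage signals.
* The GSN's localization-disjointness makes negatives easier than random
  non-interacting pairs; learned LRs are correspondingly optimistic, which
  is inherent to this gold-standard design.
* Identifier mapping between naming systems is accepted as input tables;
  no mapping service is provided.
* Self-interactions are excluded everywhere; the pair canonicalization has
  no representation for them.
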