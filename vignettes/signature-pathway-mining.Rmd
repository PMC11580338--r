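---
title: "Mining signature pathways from species co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining signature pathways from species co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocsig)
```

## The problem

Individual gut-microbial species are notoriously irreproducible markers of
disease: the species detected in one cohort rarely replicate in another,
even for well-studied conditions such as the inflammatory bowel diseases
(Crohn's disease, CD, and ulcerative colitis, UC). Communities of
co-occurring species, however, tend to carry conserved *functional*
capacity — different taxa in different cohorts can contribute the same
metabolic pathways. `coocsig` operationalizes this idea: it finds groups
of species that co-occur more often than chance within a phenotype, maps
them to the KEGG Orthologs (KOs) they encode, asks which KEGG pathways
those KO sets over-represent, and keeps only the pathways that are
(i) unique to the disease phenotype relative to controls and
(ii) replicated across independent datasets.

## The model

### Presence/absence and the exact pair test

After the filter cascade (below), relative abundances are binarized:
a species is *present* in a sample iff its abundance is strictly positive.
For two species with occupancy counts $N_1$ and $N_2$ among $N$ samples of
one phenotype, the number of jointly occupied samples $j$ under
independent placement follows the hypergeometric law

$$P(j) = \frac{\binom{N_1}{j}\binom{N-N_1}{N_2-j}}{\binom{N}{N_2}},
\qquad \max(0, N_1+N_2-N) \le j \le \min(N_1, N_2).$$

The package reports $p_{gt} = P(j \ge j_{obs})$ and
$p_{lt} = P(j \le j_{obs})$ (both tails include the observed term, so
$p_{gt} + p_{lt} \ge 1$), plus the expected joint occupancy $N_1 N_2 / N$.
Terms are computed in log space via `lchoose` and the tails renormalized
by the summed mass, keeping at least ten significant digits up to
$N = 10^4$. A pair is a *positive co-occurrence* when $p_{gt} < \alpha$
(strict, default $\alpha = 0.05$, no multiple-testing correction at this
stage). Pairs with expected joint occupancy below 1 are not tested by
default (`expected_threshold = 1`, settable to 0); this mirrors the common
practice of skipping pairs whose expectation is too small for the test to
be meaningful, and the setting is echoed in the run report because
conventions differ. The unweighted co-occurrence network has the
significant positive pairs as edges; species without any significant edge
do not enter the network.

### Three granularity levels

* **Global** — the full node set of a phenotype's network.
* **Community** — Leiden partitions under the Constant Potts Model,
  $Q = \sum_c \left[e_c - \gamma \binom{n_c}{2}\right]$, with the
  resolution $\gamma$ derived from the network itself as the first
  quartile of node degree divided by $n - 1$ (both the quartile
  probability and the denominator are configurable, since "the quartile
  of node strength over the node count" admits several readings; on these
  unweighted graphs strength equals degree and linear-interpolation
  quantiles are used). Only clusters with at least 2 species are carried
  into enrichment — singletons hold no co-occurrence signal.
* **Central nodes** — the top 5 species by hub score and, separately, by
  betweenness centrality. Hub scores are eigenvector centrality
  (identical to Kleinberg hub scores on undirected graphs), computed per
  connected component by exact symmetric eigendecomposition and globally
  max-normalized to 1; computing per component avoids the dominant
  component zeroing out all others. Betweenness is unnormalized
  shortest-path betweenness with each unordered pair counted once. Ties
  in top-$k$ selection break by ascending species name; $k$ is
  configurable.

Because a single Leiden pass can stall in a local optimum of the CPM
landscape (observed on roughly a tenth of small random graphs when checked
against exhaustive search), `leiden_cpm()` restarts the algorithm 10 times
from consecutive seeds and keeps the partition with the best CPM value;
the reported quality is always recomputed from the returned assignment, so
it is exactly the edge-count CPM objective above. The whole procedure is
deterministic given its seed.

### Enrichment and signatures

A species *contributes* a KO when its stratified abundance for that KO is
positive in at least one sample of the phenotype (presence, not
magnitude — a single-sample detection threshold is the package default
and adjustable). For a query of $n$ KOs against a pathway of $K$ KOs in a
universe of $M$, the enrichment p-value is the upper hypergeometric tail
$P(X \ge k)$ at the observed overlap $k$, computed with `phyper`;
Benjamini–Hochberg adjustment runs across the pathways with at least one
hit. The universe defaults to all annotated KOs; an `"observed"` mode
restricts it to KOs actually seen in the dataset's profile. Significance
calls use the adjusted p-value at 0.05 by default (the raw-p mode is
provided because published practice is often ambiguous about which scale
"significant at 0.05" refers to).

Per dataset and level, the disease pathway pool minus the control pool
gives the disease-unique set; intersecting those sets across datasets
gives the robust signature. At the community level the pools are unions
over clusters, and control subtraction at that level is configurable
(`subtract_control_community = FALSE` falls back to pure cross-dataset
consistency) because the subtraction mechanics for cluster-level pools are
a genuine design choice rather than an established convention; the
default subtracts, which is the more conservative call. For every robust
community pathway the report records each contributing cluster's id,
total species count and the number of member species carrying at least
one of the pathway's KOs, and per-species KO counts are rendered as
`"k/K"` strings together with the joint coverage
$|\bigcup_s (\text{KOs}_s \cap \text{pathway})|$ — which shows when a
pathway is covered by the community collectively rather than by any
single species. Node-set Jaccard indices between datasets quantify how
little the species themselves overlap even when the pathway signal
replicates.

## The filter cascade

Order is fixed and idempotent: (1) metadata selection — duplicate sample
ids dropped (first kept), medicated samples excluded, age restricted to
the inclusive window [18, 65] (the bounds stay in: exclusion applies to
those strictly younger/older), and for longitudinal cohorts only each
subject's first visit; (2) kingdom exclusion (archaea and eukaryotes by
default, reflecting their low prevalence in stool metagenomes — viral
taxa are retained unless listed); (3) zero-prevalence removal across all
phenotypes jointly; (4) removal of samples with zero Shannon diversity
($H = -\sum p_i \ln p_i$, natural log, all-zero vectors defined as
$H = 0$ so empty samples fall under the same rule), followed by one more
prevalence sweep so the cascade is a fixpoint; (5) per-phenotype
binarization. Each stage's sample and species counts are recorded in the
run report.

## The synthetic-data generator

Real cohorts for this analysis require profiling raw sequence archives
and a live pathway annotation, so the package ships a generator that
emulates the *statistical shape* of those inputs: two (configurable)
datasets, three phenotypes of 30 samples, 60 background species present
independently at occupancy 0.25, and one planted 5-species block per
disease phenotype. Block co-presence uses a shared latent per-sample
Bernoulli($q$) indicator with independent 0.9 retention per species, so
blocks are strong but not degenerate identical rows; block species occur
at a 0.05 baseline elsewhere. The default $q = 0.65$ places block
occupancy near 55–60% of samples — the regime where a presence/absence
test is most informative; at near-saturating occupancy the hypergeometric
null itself expects almost-complete overlap and no test can flag the
block. A planted 12-KO pathway is split over each block in disjoint
slices (3/3/2/2/2), so no single species carries it — the signature is
recoverable only as a community property. Thirty background pathways of
20 KOs each are drawn from a 600-KO pool shared by all species (5
background KOs per species). Present-species abundances are log-uniform
in $[10^{-4}, 10]$ percent; only positivity matters downstream. Background
species names are shared between datasets while block species are
dataset-specific, reproducing the empirical pattern of low species-level
overlap (node Jaccard well below 1) with a conserved pathway signal.

What the generator does *not* emulate: compositional constraints,
correlated abundance structure, sequencing noise, strain-level
heterogeneity, or realistic KO repertoire sizes. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers planted
co-occurrence/pathway structure of realistic strength at realistic sample
sizes — not that it is robust to every artefact of real metagenomes.

```{r end-to-end}
cfg <- simulation_config(seed = 7)
sims <- lapply(1:2, simulate_dataset, config = cfg)
run <- run_all(run_config(sims))
run
planted_truth(cfg)$pathway_id
```

## Numerical and degenerate-input choices

* Pair tails: log-space evaluation, renormalized by total mass; the
  feasible range is validated and an infeasible `j_obs` is an error.
* Degenerate pair supports ($N_1 = N$, never co-present species, empty
  tails) fall out of the same formula; `p_gt = 1` whenever the observed
  count sits at the bottom of the feasible range.
* Empty networks are valid (no significant pair): downstream stages emit
  empty tables rather than failing.
* An all-zero abundance vector has Shannon index 0 by definition,
  avoiding 0/0, and is excluded by the zero-diversity rule.
* Relative abundances are accepted on the 0–100 or 0–1 scale without
  rescaling; only the `> 0` predicate is used.
* Cluster ids are relabelled to contiguous integers in order of first
  appearance, making partitions comparable across runs.
* All randomized steps (simulation, Leiden) are seeded; a run with the
  same configuration and seed is byte-identical, and the run report
  echoes every seed and threshold.

## Problem sizes used by the test suite

The validation suite checks the pair test against exact enumeration for
every feasible configuration up to $N = 12$, enrichment against draw
enumeration for every universe up to $M = 15$, Leiden against
exhaustive-search CPM optima on 100 random graphs of up to 8 nodes,
betweenness against a path-enumeration oracle on graphs of up to 30
nodes, and planted-signature recovery on 100 simulated dataset pairs at
the default conditions above. These sizes make the oracles exact and the
suite quick while covering the combinatorial edge cases (degenerate
supports, disconnected graphs, empty results).

## Known limitations

* The pair test conditions on occupancy counts and loses power as
  occupancy approaches 0 or $N$; ubiquitous species cannot be flagged as
  co-occurring from presence/absence data alone.
* No negative-co-occurrence network is built ($p_{lt}$ is reported in the
  pair table for completeness).
* The enrichment universe is only as good as the supplied annotation;
  KOs absent from it are silently outside the test.
* Cross-dataset robustness is a set intersection, not a meta-analysis:
  no p-value combination or reproducibility statistic is attempted.
* Community detection depends on the resolution heuristic; the
  degree-quartile rule is one defensible reading of common practice and
  is deliberately configurable and reported.
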