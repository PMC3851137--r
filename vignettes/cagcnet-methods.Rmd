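---
title: "Anti-coexpression networks, conserved clusters and drug repositioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-coexpression networks, conserved clusters and drug repositioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagcnet)
```

## The model

`cagcnet` is built around one structural hypothesis: genes whose expression
profiles are consistently *anti-correlated* with a gene *g*, in more than
one species, form a functional module that opposes *g* — so inhibiting *g*
pharmacologically should upregulate them. The pipeline operationalizes this
in four layers.

**Single-species anti-coexpression networks (SANs).** All probeset pairs
are Pearson-correlated on pairwise-complete samples. A directed edge
`p1 → p2` is called when `r(p1, p2)` lies among the `k` most negative
entries of column `p2`, with `k = max(1, floor(f · (N − 1)))` for an
anti-correlation fraction `f`; an undirected edge requires the call in both
directions. Reciprocity is the key noise filter: a probeset with a heavy
negative tail drags in many partners column-wise, but few of those
reciprocate. The probeset network is then collapsed to genes (edge between
distinct genes when any probeset edge spans them).

**Conservation.** A species-A gene edge survives only when both endpoints
have one-to-one orthologs whose counterparts are connected in the species-B
network. This triple condition means the conserved edge set is always a
subset of the species-A edge set; conservation can only remove edges.
Conserved networks from any number of dataset pairs (tissue-specific or
general compendia) are merged by union of nodes and edges. The cluster of a
gene — its CAGC — is its exact neighbour set in the merged network, centre
excluded.

**Validation by enrichment.** The functional index of a cluster is the
minimum one-sided hypergeometric upper-tail p-value over an annotation
collection. Coherence of the real network is read from the comparison of
the index distribution against node-label-permuted replicates of the same
network (topology and degree sequence preserved exactly) with a two-sample
Kolmogorov–Smirnov test. Both the pooled KS and a per-replicate empirical
CDF band (mean ± sd across replicates) are reported, since either summary
of the permuted ensemble can be of interest.

**Repositioning and direction.** Pheno-clusters pool genes of phenotypes
similar at or above a threshold (closed bound; the diagonal similarity of 1
guarantees a phenotype's own genes are always included). Target-centred
CAGCs are tested against pheno-clusters with the same one-sided Fisher
machinery; the raw p-value cut (default 1e-4) is the primary filter and
Benjamini–Hochberg q-values over the full tested family are reported
alongside rather than used as a second filter. Direction of effect is
validated on perturbation rank matrices: gene rank is the maximum rank over
a gene's probesets, each targeted cluster is compared with all other
measured genes by a two-sided Mann–Whitney U test (the centre is excluded
from both groups so the target's own perturbation cannot drive the call),
and the up/down call compares the cluster median rank with the *background*
median — not the theoretical mid-rank, because max-collapsing skews the
gene-rank distribution upward and would bias calls toward "up".

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `fraction` | 0.01 | anti-correlation percentile per column; see capacity rule below |
| `min_samples` | 4 | datasets with fewer samples are refused |
| `min_overlap` | 4 | complete sample pairs below which a correlation is undefined |
| `sim_threshold` | 0.4 | phenotype similarity bound (closed) for pheno-clusters |
| `p_threshold` | 1e-4 | raw Fisher cut for drug–phenotype association |
| `fdr` | 0.05 | BH level for the perturbation significance tally |
| `permutations` | 100 | null-network replicates for the index comparison |

**The capacity rule for `fraction`.** The reciprocal-percentile rule caps
each probeset's possible partner count at `k` per column. At compendium
scale (tens of thousands of probesets) the conventional 1% yields `k` in
the hundreds, far above any cluster size, so the cap never binds. At the
synthetic scales used for testing (hundreds of probesets) a 1% cut gives
`k = 2–5`, and a planted module of 10 members is then *structurally*
unrecoverable regardless of signal strength. `recommended_fraction()`
therefore chooses `f` such that
`k ≥ module_size × max(probesets_per_gene) + 2`, reproducing the
capacity regime of the full-scale analysis. This is an a-priori structural
requirement, not a fitted quantity.

**Sidedness.** Enrichment is tested one-sided (over-representation): an
"enriched" cluster is one with *more* annotated genes than chance. The
perturbation test is two-sided by design — a drug could in principle either
upregulate or downregulate its target's cluster, and the direction is read
off the medians afterwards.

**Universe.** The background for every Fisher test is the merged-network
gene set, used consistently in enrichment and association: the network is
the sampling frame from which clusters arise, so genes outside it can
appear in neither a cluster nor a legitimate overlap.

**Multiple testing families.** BH is applied over all tests actually
performed in a run — all target-centred cluster × pheno-cluster pairs for
association, all cluster × instance tests for perturbation — not per drug
or per cluster, so q-values are comparable across the output. The
Bonferroni divisor in the centre-concordance summary is the number of sets
tested for that cluster.

## Numerical choices

- **Rounding of the percentile:** `k = max(1, floor(f · (N − 1)))`; the
  floor plus minimum keeps small instances usable.
- **Ties at the k-th most negative correlation** are broken by
  lexicographic probeset ID, so runs are bit-reproducible.
- **Only strictly negative correlations** may form anti-correlation edges,
  even when `k` would otherwise reach into non-negative values: an
  "anti-correlation" edge at `r ≥ 0` is semantically wrong.
- **Missing values** are allowed in expression input; correlations use
  pairwise-complete samples and pairs below `min_overlap` are recorded as
  undefined and excluded from edge calling. Zero-variance probesets are
  flagged at construction and never enter correlation.
- **Mann–Whitney implementation:** exact when the smaller group has at
  most 8 genes, tie-corrected normal approximation otherwise. Gene ranks
  within an instance are distinct by construction (max over disjoint
  probeset sets of a permutation), so the exact path is well defined.
- **Direction ties** (equal medians) are flagged `"tie"` and counted in
  neither direction.
- **Degenerate inputs** fail early with located messages: duplicated IDs,
  malformed numeric cells (named by probeset and sample), non-permutation
  rank columns (named by instance), one-to-one flag violations,
  asymmetric or out-of-range similarity matrices.
- **Seeding:** every stochastic component (permutation replicates, all
  fixture generators) derives its seed deterministically from one master
  seed, and the derived values stay inside the 32-bit range `set.seed()`
  accepts; identical configurations therefore give byte-identical outputs.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` defines a two-species world with planted structure: each
module is a centre gene with a latent profile and members loading on it
with coefficient `rho < 0` plus Gaussian noise `sigma` (probe-level noise
of the same magnitude on every probeset), independently re-drawn per
species for orthologous genes; phenotype families with within-family
similarity at or above 0.4 and between-family similarity below it, the
first families aligned to modules; one inhibitor drug per module plus
decoy drugs; and perturbation instances in which the targeted module's
probesets are drawn above an effect quantile before rank transformation.

The defaults — 300 genes, 3 modules of 10 members, `rho = −1`,
`sigma = 0.2`, 40 samples per species, full one-to-one orthology coverage,
effect quantile 0.95 — are the study conditions under which the pipeline
is expected to recover planted structure essentially completely; raising
`sigma` or lowering the orthology fraction degrades recovery (the latter
bounds expected recovery by the fraction itself, which is why the default
is 1). The generator is deliberately idealized: it does not emulate probe
sequence artifacts, batch effects, heteroscedastic noise, correlated
background genes, annotation bias, or the identifier messiness of real
compendia. Passing on these fixtures demonstrates that the machinery is
correct and calibrated under the model's own assumptions — not that any
particular biological dataset will yield equally clean clusters.

The null readings are likewise part of the design: with annotation labels
scrambled, the real-vs-permuted KS comparison should *fail* to reject; and
on pure-null rank matrices BH should keep the significant fraction below
the FDR level. Because FDR is an upper bound — under a global null the
expected number of BH rejections is far below the nominal level — the null
check is one-sided against the upper binomial bound, not a two-sided band
around it.

## Problem sizes used in the shipped validation

The test-suite and `scripts/acceptance.R` run at sizes chosen so the whole
battery completes in a few minutes on one core: 1000 random tables for the
hypergeometric oracle; exhaustive Mann–Whitney enumeration for groups up
to 8; a 100-probeset two-species world for the brute-force network
equivalence; the default 300-gene fixture for recovery, association and
perturbation; a 300-node / 1200-edge random network with 200 annotation
sets and 20 permutations (×20 seeds for the scrambled control) for the
index-distribution machinery; and 20 × 100 tests for the pure-null
perturbation check.

## Known limitations

- Clusters are first-neighbour sets, not community detections; a hub
  gene's cluster can be large and heterogeneous.
- Gene sets are used exactly as provided — no ontology ancestor closure,
  no evidence-code filtering, no gene-length or expression-level bias
  correction.
- Drug action labels are carried through but not used to filter
  associations; the direction validation is the check that actually
  interrogates inhibition.
- The orthology gate is strictly one-to-one; many-to-many homology is
  ignored rather than resolved.
- Identifier reconciliation across annotation versions is out of scope:
  all ID spaces are opaque strings and any number of probeset→gene maps
  can be supplied, but conflicts between map versions are the caller's
  responsibility.
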