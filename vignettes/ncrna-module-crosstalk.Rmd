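---
title: "Methods: stage-crosstalk gene modules and their essential ncRNA regulators"
author: "ncmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-crosstalk gene modules and their essential ncRNA regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumour progression from low stage (I/II) through stage III to metastatic
stage IV is accompanied by coordinated changes in gene expression. Single
differentially expressed genes (DEGs) rarely capture that coordination:
the interesting unit is a *module* — a dense cluster of interacting
proteins — and, across stages, the *crosstalk* between a stage III module
and a stage IV module, i.e. an excess of protein-protein interactions
linking the two. Noncoding RNAs enter because miRNAs repress mRNAs
posttranscriptionally and lncRNAs can antagonize miRNAs as sponges; an
ncRNA whose targets concentrate in both modules of a crosstalk pair (a
*pivot*) is a candidate essential regulator of the transition. The
pipeline asks, for each such merged module, whether its association with
overall survival strengthens when the pivot ncRNAs are added to its risk
model.

`ncmod` implements this chain end to end: preprocessing, SAM differential
expression, MCODE-style module mining, a degree-preserving permutation
test for crosstalk, regulatory-network inference, pivot analysis, Cox
risk-score survival stratification, and hallmark co-enrichment networks —
plus a synthetic-data generator that plants every structure the chain is
designed to detect, so each stage has a ground-truth recovery test.

## Preprocessing

Expression arrives as RPKM-like nonnegative matrices (features x
samples). Two zero rules apply, in this order: features that are zero in
*every* sample are removed, and remaining zeros are floored at
`zero_floor = 0.05` before the log2 transform. The source conventions
leave the order of the two rules ambiguous; dropping all-zero rows first
is the only reading under which both rules act on something, and it is
what `load_and_transform()` does. Negative input values indicate the
matrix is already log-scale and raise an error (condition class
`ncmod_loglike_input`) rather than being silently re-transformed. Stages
I and II are merged into the `low` group at load time (configurable);
samples with unknown stage or missing survival fields are dropped with a
logged count, and `harmonize_samples()` restricts all matrices to the
clinical table's sample intersection in a fixed order.

## SAM differential expression

For a two-class comparison the statistic is

    d_i = (mean_B - mean_A) / (s_i + s0)

with `s_i` the pooled standard error and `s0` an exchangeability constant
chosen from the 5%-grid percentiles of `s` to minimize the coefficient of
variation (across equal-occupancy `s` bins) of the median absolute
deviation of `d` — the Tusher-style rule. False-call estimation permutes
the class labels (`n_perm = 1000` by default, seeded; exact enumeration of
all label assignments replaces sampling whenever it is cheaper, e.g. 70
assignments for 4v4): at cutoff `|d_i|` the estimated false calls are the
*median* across permutations of the permuted exceedance count, scaled by
`pi0 = min(1, 2 x` fraction of observed `d` inside the central 50% band
of permuted `d)`. A feature's q-value is the best achievable FDR at any
cutoff at or below its own `|d|`, which makes selection monotone in the
threshold. Both directions of change are kept; the DEG set is `q <= 0.05`
by default.

## Module discovery

The PPI edge list (STRING dialect, scores 0-1000) is thresholded at 900,
deduplicated and stripped of self-loops. Each contrast's DEGs are mapped
onto the network and the subgraph induced by the DEGs plus their first
neighbours is split into connected components; every component of at
least 3 nodes is mined with an MCODE-style algorithm.

Vertex weighting is the published rule: the weight of `v` is `k x d`
where the highest k-core of `v`'s closed neighbourhood has core number
`k` and (loop-free) density `d`. Complex prediction deviates from the
published seed-and-grow in one respect, deliberately. Growing purely by
the vertex-weight threshold admits the far endpoint of a single bridge
edge between two cliques — both cliques' vertices carry identical
weights, so the complex leaks across the bridge and the two modules
merge, which would make inter-module crosstalk undetectable by
construction. `mcode()` therefore (i) initializes the complex with the
highest k-core of the seed's closed neighbourhood and (ii) admits a
candidate only if it passes the weight threshold `w > (1 - 0.2) x w_seed`
*and* has at least `k_core = 2` links into the growing complex. The
second condition only excludes vertices that the haircut post-processing
would strip anyway when they fail to recruit followers; its effect is to
stop single-edge leakage before it cascades. Post-processing is standard:
complexes without a 2-core are discarded, haircut iteratively removes
vertices with fewer than two internal links, complexes keep >= 3 nodes
and are ranked by `density x size`. Ties in seed selection break
lexicographically by node id, making the miner invariant to input order.

## Crosstalk between stage III and stage IV modules

For every stage III x stage IV module pair the real count of edges
between the two node sets (edges inside the overlap excluded, each edge
counted once) is compared against the same count in `n_random = 1000`
degree-preserving randomizations of the whole PPI — one shared ensemble
for all pairs. Randomization is the double-edge-swap chain
(`igraph::rewire`, `10 x |E|` swap trials per network; trials that would
create a self-loop or multi-edge are rejected, so degrees are preserved
exactly). The empirical p-value is taken literally as

    P = (1/N) * sum_i S_i,   S_i = 1 iff null count_i > real count

with strict inequality and no pseudocount, so `P = 0` is reportable; a
`pseudocount` option computes `(r + 1)/(N + 1)` for users who prefer a
positive lower bound. Significance is `P < 0.05`.

Two consequences of the literal convention are worth knowing. First,
p-values are slightly sub-uniform under the null when the count
distribution has appreciable ties (small modules); the calibration test
uses 25-node modules, where the count distribution is nearly continuous.
Second, if the same dense module is discovered in *both* stage
collections (one stray DEG can pull a partner-stage module into a
contrast's subnetwork), the pair tests itself: the overlap rule forces a
real count of 0 and every null count is also 0, giving `P = 0`. Such
self-pairs carry no pivot regulators and are removed at the NcModule
stage, but they can inflate the significant-pair count; interpret that
count together with the pivot-bearing module count.

## Regulatory network inference

miRNA-target regulation combines the CLIP-supported catalog with
expression: for each catalog pair the Pearson correlation across samples
is computed (two-sided t p-value), Benjamini-Hochberg adjustment is
applied across all tested pairs of the class, and active edges satisfy
`r < 0` and adjusted `p < 0.05`. ("FDR" and "adjusted P" are both
implemented as BH; the source names no procedure.)

lncRNA-gene regulation is the two-stage ceRNA-style analysis. Stage 1
keeps lncRNA-gene pairs sharing at least one miRNA whose shared-miRNA
overlap is significant under an upper-tail hypergeometric test
(`p < 0.05`); the gene-side miRNA sets come from the *active* miRNA-mRNA
edges (the expression-filtered set, not the raw catalog — the assembled
network should reflect regulation active in this cohort), while the
lncRNA-side sets come from the raw miRNA-lncRNA catalog by default
(`filter_mirna_lnc = TRUE` switches the same expression filter on; the
source is ambiguous on this point). The hypergeometric universe is the
set of miRNAs with at least one edge in either input — the natural
sampling frame. Stage 2 computes the Pearson correlation of every stage-1
candidate and keeps pairs with `r > 0` and BH-adjusted `p < 0.05` across
candidates. The assembled heterogeneous network unites PPI, miRNA and
lncRNA edges with node classes; id collisions across classes are an
error.

## Pivot analysis

For a significant crosstalk pair (A, B), a candidate regulator's targets
are its active network targets of its own class. It is a pivot when it
has at least `min_targets_per_module = 2` targets in each module and its
per-module enrichment is significant (`p < 0.05`, upper hypergeometric
tail) in both. The enrichment universe per class is the regulable frame —
all mRNA nodes that are a target of at least one regulator of that class.
The source's "more than two regulations" is ambiguous between `>= 2` and
`> 2` and between per-module and per-pair; the default is `>= 2` per
module (the standard pivot definition), and `min_targets_per_module = 3`
gives the strict reading. No multiple-testing correction is applied
across regulators, matching the raw-threshold style of the rest of the
chain (`adjust = "BH"` is available). Each significant pair with at least
one pivot becomes an NcModule: the deduplicated union of the two gene
sets plus the pivot ids.

## Survival models

Every NcModule is scored twice: on its genes only, and on genes plus
pivot ncRNAs. The source describes a "multivariable" analysis but defines
the risk score through per-factor ("unilabiate") coefficients; only the
per-factor reading makes the risk score well defined, so the default fits
one univariate Cox model per factor (Efron ties) and
`multivariable = TRUE` fits a single joint model instead. Factors that
are constant, have fewer than two events, or separate completely are
excluded with a logged reason. The risk score is the exact linear
combination `sum_i beta_i x expression_i`; patients above the median
score form the high-risk group (ties at the median go low; if ties empty
a group, the error says so). The two groups are compared by the
two-sample log-rank test, and predictive ability is `-log10(p)`. A module
*improves* — lands in group A — when predictive ability is larger with
the ncRNAs than without.

## Enrichment and pathway networks

Module-vs-gene-set enrichment is the same upper-tail hypergeometric
kernel, against a universe defaulting to all genes of the assembled
network (configurable to the full expression universe; the source is
silent). Significance is raw `p < 0.05` to match the chain's other
thresholds (BH optional). Two pathways are linked in the co-enrichment
network when the overlap of the module sets they enrich is itself
hypergeometrically significant at `p < 0.01` (population = module count).
Networks are built separately for group A, group B, and the full
stage-module collection. With only a handful of NcModules the
co-enrichment test cannot reach `p < 0.01` — its minimum achievable
p-value on four modules is 0.25 — so empty group networks at synthetic
scale are the expected, honest outcome; the operation itself is validated
on larger synthetic incidence matrices. "Core" pathways (enriched in at
least `min_modules` modules and with co-enrichment degree at least
`min_degree`) default to `min_modules = 3` and the upper quartile of
degrees; both are explicit configuration, since the source defers the
exact definition to unavailable supplementary material.

## The synthetic study

`simulate_study()` plants, under one global seed fanned out to
per-component child seeds by fixed offsets:

* **PPI** (`generate_ppi`): 400 nodes; ten 8-node near-cliques
  (within-module edge probability 0.95, density floored at 0.8), five per
  stage; a configuration-model background at mean degree 4 (Poisson
  degrees, simplified), giving a nontrivial degree sequence for the swap
  null; four bridged III/IV pairs with 12 extra bridge edges each and one
  unbridged control pair. Bridges attach only to 4 designated *boundary*
  genes per module, and boundary genes are excluded from the planted DEG
  sets — so each stage's DEG-plus-neighbour subnetwork contains its own
  modules in full while the partner module stays two steps away, and
  crosstalk is carried by genes that are not themselves differentially
  expressed. Planted edges score 950-999 and background edges 700-999 on
  the STRING scale, so the 900 cutoff thins the background without
  touching planted structure.
* **Regulatory layer** (`plan_regulation`): per bridged pair, four pivot
  miRNAs repressing three core genes in each module, and one pivot lncRNA
  repressed by the same miRNAs (hence positively correlated with the
  targets); two off-module sponge groups (three miRNAs, one lncRNA, two
  genes each); eight extra single-target miRNAs. Sixty miRNAs and thirty
  lncRNAs in total, leaving plenty of unplanted features for decoys.
* **Expression** (`generate_expression`): log2-space signal with
  multiplicative log-normal noise on the linear scale. Defaults: 100/70/40
  patients in low/III/IV (a realistic single-cohort split), DEG shift of
  1 log2 unit with random sign, couplings of 1 against miRNA deviations
  of sd 1 and residual noise sd 0.5 — yielding per-edge correlations
  around -0.35 (pivot targets, four regulators sharing the signal) to
  -0.7 (single-regulator pairs), comfortably detectable at n = 210
  without being trivial. The lowest 2% of linear entries are set to
  exactly 0, emulating an assay detection floor and exercising the
  zero-handling path; zeroing the *lowest* entries (rather than random
  ones) mirrors how RPKM zeros actually arise and avoids planting
  nonsensical high-abundance dropouts.
* **Catalog** (`generate_interaction_catalog`): planted pairs plus 300
  mRNA-class and 60 lncRNA-class decoys drawn only among features with no
  planted coupling, deduplicated against the planted set.
* **Survival** (`generate_survival`): exponential proportional hazards
  with linear predictor `sum(beta x centred log2 expression)` (centring
  only rescales the baseline hazard, so Cox fits on the same expression
  recover the betas); independent exponential censoring whose rate is
  tuned by bisection to the requested censored fraction (default 0.3).
  Planted betas: 0.2 on four genes of the first bridged pair, 0.8 on its
  pivot lncRNA, 0.5 on its first pivot miRNA — a weakly informative gene
  module whose prediction should improve when the ncRNAs join.
* **Gene sets** (`generate_gene_sets`): one enrichment-positive set per
  planted module (containing 80% of its genes plus padding) and an equal
  number of random sets.

What the generator does *not* emulate: library-size or batch effects,
count noise at low abundance, correlated co-expression beyond the planted
couplings, competing risks or informative censoring, and gene sets that
tile several modules. Passing tests therefore demonstrate that the
algorithms recover the structures they define, under clean conditions —
not that any particular real cohort contains such structures.

## Numerical choices and degenerate inputs

Hypergeometric tails go through one shared kernel (`phyper` upper tail)
validated against exhaustive enumeration to 1e-12 for populations up to
20. Constant vectors in correlation are a defined error, not NaN.
Zero-variance features with `s0 = 0` are an error rather than infinite
`d`. Seed-selection and complex-membership ties break lexicographically.
Graphs with fewer than two edges pass through randomization unchanged
with a warning; `n_random < 100` warns that p-resolution is `1/N`. All
randomness is seeded, and a rerun of `run_all()` with the same inputs,
configuration and seed reproduces every statistic exactly.

Test problem sizes are chosen to make each property measurable at
interactive cost: 50-seed batteries for calibration and recovery
(planted-DEG FDR/recall, regulatory and pivot recovery, crosstalk null
uniformity with 200 randomizations per seed), 10,000 randomizations for
the exact-null comparison on an exhaustively enumerable degree class, and
100 replicates of n = 300 for Cox coefficient recovery.

## Known limitations

MCODE's optional fluff stage is not implemented. The crosstalk test
reuses one null ensemble across pairs, so pair p-values are positively
dependent (this matches constructing "1000 random networks" once, and
makes reruns cheap, but a per-pair ensemble would decorrelate them). The
self-pairing artifact described above is reported, not suppressed.
Survival analysis is single-cohort; no external validation step is
provided. The pipeline treats feature ids as opaque strings and never
checks that miRNA/lncRNA/mRNA identifiers follow any nomenclature.
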