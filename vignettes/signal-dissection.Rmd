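---
title: "Dissecting phylogenomic signal with phylosieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting phylogenomic signal with phylosieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Deep phylogenomic questions — for instance, where an "orphan" protist
lineage attaches to the eukaryotic tree — are usually approached by
concatenating hundreds of single-gene protein alignments into a
supermatrix and estimating a maximum-likelihood (ML) tree. A strongly
supported clade in such a tree is not automatically trustworthy: the
support may come from a small subset of genes, from the fastest-evolving
alignment columns, from long-branch attraction (LBA) enabled by sparse
taxon sampling, or from genes whose history differs from the species
tree (for example genes partly acquired by endosymbiotic gene transfer,
EGT). `phylosieve` implements the standard battery of perturbation
analyses used to dissect such signals:

* **screening** of individual genes against well-established clades
  before concatenation;
* **FPR** (fast-evolving position removal): rank all columns by
  evolutionary rate and re-measure clade support as the fastest 20%,
  40%, 60%, 80% are removed;
* **RGS** (random gene sampling): measure the distribution of clade
  support over random gene subsets of increasing size;
* **taxon deletion**: re-run a design after removing "breaker" lineages
  whose presence subdivides long branches;
* **two-topology scans**: per-gene and per-site log-likelihood
  differences between two candidate topologies, the diagnostic for
  EGT-chimeric genes.

All of this runs on a self-contained ML engine (LG/WAG/Poisson +
discrete gamma) and a simulator that generates alignments with known
ground truth, so each stage of the pipeline is testable end to end
without any external data.

## The model and its machinery

The engine implements reversible amino-acid substitution models
`Q[i,j] = s[i,j] * pi[j]`, normalized to one expected substitution per
unit branch length. The LG and WAG exchangeability tables are the
published matrices (Le & Gascuel 2008; Whelan & Goldman 2001), obtained
at run time from phangorn's model tables rather than re-typed; the
Poisson (20-state Jukes–Cantor) model is closed-form and is used
wherever an analytic oracle is wanted:
`P[i,i](t) = 1/20 + (19/20) exp(-20 t / 19)`.

Among-site rate variation uses the discrete-gamma approximation with
`k` equiprobable categories whose rates are the bin means of a
Gamma(alpha, alpha) density (mean, not median, matching the mainstream
implementation lineage). Likelihoods are computed by Felsenstein
pruning with per-node log-scaling against underflow; `'-'`, `'?'`,
`'X'`, `'B'`, `'Z'`, `'J'`, `'U'`, `'O'` and `'*'` are treated as fully
missing and marginalized (ambiguity codes are *not* expanded into
partial state sets — a deliberate simplification, consistent across the
whole package).

Branch lengths are optimized by exact coordinate ascent: for each edge
the likelihood as a function of that edge's length alone is maximized
by Brent search, with outside ("up") partial likelihoods propagated
incrementally so every one-dimensional problem is exact at the current
parameter values. Each Brent evaluation contracts the cached inside and
outside partials through the eigenbasis of `Q`, so it costs a single
matrix–vector product per category. The gamma shape is optimized by
Brent search on `log(alpha)` over [log 0.02, log 50], alternating with
branch sweeps. Branch lengths are bounded in [1e-8, 20]; tolerances are
in log-likelihood units (default 1e-4 per sweep).

Tree search is neighbor joining on pairwise ML distances followed by
NNI hill climbing. Each internal edge defines two
nearest-neighbor-interchange rearrangements; both are scored by
re-optimizing only the central branch from cached subtree partials (the
four subtrees around the edge keep their stem branches, so their
partials are reusable). The best improving move is applied, tidied with
a quick branch sweep, and the cycle repeats; a full branch
re-optimization (and optional alpha re-fit) runs when no move improves
the likelihood. NNI-only hill climbs can stall in local optima when the
starting tree misplaces a long-branch taxon; `search_control(restarts =
n)` therefore supports seeded stochastic restarts (a few random NNI
perturbations followed by a fresh climb, best result kept), and
`bootstrap_support(start = )` accepts a guide tree so replicate
searches can start from the full-data ML tree — the rapid-bootstrap
convention. The search is deterministic given its inputs and seed.

Site rates are empirical-Bayes posterior means: for column `s`,
`r_hat_s = sum_m r_m P(m | x_s)` with equal prior category weights —
the same quantity mainstream programs report for slow–fast analyses.
Ranking ties are broken toward the smaller column index, so removal
sets are reproducible and nested across FPR fractions.

## Resampling designs and their seed schedule

Clade support is the standard nonparametric (Felsenstein) bootstrap:
resample columns with replacement, re-search the tree, and count the
fraction of replicate trees containing the clade's bipartition. (The
ultrafast bootstrap approximation used by some ML programs is an
engine-internal device; the monitored quantity — clade support in
percent — is the same.) Support for a clade after taxon deletion is
evaluated on the restricted taxon set, restriction happening before
canonicalization of the split.

Every stage derives its RNG seeds as fixed integer offsets from a base
seed (documented in the resampling module), so any single replicate can
be reproduced in isolation and an FPR series at fraction 0 is
bit-identical to a plain bootstrap run with the same base seed.

Defaults are desk-scaled: 100 bootstrap replicates (not 1000), and the
RGS default plan of 50/50/10/10 replicates at sizes 50/100/150/200
genes mirrors the classic design. The test suite runs much smaller
plans (10–20 replicates, 20 bootstraps) chosen so the full suite
completes in minutes on one core; these sizes are stated where used.

## What the simulator emulates — and what it does not

`simulate_alignment()` draws a root state from the stationary
frequencies and evolves it along the tree with per-site gamma category
drawn once per site; ground truth (per-site category and rate) is
recorded. On top of this the package builds three named study designs.

**LBA scenario** (`lba_scenario()` / `simulate_lba_case()`). The true
tree is `((longA,breakA),outA | (longB,breakB),outB)` with the two long
terminal branches (`lambda_long = 1.5`) on opposite sides of a short
internal branch (`lambda_int = 0.02`), each long branch paired with a
short-branch "breaker" sister (`lambda_breaker = 0.1`). Sequences are
simulated under strong rate heterogeneity (`alpha = 0.3`, 5000
positions); the artefact is elicited by *analyzing* the data with a
rate-homogeneous (k = 1) model — a well-understood, desk-scale stand-in
for the model misfit that real analyses try to absorb with profile
mixture models. Two geometric choices matter and were fixed at design
time:

* the cherry stems are short (0.15) so that ignoring rate
  heterogeneity pulls `longA` and `longB` together away from their
  breakers — the classic artefact;
* the outer terminals are long (`lambda_out = 1.5`), which keeps the
  total tree length near 6.5 expected substitutions per site. Under
  `alpha = 0.3` roughly half of all columns are invariant; with a
  shorter tree the slowest 40% of columns would be *entirely* invariant
  and the strongest removal fractions would leave no signal at all.
  With this geometry the slow tail retains a few hundred variable
  columns, which is what makes fast-site removal informative rather
  than merely destructive — mirroring real supermatrices, where even
  slow quantiles contain substitutions.

**Chimera scenario** (`chimera_scenario()` /
`simulate_chimera_study()`). Two 11-taxon topologies are identical
except for the taxon `M`: the host tree attaches it next to the
outgroup pair across a nearly unsupported internal edge (`host_edge`),
the donor tree attaches it to the `R1`/`R2` pair across a modest edge
(`donor_edge`), and three decoy pairs with long stems sit within two
short hops of M's host position. Each gene evolves a fraction `c` of
its columns (default 0.3, contiguous block at the gene's end) on the
donor tree. The design expresses the EGT hypothesis in miniature: the
vertical placement of a plastid-bearing lineage is weakly supported, so
a minority of transferred columns per gene — individually undetectable
— can dominate the concatenated signal. Three geometric features were
found necessary at design time and are deliberate: the donor stem is
exactly one weak edge away from M's host position (the concatenated
move must not cross any well-supported backbone edge); the decoy stems
are long and nearby (a noise-placed M otherwise lands on the donor stem
far too often — with few central directions the spurious
donor-clade rate reaches 20–40%); and M's terminal branch is long
(`m_branch = 0.5`), which attenuates every per-gene placement signal
relative to sampling noise while the concatenated margin, a hundred
times larger, remains decisive. The defaults are calibrated so that
single-gene ML rarely recovers the donor clade while 100-gene
concatenation supports it strongly; there is an intrinsic tension
between the two (both scale with the same per-site margins), and the
defaults sit at the most favourable point found.

**Missingness profiles** (`apply_missingness()`) drop each (taxon,
gene) pair independently with a per-taxon retention probability,
re-drawing masks that would leave a gene with fewer than 4 taxa. This
emulates uneven transcriptome coverage (a taxon sequenced shallowly is
missing from many genes), not biased, phylogenetically structured
missingness.

What passing tests on these fixtures shows: the pipeline detects the
signals it is designed to detect when those signals are present by
construction, at small scale, under a correctly specified or
deliberately mis-specified model. What it does not show: performance on
real data with alignment error, compositional heterogeneity,
site-specific profiles (CAT-like), partitioned models, or deep
time-scale saturation — none of which the simulator generates.

## Numerical choices and degenerate inputs

* Transition matrices come from the symmetrized eigendecomposition of
  `Q`; tiny negative entries are clamped at zero. Rows sum to 1 within
  1e-10.
* Per-node scaling keeps pruning finite down to effectively zero
  branch lengths; an all-missing column has site log-likelihood exactly
  0 by the marginalization convention.
* The per-site vector and its reported total satisfy
  `sum(site) == total` exactly (same accumulation order); internal
  optimizers use pattern-weighted sums instead.
* Site-rate ranking ties (e.g. among invariant columns, which share a
  posterior mean) break toward the smaller column index; the number of
  sites removed at fraction `f` is `round(f * L)`.
* Empirical "+F" frequencies floor unobserved states at 1e-4 before
  renormalizing, so no state has zero stationary probability.
* Screening verdicts for genes with fewer than 4 taxa overlapping the
  constraint universe are "unscreenable", not errors; taxon-deletion
  schemes that would leave a monitored clade with fewer than two
  members (or complement members) report `NA` ("not evaluable"), not
  0%.
* `subset_taxa()` never drops columns: constant or empty columns
  created by taxon removal are retained, so coordinates stay comparable
  across deletion schemes.

## Open design choices, resolved

* **Screening threshold.** The screening engine bootstraps its quick
  gene trees and excludes a gene when a bipartition incompatible with a
  constraint clade reaches support `tau`; `tau` defaults to 0.95 and is
  configurable. This replaces approximate-likelihood local support
  values, for which no published cutoff exists, with an explicit,
  reproducible criterion.
* **Coverage convention.** Coverage counts *all* missing characters,
  including gaps inside genes a taxon possesses; a per-gene presence
  flag table is reported alongside so either convention can be
  recovered.
* **Rate ranking is computed once**, on the full alignment over the
  supplied guide tree with a single alpha estimate, and reused for all
  removal fractions (removal sets are then nested by construction).
  After taxon deletion the ranking may be supplied precomputed from the
  richer taxon set (`fpr_plan(ranking = ...)`), which is how the
  package's own LBA experiment ranks sites: rates estimated from few
  taxa on an artefactual topology systematically misrank the very
  columns that drive the artefact.
* **Delta-lnL normalization** divides by the gene's total column count
  including gap-bearing columns; the site-wise scan holds branch
  lengths at their per-alignment optima per topology (a per-site re-fit
  would make site values incomparable).
* **Alpha in two-topology scans** is optimized per gene and per
  topology in the default mode; a fixed-branch-length mode exists and
  makes per-gene values exactly additive over concatenation.

## Problem sizes used by the automated checks

The acceptance script and test suite use: quartet oracles (4–5 taxa,
5–10 sites) for exact likelihood checks; 12 taxa x 10,000 sites for
parameter recovery (5 seeds); the 6-taxon LBA fixture at 5,000 sites
with 20 bootstrap replicates per removal fraction; a 100-gene RGS
fixture (6 taxa, 60-position genes) at subset sizes 10/25/50/100 with
20 replicates x 20 bootstraps; and the 11-taxon chimera fixture (100
genes x 100 positions, c = 0.3; 300-position genes for the
planted-gene ranking check). These sizes were chosen so the whole
battery runs on a single core in well under an hour while leaving each
statistical effect away from its detection threshold.

## Known limitations

* No codon or nucleotide models, no profile mixtures (C20/C60/CAT), no
  PMSF, no partitioned branch lengths or per-gene models, no Bayesian
  sampler, and no AU/KH/SH significance tests on topology comparisons —
  the scans report raw (normalized) log-likelihood differences.
* NNI-only rearrangements can in principle stop short of the global ML
  tree on large, conflict-rich alignments; for the problem sizes here
  exhaustive checks show they do not.
* The simulator generates neither indels (gaps only via the
  missingness profile) nor alignment uncertainty.
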