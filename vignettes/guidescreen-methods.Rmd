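---
title: "Empirical sgRNA library design and screen analysis with guidescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical sgRNA library design and screen analysis with guidescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidescreen)
library(dplyr)
```

## The problem

Pooled CRISPR knockout screens measure gene fitness effects by tracking the
abundance of single-guide RNAs (sgRNAs) in a proliferating cell population:
guides that disrupt an essential gene deplete over the course of the screen.
The quality of such a screen is limited by its guide library. Two failure
modes dominate: guides that do not cut their target efficiently (false
negatives) and guides with off-target activity that kills cells independently
of the annotated target (false positives).

`guidescreen` implements an *empirical* design strategy: rather than
predicting guide activity from sequence models, it mines collections of
published viability screens for guides that have repeatedly demonstrated
on-target activity and have never shown outlier phenotypes relative to other
guides against the same gene. The selected guides are assembled into two
mutually exclusive genome-scale sub-libraries (A and B, four guides per gene
each) sharing a common set of control guides, so the sub-libraries can be
screened independently or combined into an eight-guides-per-gene library.
The package also provides the downstream analysis the design depends on —
normalisation, fold changes, Bayes-factor essentiality calling, screen
quality gating — plus a mixture-model classifier of guide cutting activity
and a coverage (guides-per-gene) subsampling analysis.

Everything is exercisable on synthetic data with known ground truth; no
external downloads are required.

## Screen processing model

Counts are organised as tibbles with one row per guide (`sgrna`, `gene`,
`control_class`, one column per sample). Guides are gene-targeting unless
their gene label is one of two reserved names: `NON_TARGETING` (no genomic
match at all) or `TARGETING_CTRL` (cuts a neutral locus, paying the
double-strand-break cost without a gene phenotype).

Normalisation (`normalize_counts()`) adds a pseudocount (default 1, applied
before any median is taken) and divides each sample by the median
pseudocounted count of its *targeting controls*, so the targeting-control
median of every normalised sample is exactly 1. Targeting controls are the
right reference because they experience the same DNA-damage burden as library
guides. Per-guide depletion is the log2 ratio of normalised endpoint to
plasmid/T0 counts (`log2_fold_change()`); replicate agreement is summarised
with Pearson and Spearman correlations.

Two sub-library screens over the same samples are merged
(`combine_sublibraries()`) by rescaling each sample to the median count
across all samples of both inputs, rounding half-up (the half-up choice
pins down tie behaviour that plain "round to the closest count" leaves
open). Control guides present in both inputs are kept as two origin-tagged
rows (`id__A`, `id__B`) rather than averaged — no information is discarded.
Per-sample medians are computed over *all* guides; restricting to
gene-targeting guides changes the scale factor by well under a percent at
genome scale and the choice is internal to the combination step.

## Essentiality calling

Gene essentiality is scored with a Bayes-factor caller in the BAGEL
tradition. Reference gene sets anchor the two hypotheses: a core-essential
set (CEGv2-like) and a nonessential set (NEGv1-like). Per bootstrap round,
reference genes of each class are resampled and a Gaussian kernel density
(Silverman bandwidth, floored at `1e-12` before logs) is fit to the fold
changes of their guides. Each guide contributes the log2 ratio of the
essential to the nonessential density at its fold change; a gene's Bayes
factor (BF) is the bootstrap mean of the sum over its guides. Reference
genes are scored with their own fold of genes (10-fold partition) held out
of training, so no gene scores against a density it helped shape. One
hundred bootstrap rounds are the default; the scores stabilise well before
that on thousands of guides. Numeric equality with any particular BAGEL
release is *not* a goal — rank agreement and reference-set separation are
the contracts, and both are tested on synthetic data.

Essential genes are called two ways, mirroring common practice:

* **BF mode** — strictly greater than a fixed evidence cutoff (default 6).
* **FDR mode** — genes ranked by BF; at each candidate threshold the false
  discovery rate is estimated over reference genes only as FP/(TP+FP); the
  most lenient threshold with estimated FDR at or below the target (default
  5%) defines the call set.

Screen quality is the area under the precision-recall curve for separating
the two reference sets by BF (`precision_recall_auc()`, trapezoidal over
recall, tied scores handled as blocks). Screens below 0.9 are dropped by
`screen_quality_gate()`. The wording of the source material is ambiguous at
the boundary (retain "greater than 0.9" vs exclude "less than 0.9"); the
gate excludes only strictly below 0.9, the lenient reading.

Two scalar screen metrics complete the module. The skew ratio is the
90th/10th percentile ratio of counts (type-7 linear-interpolation
quantiles — "top/bottom 10 quantile" does not pin an estimator, so the R
default is used). The ECDF-AUC summarises how depleted a guide subset is:
the subset's empirical cumulative distribution is integrated against the
full library's ECDF, a probability–probability curve. The resulting area is
the probability that a random subset guide is more depleted than a random
library guide (ties split evenly): 0.5 for an undistinguished subset, near 1
for a consistently depleted one. An alternative — rescaling the fold-change
axis linearly over the library's [min, max] — was rejected: a single extreme
fold change (one toxic guide) then compresses the whole essential bulk
toward mid-range, capping the statistic near 0.7 on even ideal screens,
whereas published effective screens are characterised by essential-set
values close to 1. The rank-scale definition reproduces that behaviour and
is insensitive to outliers.

## The design algorithm

The selection pipeline (`design_from_screens()` ties the steps together)
works on a collection of screens that passed the quality gate:

1. **Per-screen activity** (`label_active()`): a guide is *active* if its
   target gene was called essential in the screen (FDR mode) *and* its fold
   change lies at or below the 20% quantile of all fold changes in the
   screen (ties at the threshold included). The 20% cut is deliberately
   lenient: with roughly 12% of genes essential, about 12% of guides can
   show a true phenotype, and the looser threshold retains guides with
   subtler effects.
2. **Aggregation** (`aggregate_activity()`): activity is tallied over the
   screens in which each guide was used. To keep single sporadic hits (for
   example copy-number artefacts in one cell line) from driving selection,
   activity only counts as a selection criterion if the guide was active in
   at least 5% of its screens (inclusive boundary).
3. **Outlier flagging** (`flag_offtarget_outliers()`): guides are grouped by
   target gene and their aggregate effect scores centred and scaled (sample
   standard deviation). A guide whose |z| exceeds 1.25 behaves unlike its
   siblings — unexpectedly toxic for a nonessential gene, or inert for an
   essential one — and is excluded as potentially off-targeting. Groups
   smaller than 3 or with zero spread are never flagged (a z-score from one
   or two guides is meaningless). The aggregate effect score stands in for a
   database effect score: within-screen rank-normalised fold changes mapped
   to [-1, 1], averaged over screens after aggregation (aggregating first,
   then flagging, keeps each guide a single observation).
4. **Sequence filters** (`sequence_flags()`): homopolymer runs (four or more
   A/T, five or more G/C — these stall synthesis and PCR), BbsI sites
   (GAAGAC and its reverse complement GTCTTC, incompatible with library
   cloning), and extreme GC (strictly above 75% or strictly below 20%). All
   comparisons are strict per the stated wording.
5. **Ranking** (`rank_candidates()`): surviving candidates are ordered with
   empirically active guides first (by number of active screens, then active
   fraction). Guides without activity evidence — the normal case for
   nonessential genes — are ordered by annotation quality: exons present in
   many transcript isoforms first, then proximity to the transcription start
   site, then fewest predicted off-targets. The lexicographic order of those
   three criteria is a package choice (the criteria are stated without an
   order); sequence string order is the final deterministic tie-break.
6. **Assembly** (`assemble_library()`): ranks 1–4 form sub-library A, ranks
   5–8 sub-library B ("A gets the best, B is second-tier"). Genes with
   fewer than eight surviving candidates are topped up from de novo designs
   (`design_de_novo()`: all NGG-adjacent 20-mers in the gene's exons,
   sequence-filtered, ordered by exon rank, off-target count, sequence); A
   is filled before B. Genes that still cannot fill both sub-libraries are
   reported in a failed-genes table and omitted entirely, preserving the
   structural invariants (exactly four guides per gene per sub-library,
   disjoint sub-libraries, no duplicated sequence). 300 non-targeting and
   135 targeting controls are appended to each sub-library and are identical
   in both.

Off-target counts use an exhaustive mismatch scan: genomic 20-mers on either
strand within 3 substitutions of the guide, minus one on-target occurrence
when the guide has an exact match. No PAM is required by default, matching
the permissive alignment-based proxy the design strategy is built on; a
PAM-aware mode is available (`require_pam = TRUE`). Gapped alignment is out
of contract. Guide annotation places the cut site between protospacer
positions 17 and 18 (three bases from the PAM-proximal end); exon rank is
taken on the gene's longest annotated transcript (the transcript choice is
otherwise unspecified), and coordinates are 0-based half-open internally
with GFF input converted from 1-based closed.

## Cutting classification

Whether a guide cut at all — independent of a fitness phenotype — is
inferred from the control fold-change distribution. A four-component
univariate Gaussian mixture is fit by EM to all control fold changes of a
screen: the highest-mean component tracks non-targeting controls (role 1),
the next targeting controls (role 2, shifted down by the double-strand-break
cost), and the two lowest capture moderate and severe toxic phenotypes
(roles 3 and 4). Roles are anchored by the order of fitted means; the
descriptive anchoring to control types in the source material is not
algorithmic, and mean-ordering is the deterministic equivalent. Note the
identification of component 1 with the non-targeting distribution follows
the figure-level description; the methods prose swaps the two labels
relative to its own classification rule, and the swapped reading would call
a guide "likely cutting" for behaving like a control that never cuts.

EM details: means initialised at the 12.5/37.5/62.5/87.5 data percentiles
(deterministic, so fits are reproducible by construction), equal weights,
variances floored at `1e-4` (keeps degenerate clusters from collapsing),
convergence at a log-likelihood increment below `1e-8`, at most 2000
iterations; the log-likelihood trace is retained and is non-decreasing.

Each library guide is mapped to the control with the most similar fold
change (ties toward the lower fold change) and inherits that control's
posterior responsibilities `p1..p4`. With a confidence threshold of 0.8: if
`p3 + p4 >= 0.8` the guide has a target-dependent viability phenotype; else
`p2 >= 0.8` means likely cutting; `p1 >= 0.8` likely not cutting; anything
else is undetermined. The toxic components are *summed* — the stated rule
("assigned to components 3 or 4 with a probability of at least 80%") is
ambiguous between sum and max, and the sum is the probability of the union,
which is what "assigned to 3 or 4" describes. Guides targeting
core-essential reference genes are excluded up front: their depletion is
expected and says nothing about cutting. Classification is performed on
replicate-averaged fold changes per screen by default; nothing prevents
fitting per replicate instead.

## Coverage analysis

`coverage_curve()` asks how many essential genes are recovered as the
library is thinned to k = 2..8 guides per gene: for each k, five independent
subsamples are drawn (controls always retained in full — they are needed
for normalisation), counts renormalised (renormalisation after subsampling
keeps the control median contract intact), fold changes recomputed, and
essential genes called with both the BF > 6 and 5%-FDR callers. The report
carries the mean and standard error (sample sd divided by the square root
of the number of samplings) of the hit count per (k, caller).

## The synthetic-data generator

`simulate_screen_collection()` generates screen collections with known
truth. Its defaults are the study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| `essential_fraction` | 0.12 | expected fraction of essential protein-coding genes in proliferation screens; the essential count is `round(fraction * n_genes)` |
| `essential_effect` | -3 log2 units | mean depletion of a fully effective guide against an essential gene over a 14-day screen |
| efficacy | Beta(6, 2) | most guides in published libraries cut well (mean 0.75) with a tail of poor cutters |
| `toxic_offtarget_rate` | 0.01 | rare gene-independent toxic guides |
| `toxic_effect` | -3 | toxic phenotypes are as strong as true essential knockouts |
| `targeting_dsb_effect` | -0.3 | the small fitness cost of any double-strand break, visible as the shift between targeting and non-targeting controls |
| `nb_dispersion` | 0.05 | negative-binomial count noise, the community-standard model for screen counts |
| `sequencing_depth` | 1e7 | typical per-sample read depth |
| controls | 300 non-targeting + 135 targeting | the control complement of each designed sub-library |

Mechanistically: per-guide plasmid abundance is log-normal (sdlog 0.5),
endpoint means are `plasmid * 2^(efficacy * gene_effect + toxic + dsb)`, and
all counts are negative-binomial. The plasmid sample carries no treatment
effect. Guide sequences are unique random 20-mers that pass the sequence
filters, emulating a pre-filtered (designed or published) library; this
matters because the design stage must not lose whole genes to cloning-filter
attrition that a real candidate pool would already have absorbed.

Two experiment-specific conditions deviate from the defaults, by design
rather than convenience. Design-selection experiments use candidate pools of
12 guides per gene with uniform (Beta(1,1)) efficacy: the outlier flag
removes roughly a fifth of guides under pure noise (|z| > 1.25 with
within-gene groups), so a pool close to the published 8-guide minimum
cannot fill two sub-libraries, and published pools averaged ~25 candidates
per gene; uniform efficacy guarantees both high- (>= 0.9) and low- (<= 0.3)
efficacy guides exist in numbers worth comparing. Effect-recovery checks fix
efficacy at 1 and disable the DSB and toxic terms so the raw fold change
estimates the generative effect directly.

What the generator does *not* emulate: genuine guide-sequence/activity
relationships (efficacy is assigned, not predicted), copy-number-driven
off-target toxicity localised to particular cell lines, context-dependent
essentiality differing between screens, chromatin effects, or realistic
genome sequence composition. Passing tests therefore demonstrate that the
algorithms recover the structure they are defined on — not that the design
strategy would beat sequence-model baselines on real screens.

`simulate_genome()` provides small random genomes with non-overlapping
genes, engineered NGG-adjacent guide sites, and planted near-duplicate sites
at 0–4 mismatches, giving exact expected off-target counts at the 3-mismatch
budget.

## Numerical and interface choices

* Quantiles everywhere are R's type-7 (linear interpolation); activity
  thresholds are inclusive ("ties count as active").
* The FDR threshold scan is over observed BF values, inclusive at the
  selected threshold.
* All randomised operations (bootstrap, subsampling, simulation) restore the
  caller's RNG state and are fully determined by an explicit seed argument;
  the command-line interface fans a single configured seed out to every
  stage, so identical config + seed gives byte-identical outputs.
* Problem sizes in the shipped tests and the acceptance script (1000-gene
  screens for calling, 200-gene collections for design, 300-gene screens for
  coverage) were chosen as the smallest sizes at which the statistical
  contracts are comfortably non-marginal; they run in seconds on one CPU.
* The command-line entry point (`exec/guidescreen`, subcommands `simulate`,
  `qc`, `design`, `analyze`, `classify-cutting`, `coverage`) is a thin
  wrapper over the exported functions; it rejects unknown config keys and
  writes the resolved configuration next to its outputs.

## Known limitations

* The Bayes-factor caller is a compact reimplementation: absolute BF scales
  differ from published BAGEL outputs; only ranks, call sets and
  reference-set separation are comparable.
* The off-target scanner counts full-length substitution-only matches; local
  or gapped alignments (which a read aligner in very-sensitive-local mode
  would also report) are out of scope, so counts are a lower bound relative
  to that proxy.
* The de novo designer is a minimal stand-in (exon-restricted NGG
  enumeration with the package's own filters), not a full-featured design
  tool.
* FDR estimation from reference sets inherits the reference sets' biases;
  genes resembling neither reference class are calibrated only by proxy.

## A minimal worked run

```{r example, eval = FALSE}
sim <- simulate_screen_collection(simulation_config(n_genes = 300, seed = 1))
cm <- sim$screens[[1]]
fc <- log2_fold_change(normalize_counts(cm), "T14_R1", "plasmid")
refs <- reference_sets(sim$truth$genes$gene[sim$truth$genes$essential],
                       sim$truth$genes$gene[!sim$truth$genes$essential])
scores <- bayes_factor_scores(fc, refs)
precision_recall_auc(scores, refs)
head(call_essentials(scores, refs, mode = "fdr"))
```
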