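---
title: "Methods: isomiR-aware small-RNA profiling, novel miRNA discovery and breed-group expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR-aware small-RNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRpipe)
```

# Scope and data model

`isomiRpipe` implements the analysis chain of a 454-era multiplexed
small-RNA sequencing experiment: seven barcoded kidney libraries from
porcine breeds grouped by origin (EU = Iberian and Wild Boar, EA = the
commercial Landrace/Large White/Pietrain breeds, AS = Meishan and
Vietnamese). Reads carry a 5-nt multiplex identifier (MID) at the 5' end
and a 3' adapter. After demultiplexing and trimming, identical inserts
are collapsed into *unique tags* with per-library counts; the total count
of a tag (or of a cluster of tags) is its *copy number* (CN).

Tags are annotated against a mature miRNA reference with an end-tolerant
matcher; the tags assigned to one reference form a *miRNA cluster* whose
members are the miRNA's isomiRs. Unassigned tags feed novel-miRNA
discovery. Expression analysis works on counts per thousand per library
(cpt), averaged within breed groups. qPCR support (standard curves,
geNorm reference stability) and hypergeometric category enrichment round
out the validation stages.

The raw reads of the kidney experiment are not redistributable at desk
scale, so the package pairs two complementary data sources:

* **Published count fixtures** (`kidney_fixture()`): the per-library
  sequencing totals and the per-breed counts of the 23 most abundant
  miRNAs (CN > 350). These drive exact, deterministic checks of the
  expression arithmetic.
* **A synthetic-data generator** (`simulation_config()`,
  `simulate_srna_experiment()`): a mini genome with planted miRNA
  hairpins, novel hairpins and decoy loci, plus multiplexed reads with a
  known isomiR structure and planted group effects. Everything downstream
  is testable against simulation truth.

# Preprocessing rules

MID matching is an exact 5-nt prefix: 454-era barcodes carry no error
correction, and at these depths a false library assignment is worse than
the loss of an occasional read. The 3' adapter is removed at its first
exact occurrence; if absent, the full remainder is kept. Unassignable and
empty reads are logged with a reason, never silently dropped, so read
conservation (assigned + discarded = input) is assertable.

Tag filters are inclusive on both boundaries: length in [15, 29] nt and
CN >= 3. U is canonicalized to T and all sequences are stored 5'->3'
uppercase. The per-library *totals of all length-filtered reads* are the
library-size denominators used by the expression stage; this
denominator choice is what reproduces the fixture fold changes below.

# End-tolerant annotation

The matcher interprets "up to 4 mismatches at the ends" as **at most 4
terminal variant nucleotides summed over both ends** (not 4 per end),
with a 100% identical core of at least `query length - 4` nt. Terminal
variants count query extensions beyond the reference, query truncations
relative to the reference, and mismatching terminal positions. This is
the stricter of the two possible readings and reproduces the observed
1-2-nt end variants while preserving long identical cores; the tolerance
is a parameter (`tolerance`) for users who want the per-end reading.

Internal (non-terminal) substitutions are deliberately **not** tolerated:
the matching contract is exact-core identity with end tolerance only.
Internally edited tags fall to the unannotated pool (and from there are
discarded by discovery's perfect-mapping filter, since an edited tag no
longer maps). RNA editing is real but rare at these depths; tolerating it
would blur the isomiR/sequencing-error boundary without a quality model.

When several references match at equal cost the assignment priority is:
lower total terminal variants, species prefix `ssc` first (porcine
references outrank orthologs), longer identical core, then lexicographic
id. Predominance ties inside a cluster break by lexicographic sequence
order. Both rules exist purely for determinism. A cluster is named by the
reference its most expressed member matched, diverging clusters (where
the predominant isomiR differs from the database mature) are flagged, and
clusters with CN < 3 are excluded from the profile.

The matcher is validated against a brute-force oracle that enumerates
every (offset, trim) pair, over 10,000 randomized cases in the test
suite.

# Novel miRNA discovery

Candidate tags must map to **exactly one** perfect (100% identity,
full-length) genomic locus, be 19-23 nt long, lie outside the annotation
mask, and have CN > 2 (strict). These filters commute. Candidates are
clustered single-linkage by >= 1 nt same-strand overlap -- the most
inclusive deterministic reading of "positioned in the same region" -- and
each cluster's max-CN member becomes its reference sequence. The putative
precursor is the reference locus plus 50-nt flanks, strand-oriented,
clipped (and logged) at chromosome ends. Coordinates are 0-based
half-open internally and 1-based inclusive in user-facing tables.

## Hairpin folding

Folding is **base-pair maximization** (Nussinov-style dynamic
programming, minimum hairpin loop 3 nt, Watson-Crick plus G.U pairs), not
thermodynamic free-energy minimization. The decision criteria are
pass/fail, not energies, and a maximization DP is auditable against
exhaustive enumeration of nested structures, which the test suite does
for precursors up to 40 nt. Two consequences are worth knowing:

* Maximization decorates structures with incidental pairs a
  thermodynamic fold would not form. The hairpin verdict therefore
  tolerates up to `branch_tolerance = 2` stray pairs (pairs from the
  mature span to the minority side, or wholly inside the span); a strict
  zero-stray rule rejects genuine stems over single spurious pairs.
  A pass requires at least `min_arm_pairs = 16` pairs from the mature
  span to one arm -- the canonical "~16 bp" guideline -- with the stray
  budget respected.
* G.U wobbles are not closed under complementation (the complement of a
  G.U pair is C.A, which does not pair), so only Watson-Crick-only folds
  (`allow_gu = FALSE`) have a pair count exactly invariant under reverse
  complement. The shipped default keeps wobbles, as real stems use them.

On random 121-nt precursors the criteria reject roughly 95-98% of
non-hairpin loci while planted hairpins with fully pairable arms always
pass; a small false-pass rate is inherent to pair maximization and is the
reason candidate validation in practice still ends with wet-lab
confirmation.

# Expression analysis

cpt = raw count / library total x 1000, so each library's tag cpt values
sum to exactly 1000. Group means are **unweighted** arithmetic means over
member libraries (not pooled counts). The signed fold change between
group means a and b is `+a/b` if `a >= b`, else `-b/a`, giving
`|fc| >= 1` and antisymmetry. A miRNA is differentially expressed iff
`|fc| > 1.5` (strict) or it is absent (zero raw count in every library)
in exactly one of the two groups; with both groups absent the comparison
is skipped. No p-value is attached to these ratio calls -- read-count
ratios at 454 depths are semi-quantitative, and the package deliberately
reproduces the ratio-based procedure rather than wrapping a count model
(use DESeq2/edgeR if you want one).

Running this arithmetic on the packaged kidney fixture reproduces all 15
published fold-change cells of the five RT-qPCR-validated miRNAs to 2
decimal places, and the abundance shares (23.50% for Hsa-miR-200b-3p,
7.64% for Ssc-miR-125b of the 115,305-read grand total) exactly. Printed
fold changes are compared at 2 dp rather than bit-exactly, since the
original rounding convention is not recoverable.

# qPCR quantification

Standard curves are ordinary least squares of Cq on log10 (relative
input) over >= 3 dilution levels; efficiency is `10^(-1/slope) - 1` and
QC requires efficiency in [90%, 110%] with r^2 >= 0.99. Quantities come
from inverting the calibration line (absolute-relative quantification,
not delta-delta-Cq).

geNorm stability is the single-pass M statistic -- for reference j, the
mean over partners k of the SD across samples of log2(q_j/q_k) -- with
threshold exclusion at M < 1.5 and the per-sample normalization factor
(NF) the geometric mean of retained reference quantities. The original
iterative worst-reference elimination is available behind
`iterative = TRUE`, but the screening workflow only needs the M < 1.5
filter. Normalized target quantities are expressed relative to the
lowest normalized value and log2-transformed; group testing on those
values is routine two-way ANOVA territory and is left to standard tools
(`aov`/`lm` on the returned long-format table).

# Enrichment

Over- and under-representation of categories among target genes uses
exact hypergeometric tails (`P(X >= k)` and `P(X <= k)`; the tails share
`P(X = k)`). Benjamini-Hochberg adjustment is applied to the two tails
as **separate families** by default (`joint = TRUE` pools them; which
convention a study used is rarely stated, so both are available). The
universe defaults to all genes in the category map, overridable. Target
prediction itself is consumed as input -- external predictors are a
service, not an algorithm to re-implement.

# The synthetic-data generator

The generator emulates the seven-library design: default depths are the
per-library totals of the kidney run (4,022-23,815 reads; 115,305 in
total), default groups are EU/EU/EA/EA/EA/AS/AS, and each library gets a
distinct 5-nt MID and a shared 17-nt 3' adapter.

* **Genome and loci.** The background genome is i.i.d. uniform ACGT --
  the simplest null that makes unique-mapping checks meaningful. Each
  annotated miRNA locus is a planted hairpin: a 19-23-nt mature, an 8-nt
  loop and an opposite arm that is the mature's reverse complement with
  2-3 G.U wobble substitutions. The wobbling keeps the arm fully
  pairable while ensuring the mature occurs exactly once over both
  genome strands (a perfect complement would duplicate it on the minus
  strand). Novel hairpins are planted the same way but excluded from the
  mature reference and the annotation mask; decoy loci are planted
  without hairpin structure as discovery negative controls. The
  generator verifies single-copy placement and that unannotated loci do
  not match any annotated mature within the default end tolerance,
  re-drawing sequences if needed.
* **IsomiR model.** Each read's insert perturbs its source mature
  independently at both ends: with probability `p_shift3` (default 0.3)
  the 3' end is shifted by 1-2 nt, with `p_shift5` (default 0.1) the 5'
  end; shifts are equally likely truncations or *templated* extensions
  read from the precursor, so variants stay genome-mappable -- matching
  the biology of imprecise Drosha/Dicer cleavage rather than untemplated
  tailing. The published account gives no end-shift rates, so the
  defaults are free parameters chosen to make 3' variability dominate
  (as observed in kidney and elsewhere), not estimates of any dataset.
  An internal substitution occurs with probability 0.02. All
  probabilities and `max_shift` (<= 4, default 2, matching the
  "one or two nucleotides" scale of observed end variants) are exposed.
* **Abundances and effects.** Base expression weights are log-normal
  (sdlog 1), giving the heavy-tailed profile real miRNAomes show. Group
  effects act on **expected read shares**: an affected miRNA's sampling
  probability is scaled by exactly its effect and the unaffected
  background is renormalized to absorb the compositional shift. Without
  this renormalization a 2x effect on abundant miRNAs would surface as a
  much smaller cpt fold change (the denominator grows too), and planted
  truth would not equal the quantity the pipeline estimates.
  `top_effect_table()` picks affected miRNAs from a mid-to-high
  abundance window (default individual share 1.5-6%, total post-effect
  share capped at 60%), mirroring how validation candidates are chosen
  from well-expressed miRNAs and keeping each fold change estimable at
  the default depths.
* **Determinism.** One global integer seed; every stage derives its
  stream by fixed offsets. Identical seed and configuration give
  byte-identical outputs.

What the generator does **not** model: 454 homopolymer errors, quality
scores (the pipeline never reads them), RNA degradation, cross-mapping
between paralogous miRNA families, and untemplated 3' tailing. Passing
tests on simulations therefore demonstrate the pipeline's correctness
given its stated read model, not robustness to platform-specific error
modes.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
plus the count fixtures: simulations use 10-40 miRNAs, genomes of 7-20
kb, and depths of 300-6,000 reads per library (the effect-recovery
checks use 6,000 x 7 reads over five seeds). These sizes were chosen so
that every stochastic property has comfortable sampling margins while a
full run stays in the tens of seconds. Matcher results are exact integer
costs; folding DP results are exact integer pair counts; fold-change
comparisons against printed values use 2-dp rounding; curve-efficiency
recovery is asserted to 1e-6.

Known limitations: the matcher is ungapped by design (a gapped variant
would conflate isomiRs with paralogs); cluster naming follows the
predominant member, so arm-switching or family collapses are not
resolved; the hairpin verdict is an explicit, reproducible stand-in for
what is in practice a partly visual judgment; and the ratio-based DE
calls carry no error control.

# A worked example

```{r example, eval = FALSE}
library(isomiRpipe)

# exact reproduction of the published fold-change cells
fx <- kidney_fixture()
fc <- hts_fold_change_table(fx$counts, fx$totals, fx$groups)
round(fc[fc$mirna_id == "Hsa-miR-200b-3p",
         c("fc_EU_vs_EA", "fc_EU_vs_AS", "fc_EA_vs_AS")], 2)

# a full synthetic run
run <- run_pipeline(config = simulation_config(seed = 1))
print(run)
head(run$profile)
run$novel$table
```
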