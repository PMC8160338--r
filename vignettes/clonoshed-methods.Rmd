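---
title: "Methods: multi-lesion heterogeneity and ctDNA shedding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-lesion heterogeneity and ctDNA shedding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoshed)
```

# The problem

A patient with pretreated metastatic cancer typically harbors many
lesions whose mutation profiles have diverged. Sequencing one biopsy can
therefore miss actionable alterations and mislabel a locally clonal
mutation as truncal. clonoshed models the two complementary readouts:
multi-region tissue sequencing (which lesions carry which mutations,
after correcting for uneven detection power) and a plasma cfDNA sample
(a shedding-weighted mixture of all lesions). All operations work on
plain data frames read from VCF/TSV, SEG-like TSV and a sample sheet.

# Presence matrices: rescue, power, classes

Callers miss real variants near their sensitivity limit, which inflates
apparent heterogeneity. Two corrections are applied, in order:

1. **Rescue.** A mutation called with high confidence in any lesion of a
   patient is scored present in each other lesion where it has at least
   3 supporting reads with base quality ≥ 30 and mapping quality ≥ 60.
   Rescue never downgrades an original call, so per-lesion presence
   counts are monotone in the rescue step and the operation is
   idempotent.
2. **Power filter.** A locus is retained only if every lesion had ≥ 90%
   probability of showing ≥ 3 variant reads for a clonal heterozygous
   mutation, i.e. `P(Binom(d, f) ≥ 3) ≥ 0.9` with
   `f = expected_vaf(ccf = 1)` from the lesion's purity at the default
   diploid state. The power is evaluated at CCF 1 and multiplicity 1:
   the filter asks whether a *clonal* variant would have been seen,
   matching the intent of the rescue step. Zero or missing depth is
   never powered.

Classes then follow set logic on powered mutations: present in all
lesions = truncal, exactly one = private, otherwise branch. A mutation
present everywhere but unpowered somewhere is *unclassifiable*, not
truncal — treating it as truncal would launder a detection failure into
a biological claim. Patients with a single lesion are entirely
unclassifiable for the same reason.

Pairwise lesion similarity is the Jaccard index over powered present
sets. Rescued mutations count as present: the rescue exists precisely to
avoid overstating heterogeneity, and excluding rescues would reintroduce
the bias the procedure removes. Burden summaries use TMB (coding
mutations at depth ≥ 30 and VAF > 0.01 per powered megabase) and the
*unscaled* median absolute deviation — a raw descriptive dispersion, so
no 1.4826 normal-consistency factor is applied. The TMB VAF cutoff is
configurable; 0.01 is the default, with 0.005 a common alternative for
deep panels.

# Cancer cell fractions

For purity $\alpha$, tumor total copy number $q_t$, normal copy number 2
and multiplicity $m$, a mutation in fraction $c$ of cancer cells has
expected VAF

$$f(c) = \frac{\alpha c m}{\alpha q_t + (1 - \alpha) \cdot 2}.$$

The CCF posterior evaluates `Binom(a | d, f(c))` over a grid of 100
values `c = 0.01, 0.02, …, 1.00` with a uniform prior. Numerical
choices:

- **Grid.** `c = 0` is excluded (a somatic mutation in zero cancer cells
  is not a state); 100 points give 0.01 resolution, matching the
  reporting precision of CCFs.
- **Interval.** A central 95% credible interval from the cumulative
  posterior (2.5/97.5 percentiles on the grid). A highest-density
  interval was the alternative; the central interval is monotone in the
  cumulative sum, cheap, and identical for the unimodal binomial
  likelihoods that occur here.
- **Degenerate inputs.** `a = 0` gives a monotone decreasing posterior:
  point and lower bound collapse to 0.01. `a > d` is an error. Depth
  < 30 flags the estimate non-reportable; clonality classification
  refuses such estimates rather than guessing.
- **Clonality.** Clonal ⟺ point ≥ 0.9, boundary inclusive.
- **Multiplicity.** When unknown it is estimated by inverting the VAF
  model, `m = round(f (αq_t + (1−α)2)/α)` clipped to `[1, major]`.
  Mutations with `m > 1` in regions of major copy number ≥ 2 are timed
  before the copy gain.

ctDNA CCFs reuse the same posterior with the plasma tumor fraction in
place of purity and the plasma copy state; every posterior invariant is
inherited.

# Copy-number events

With sample ploidy $\psi$: high-level amplification at total ≥ 3ψ, gain
at ≥ 2ψ, partial deletion below ψ/2, homozygous deletion at 0; LOH
(minor = 0, total > 0, including copy-neutral) is an orthogonal flag.
Totals between ψ/2 and 2ψ are neutral for driver purposes but count as
altered for CIN whenever total ≠ round(ψ); copy-neutral LOH is also
counted altered — it is a genuine copy-number event even though dosage is
preserved. SCNA profile similarity is computed at base level with event
labels required to match, because segment-identity comparisons are
brittle to breakpoint jitter between independently segmented samples.

Mutation loss (mutant allele removed by LOH) uses a deliberately
conservative three-condition rule: at least one lesion with the mutation
and no LOH, at least one lesion with LOH and no mutation, and no lesion
lacking both (such loci are removed from consideration, since absence
there could reflect clonal structure rather than loss).

# Detection power in plasma

With per-base error rate $e$ = 10⁻³ and a per-locus false-positive
budget of 5 × 10⁻⁷, the minimum supporting read count at depth $d$ is
the smallest $k$ with `P(Binom(d, e) ≥ k) ≤ 5e-7` (about 10 reads at
1200×). Power at ctDNA CCF $c$ is then the binomial tail above that
threshold at the expected plasma VAF, and the minimum detectable CCF is
found by bisection on the monotone power curve. The error rate is
interpreted as a per-base substitution probability; it is not divided by
three per alternative base (configurable in principle, off by default,
as the substitution spectrum of panel errors is not modeled). Expected
VAFs at or below the error rate are reported but flagged unreliable.

Tissue-defined mutations are scored detected in plasma at ≥ 3 supporting
reads, mirroring the tissue rescue; plasma-only variants survive only at
VAF ≥ 0.005. Association models are standard: logistic detection ~
lesion count + maximum tissue CCF with Wald intervals, switching to a
hand-rolled Firth (Jeffreys-prior score-corrected) fit under complete
separation, which is common at saturating depth where every branch
mutation is detected; and OLS with a 95% slope interval for ctDNA CCF on
lesion count. Under equal shedding, clonal mutations and diploid loci,
the expected ctDNA CCF of a mutation carried by k of N lesions is
exactly k/N, so the regression slope has closed form 1/N — the main
calibration target of the whole plasma model.

# Biopsy subsets and truncality from plasma

`subset_statistics` enumerates all C(N, s) biopsy subsets exactly
(N ≤ 20, s ≤ 5 everywhere in practice; a seeded Monte-Carlo fallback
with a warning exists above a 10⁶-subset cap). A driver is detected by a
subset when present in ≥ 1 sampled lesion, and a non-truncal driver is
misclassified as truncal when present in *all* sampled lesions. The
standard deviation uses the n−1 sample denominator: for a five-lesion
patient with one private driver the per-subset detected counts at s = 4
are {4,4,4,4,3}, giving sd 0.447 (population sd would give 0.40), and
the sample convention reproduces the conventional reporting of such
experiments. For a single private driver among t truncal ones the
summary has closed form mean = t + s/N, completeness = s/N, used as a
test oracle for all N ≤ 20.

The ROC for truncality from plasma sweeps thresholds at midpoints
between sorted distinct CCFs (plus sentinels), classifying truncal at
CCF ≥ threshold. AUC is the trapezoidal area, identical to Mann–Whitney
pairwise concordance with ties counted ½ (a test verifies the identity).
The operating point minimizes the Euclidean distance to the top-left
corner in (FPR, 1−TPR) space with equal weights — the rule names the
corner, not the metric, and the unweighted Euclidean distance is the
conventional reading; ties break toward the higher (more specific)
threshold.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are fixed study
conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| lesions per patient | uniform 4–17 | observed range in rapid-autopsy series (median ~9) |
| tissue depth | Poisson, mean 117× | typical exome depth in such series |
| plasma depth | Poisson, mean 1200× | deep targeted panels run ~1000–1600× |
| purity | Beta(8, 3) clamped to [0.05, 1] | breast-dominant autopsy tissue is high-purity; sub-40% samples are usually curated out |
| ctDNA tumor fraction | 0.3 | advanced pretreated metastatic disease sheds heavily |
| per-base error | 10⁻³ | Illumina substitution error scale |
| mutations/patient | 50 truncal, 30 branch, 40 private (Poisson) | panel-scale counts matching published non-truncal denominators |
| panel fraction | 0.3 | a 566-gene panel covers a minority of exome-wide sSNVs |

Branch mutations are placed on the internal edges of a random
bifurcating clone tree over the lesions, producing nested presence
patterns; the alternative `branch_k_dist = "uniform"` draws the
harboring-lesion count uniformly on 1..N−1, the design used for the
shedding-slope experiment where a uniform k design matrix is wanted.
The lesion-set size distribution of real branch mutations is unknown;
the tree placement is a modeling choice, not an empirical claim.

Within a harboring lesion mutations are clonal (CCF 1) by default, with
an optional subclonal fraction; per-lesion presence is the primary
signal of the truncality analysis, and keeping lesions internally clonal
isolates it. Copy number defaults to diploid everywhere so mutation
tests are not confounded by CN complexity; segment tables can be
injected for the CNA operations. Depths are Poisson around the mean
(no overdispersion, matching the binomial read model); read counts are
binomial at the expected VAF; non-harboring loci draw error reads at the
per-base rate. High-confidence "calls" are defined from the data alone
(≥ 5 reads and VAF ≥ 0.05). A single integer seed drives one RNG stream;
identical config + seed reproduce the cohort exactly. The global RNG
state is saved and restored around simulation.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: mapping artifacts and strand bias (base
and mapping qualities are constant placeholders), overdispersed
coverage, subclonal copy number, indels (the CCF machinery is
sSNV-only), germline contamination of the plasma panel, and any
realistic genome coordinates or mutational context. Results on real
cohorts will additionally depend on caller behavior upstream of this
package, which starts from call tables, not reads.

# Problem sizes and runtime

The test suite simulates cohorts of 1–6 patients with 4–17 lesions and
10³–10⁴ mutations where distributional checks need them; the acceptance
script simulates nine 12-lesion patients (~2200 non-truncal sSNVs).
These sizes give Monte-Carlo standard errors well inside the asserted
tolerances while keeping a full run in tens of seconds on a laptop.

# Interface notes and limitations

The package is function-first: `run_pipeline(run_config(...))` is the
single-command entry point, and each stage is an exported function;
file-based workflows go through the VCF/TSV/SEG readers and writers
(1-based inclusive coordinates throughout). There is no shell
executable — an R session or Rscript one-liner plays that role.

Known limitations: purity/ploidy/segmentation are inputs, not inferred;
driver rules ship only as a small illustrative synthetic fixture
(`inst/extdata/driver_rules_synthetic.tsv`) and real analyses must
supply curated lists; the plasma mixture model assumes shedding weights
are constant across mutations within a lesion; and ROC thresholds
derived on one cohort do not transfer across assays, cancer types or
tumor-fraction regimes.
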