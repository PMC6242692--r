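---
title: "Models and methods behind crispriscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crispriscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crispriscreen)
```

This vignette explains the statistical models, conventions and design
choices in `crispriscreen`, in the spirit of the methods sections of
count-based genomics packages. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The screen model

A pooled CRISPRi screen follows guide abundances through a selection. Guide
*g* carries a per-generation fitness effect *w(g)* (log2 units) determined by
what it silences; after *G* generations its abundance is multiplied by
`2^(w·G)`. Sequencing before and after selection yields counts whose paired
comparison estimates `w·G` as a log2 fold-change (log2FC). Three selections
are supported: growth (17 generations in rich medium by default), phage
infection (survival selection), and cosmid transduction (packaging
selection).

### Coordinates and strand conventions

All coordinates are 1-based and inclusive on the forward axis, as in GFF and
throughout R. A guide's *protospacer strand* is the strand whose 5'→3'
sequence equals the spacer, with the NGG PAM immediately 3' on that strand.
The sgRNA hybridizes to the opposite strand; `targets_coding` is `TRUE` when
that hybridized strand is the gene's sense (coding) strand — the orientation
that blocks the elongating RNA polymerase and gives strong repression.
Deposited guide tables in this field do not state this sequence-level
convention explicitly; the simulator and the analyzer share this single
convention, so all internal contracts are consistent, but anyone comparing
against externally published guide tables should check the orientation
column's meaning.

Guides are assigned to the gene whose interval contains the spacer midpoint
(the 10th base of the forward-axis window; ties broken by smallest left
coordinate, then name). Bacterial chromosomes are treated as circular by
default: protospacer windows may wrap the origin.

## Guide quality control

Four published exclusion rules are implemented exactly:

* **Bad seeds.** Ten 5-nt PAM-proximal sequences (`AGGAA`, `TAGGA`, `ACCCA`,
  `TTGGA`, `TATAG`, `GAGGC`, `AAAGG`, `GGGAT`, `TAGAC`, `GTCCT`) make dCas9
  toxic regardless of target; guides whose spacer ends in one are dropped.
* **Off-targets.** A guide is dropped when its 9 PAM-proximal bases match
  perfectly next to an NGG PAM inside any gene's promoter window, or when its
  11 PAM-proximal bases match in the orientation that hybridizes the sgRNA to
  a gene's coding strand. The promoter window is measured on the gene's
  strand from the first base of the start codon: 100 nt upstream through
  20 nt downstream. The window is described only loosely in the field; this
  definition makes it exact. Both match orientations are checked for the
  promoter rule (the conservative reading). The guide's own on-target site is
  always excluded from off-target matching. Off-target sites are localized by
  the midpoint of the matched k-mer, consistent with gene assignment.
* **Multiple targets.** Guides with more than one perfect 20-nt + PAM site
  are excluded from gene-level scoring but remain available for the separate
  multi-target enrichment analysis (`drop_multi_target` controls this).
* **Read floors.** Guides with fewer than 20 raw reads summed over all
  samples are dropped; phage screens additionally require a BaseMean of at
  least 10. "In total" is interpreted as the sum over every sequenced sample
  of the experiment.

**BaseMean scale.** The control-guide normalization divides counts by the
control guide's reads, which puts normalized values near 1 — while the
BaseMean threshold of 10 clearly refers to the read-count scale. The QC
filter therefore rescales the control size factors to unit geometric mean
(the DESeq2 convention), keeping BaseMean on the count scale without changing
which guide is the normalization factor.

## Fold-changes and significance

`normalize_by_control()` divides each sample by its control-guide count (the
control row becomes 1). `guide_log2fc()` averages per-replicate log2 ratios,
guarded by a pseudocount of 0.5 on the raw-count scale, propagated through
normalization as `0.5 / control_count` per sample. The pseudocount makes the
depth-scaling invariance of log2FC exact only up to `O(ε)`; tests assert it
at 5×10⁻³ absolute.

`nb_test()` is a deliberately transparent stand-in for a DESeq2-style
analysis, not a port. Counts are negative binomial; the extra-Poisson
dispersion of each guide is estimated by the method of moments within each
condition, floored at 0.01. Two choices matter and were made for
calibration, verified on null simulations in the test suite:

1. **Dispersion is estimated on median-of-ratios-normalized counts**, not on
   control-normalized counts. A single control guide is a noisy size factor;
   its sampling noise shifts all log2FCs of a replicate together. Estimating
   dispersion from control-normalized replicate variation would charge that
   shared offset to every guide and roughly triple the variance estimate,
   making p-values severely conservative.
2. **The Wald statistic is computed on per-replicate median-centered log
   ratios** — it asks whether a guide's fold-change differs from the
   library-typical fold-change, which removes the shared normalization
   offset. The reported `log2fc` column remains on the control-normalized
   scale.

Per-guide moment estimates at 3 replicates are noisy, so they are shrunk
25/75 toward the lightly trimmed library mean (the mean, not the median: the
moment estimates are right-skewed and the median undershoots). With these
choices the null type-I error at α = 0.05 sits near 0.055 and the
Kolmogorov–Smirnov distance of the null p-value distribution is ≈ 0.02; both
are asserted by the test suite. Multiple testing uses Benjamini–Hochberg. An
independent cross-check against DESeq2 with control-guide size factors (log2FC
correlation > 0.95) runs in the test suite.

With one replicate, dispersion cannot be estimated; p-values are set to 1
with a warning.

## Gene scoring

Gene statistics are medians and **unscaled** median absolute deviations
(no 1.4826 consistency factor — they mirror the MAD error bars conventional
in these screens) of guide log2FC, split by strand class. Essentiality uses a
strict `median_coding < -2` rule; a gene sitting exactly at −2 is not called.
ROC/AUC against a gold-standard label uses the rank (Mann–Whitney) formula
with midrank tie correction, scoring only genes with at least one
coding-strand guide; the curve is evaluated at every distinct threshold and
the rank-formula AUC equals the trapezoidal integral of that curve (tested).
Fisher's exact test (two-sided, minimum-likelihood) and the guide-set
Mann–Whitney U (normal approximation, tie-corrected) delegate to base R's
`fisher.test`/`wilcox.test`, with independent enumeration oracles in the
tests; `fisher.test` remains exact at p ≈ 10⁻⁵⁰.

## Operon-aware classification

Silencing is polar: dCas9 on one gene silences every downstream gene of its
transcription unit. Within each maximal run of consecutive depleted observed
genes, only the most downstream gene is called *confidently essential*; the
others are *potentially essential* because their depletion may be entirely
polar. A non-depleted gene upstream of a depleted one (no depleted gene
between them) is an *internal-promoter candidate*: the polar effect through
it evidently does not reach the downstream gene, so that gene must have its
own promoter. A subtle point decided here: a depleted gene whose next
observed downstream neighbour is clean is called confident even if a
*further* downstream gene is depleted — the clean gene in between demonstrates
an internal promoter, which also breaks the polar explanation for the
upstream gene. This run-based rule is the only one consistent with the
one-confident-call-per-depleted-run invariant.

Genes with no coding-strand guides are *unobserved*: they are skipped when
scanning downstream (they neither rescue nor demote a call), never called
themselves, and noted in the evidence string. Depleted genes outside any
transcription unit are confidently essential. Transcription-unit definitions
are an input; no operon prediction is performed.

## The transduction model

Packaged-cosmid output tracks guide fitness: guides that slow growth also
slow phage production. To find genes whose silencing disproportionately
reduces functional-capsid output, each gene is tested by the nested OLS
comparison of `y = β₀ + β₁x` against `y = β₀ + β₁x + β₂z` over **all**
retained coding-strand guides, with `z` marking the focal gene's guides —
the only reading under which "the gene, or not" is meaningful; each gene's
fit is independent. `y` is the guide-level transduction log2FC, `x` the
growth-screen log2FC; guides lacking a growth value are dropped from all
fits. The F statistic has 1 numerator degree of freedom, genes are corrected
by Benjamini–Hochberg, and a hit with negative β₂ ("estimate") decreases
capsid production. Guide-level log2FC values (not replicate-level) are the
observations. Degenerate designs are handled explicitly: an all-true or
all-false indicator is an error; a collinear indicator yields p = 1 with a
warning; noiseless fits cap F at 0 (no gene effect) or ∞ (exact effect).

## The simulator

`sim_config()` defines the study conditions; its defaults are the conditions
the analysis is designed for, not tuning knobs:

| Parameter | Default | Meaning |
|---|---|---|
| `generations` | 17 | growth generations between before/after samples |
| `n_genes`, `genome_length` | 200, 200 kb | desk-scale chromosome |
| `library_size`, `depth`, `n_replicates` | 8,000, 10⁶, 3 | guides, reads/sample, paired replicates |
| `fraction_essential`, `fraction_near_essential` | 0.20, 0.10 | label probabilities |
| `coding_effect_mean/sd` | −0.4 / 0.1 per generation | essential-gene cost at full silencing |
| `near_effect_mean/sd` | −0.15 / 0.05 | slow-growth cost |
| `template_effect_scale` | 0.1 | residual repression from template-strand binding |
| `fraction_sensitive` | 0.1 of essentials | genes paying full cost even under weak repression |
| `repression_alpha/beta` | Beta(9, 1) | per-guide repression efficiency (mean 0.9) |
| `bad_seed_penalty` | −0.1 per generation | toxicity of bad-seed guides |
| `dispersion` | 0.05 | negative-binomial overdispersion of counts |
| `abundance_sdlog` | 0.5 | log-normal spread of initial abundances |
| `n_host_factors`, `protection_effect`, `survival_floor` | 10, 0.9, 0.05 | phage screen structure |
| `n_capsid_genes`, `packaging_penalty` | 10, −3 log2 | transduction structure |
| `pregrowth_generations` | 17 | growth with dCas9 induced before infection |

Effect sizes are not published quantities; they were chosen once so that full
silencing of an essential gene over 17 generations yields a log2FC near −7,
matching the depleted tail of real screens qualitatively. Gene lengths are
normal (900 ± 200 nt, floored at 300); transcription-unit sizes are
1 + geometric with mean 2; units pack along the genome with 20 nt intra- and
150 nt inter-unit gaps. Host-factor and capsid gene sets are drawn disjoint
from the non-essential genes so the two screen readouts separate cleanly. A
guide's true effect composes repression efficiency, strand scaling (full for
coding-strand binding or sensitive genes, ×0.1 otherwise), polar propagation
to all downstream unit genes, and the bad-seed penalty. Counts are multinomial
at `depth` per sample, then overdispersed (`dispersion = 0` switches the
second stage off, which is how the depth-conservation test pins the
multinomial stage). The transduction "before" samples are drawn from the
initial pool, as in the experimental design, so growth effects appear in the
transduction log2FC with slope ≈ 1 against the growth screen.

All randomness flows from the mandatory seed; each stage derives a fixed
sub-seed so stages are individually reproducible and reruns are
byte-identical.

**What the simulator does not emulate:** sequencing reads (counts are drawn
directly), PCR jackpotting beyond the negative-binomial stage, guide-specific
activity differences beyond the Beta efficiency, mismatch-tolerant
off-targets, phage population dynamics (survival is a per-guide multiplier,
not an MOI/kinetic model), and real operon topology (units are geometric,
not curated). Passing recovery tests therefore demonstrates that the
pipeline's inference is correct under its own generative assumptions — not
that those assumptions capture every failure mode of real screens.

## Problem sizes and numerical choices

The test suite and acceptance script run the default 200-gene / 8,000-guide
simulation, a 6,000-guide null for test calibration, and a 300-gene null for
the transduction FDR — sizes chosen so the whole validation runs on a laptop
in minutes while leaving the statistical checks well-powered. Tolerances:
OLS oracle equality at 10⁻⁸, Fisher enumeration at 10⁻⁹, planted-effect
recovery at ±0.3 log2 units over ≥ 100 guides, AUC ≥ 0.9 at the fixed default
seed. Ties at the essentiality threshold are not called; AUC ties use
midranks; the dispersion floor is 0.01.

## Limitations

The per-gene transduction model assumes homoscedastic guide-level noise,
which understates variance for strongly depleted guides; the null-simulation
FDR check bounds the practical impact. The single-control normalization
leaves a common offset in log2FC (visible as a run-to-run shift of the whole
distribution) that medians and ranks absorb but absolute log2FC values carry.
The operon classifier sees only coding-strand depletion calls: suppressors,
feedback-regulated genes and toxin/antitoxin pairs need curation it does not
attempt.
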