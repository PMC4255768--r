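---
title: "Fine-mapping multiallelic CNV and testing selection on tandem paralogs"
author: "defensinCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping multiallelic CNV and testing selection on tandem paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(defensinCNV)
})
```

# The problem

Beta-defensin gene clusters are multiallelic copy-number variants (CNVs):
more than two copy-number alleles segregate, diploid totals commonly run
from two to seven, and the variable block sits inside repeat-rich genomic
regions full of unrelated, overlapping CNVs. Two consequences follow.
First, segmentation methods that look for a transition from "diploid" to
"variable" signal cannot delimit the block, because its flanks are not
diploid. Second, no single assay measures copy number well enough on its
own: tiling aCGH is noisy per probe, PCR-based assays are precise but
relative. This package implements the analysis strategy built around
those constraints:

1. **Boundary mapping by correlation** (`probeCnR2()`, `callBlocks()`):
   correlate each tiling-array probe's log2 intensity ratio with an
   independently assayed per-sample copy number. Probes inside the block
   correlate strongly across samples; probes outside do not — *whether
   they sit in diploid sequence or in an unrelated CNV*. The block is the
   maximal run of probes with squared correlation above a threshold.
2. **Breakpoint refinement by HMM** (`hmmSegment()`): Viterbi decoding of
   a Gaussian-emission copy-number-state HMM over a single log2 track,
   with breakpoints reported as inter-probe intervals.
3. **Copy-number integration** (`blockPC1()`, `integrateMethods()`,
   `callIntegers()`): summarize the block's aCGH signal per sample by its
   first principal component, pool it with PRT and ddPCR estimates by a
   second PCA, and round onto the integer scale anchored on ddPCR.
4. **Selection on tandem paralogs** (`partitionVariation()`, `mkTest()`):
   partition coding differences into paralog divergence (between tandem
   copies phased to one haplotype) and allelic diversity (between
   haplotypes at the same copy), Jukes-Cantor-correct each cell, and run
   a McDonald-Kreitman Fisher exact test.
5. **Insertion dating** (`markerWindow()`, `duplicationBracket()`):
   bracket the age of the duplication from diagnostic retroelement
   insertions typed across related lineages with known divergence times.

A synthetic-cohort generator (`simulateCohort()` and friends) reproduces
the statistical structure each stage assumes, so the whole pipeline is
testable end to end without any external data.

# The synthetic cohort generator

`simulateCohort()` draws, for each sample, an integer diploid copy
number uniform over the configured range, and sets the expected log2
ratio of every probe overlapping the block to

$$E[y_{ps}] = a \cdot \log_2(c_s / c_{\mathrm{ref}}),$$

with attenuation $a \in (0,1]$ (default 1) and reference copy number
$c_{\mathrm{ref}} = 2$; i.i.d. Gaussian probe noise is added everywhere.
A sample with zero copies is floored at
$\log_2(0.05 / 2.05)$ rather than $-\infty$ — arrays saturate, and the
exact value is never used quantitatively. Decoy CNVs flanking the block
receive copy numbers drawn *independently* of the block's, which makes
probe-level correlation with block copy number low there by
construction; this is the model of the repeat-rich flanking complexity
that motivates correlation-based boundary mapping in the first place.
An optional dropout element subtracts a fixed delta from a carrier
subset over a sub-interval of the block, emulating a polymorphic
retroelement present in the reference but absent from some genomes.

Two locus configurations ship with the package and define the study
conditions:

* `humanLocusConfig()` — 68 samples, a 322-kb block, copy numbers 2–7,
  400-bp probe spacing over 1 Mb, noise sd 0.15, two decoy CNVs, and a
  2-kb dropout element carried by 12 samples.
* `macaqueLocusConfig()` — 16 samples, a 20-kb block, copy numbers 3–6,
  667-bp spacing (≈1.5 probes/kb) over 982 kb, noise sd 0.25
  (sparser design on a draft assembly, higher background noise), two
  decoys.

Neither platform's true noise magnitude is published; the two defaults
are declared conventions reflecting the relative noisiness of the two
designs, exposed as tunable config rather than claimed as fact.

What the generator does **not** model: dye bias, GC waves, spatial array
artifacts, genome sequence context, linkage between block and decoy copy
numbers, or measurement error structure beyond i.i.d. Gaussian (aCGH)
and lognormal/binomial (assays). Passing tests therefore demonstrate
that the pipeline recovers truth *under its own model assumptions*; they
say nothing about robustness to artifacts the model omits.

All randomness descends from one top-level seed through named substreams
(probes, cohort, per-sample assays, sequences), so identical seed and
config reproduce a cohort bit for bit while changing one stage never
perturbs another.

# Assay models

**PRT.** A paralog ratio test co-amplifies a test locus inside the CNV
and a reference locus outside it with one primer pair; the per-replicate
peak-area ratio estimates relative copy number. `prtCopyNumber()`
averages the five replicate ratios and scales by the reference diploid
count (2, the reference locus being outside any common CNV). Replicates
with a zero reference area are rejected. Simulated ratios carry
mean-corrected lognormal noise (default CV 5%) so their expectation is
exactly $c/2$.

**ddPCR.** Droplets are Poisson-loaded; the fraction of negative
droplets estimates the per-droplet concentration via
$\lambda = -\ln(n_{\mathrm{neg}}/n_{\mathrm{tot}})$ (`ddpcrLambda()` —
the standard digital-PCR inversion, adopted here as a design decision).
Copy number is $2\lambda_{\mathrm{test}}/\lambda_{\mathrm{ref}}$,
averaged over the four replicates that pass the QC rule of strictly
more than 10,000 droplets. The Poisson inversion is what makes ddPCR
*absolute*: the naive ratio of positive counts saturates and is biased
at high loading, while the inverted estimator stays consistent (tested
as mean-squared error, since the saturating naive estimator trivially
has small variance about its biased mean).

**qPCR.** Standard curves (Ct against log10 input of known standards)
give per-assay efficiencies $E = 10^{-1/\mathrm{slope}}$; copy number is
the efficiency-corrected ratio
$E_{\mathrm{ref}}^{Ct_{\mathrm{ref}}} / E_{\mathrm{test}}^{Ct_{\mathrm{test}}}$
normalized against a calibrator sample of asserted diploid copy number.
Without a calibrator the raw ratio is returned, flagged.

# Boundary mapping choices

* **Pearson, not Spearman**: the probe response is modelled as linear in
  the log2 copy-number ratio, so the squared *linear* correlation is the
  right statistic.
* **Zero-variance probes get r² = 0**, not missing: a flat probe is
  evidence against copy-number response, and segmentation should treat
  it as non-supporting rather than ignorable.
* **Thresholds** (r² ≥ 0.5, ≥ 10 qualifying probes, ≤ 20 consecutive
  sub-threshold probes bridged) are declared conventions, exposed per
  config. The gap tolerance serves two purposes: it keeps the human
  block's weakly correlating core section (a shared low-copy repeat)
  inside a single call, and it holds the short macaque block together
  in small cohorts whose drawn copy numbers happen to span little of
  the 3–6 range, where per-probe r² can dip below threshold in runs. A
  narrower tolerance was evaluated and rejected: it traded a rare
  oversize tail (a chance-correlated flanking probe chained onto the
  call) for occasional shattering of the block into sub-threshold
  fragments, which is the worse failure.
* **Edges are the outermost qualifying probes**, and every call carries
  the flanking inter-probe intervals within which the true boundary must
  lie; boundaries are intervals, never point estimates. The estimator is
  consequently biased slightly short (about one probe spacing per edge
  at the packaged noise levels), which the recovery tests account for.
* **HMM**: a univariate Gaussian-emission three-state (loss / neutral /
  gain) model with a conservative inter-state transition probability of
  1e-6, which suppresses single-probe outlier segments that a laxer
  0.01 would chase. This is a deliberate simplification of
  discrete-valued bivariate breakpoint HMMs that additionally model
  sequence features; emissions here are intensity-only. Equal emission
  means are rejected at construction (degenerate decoding).

# Copy-number integration choices

Methods are standardized before the joint PCA (the source procedure does
not say whether they were; standardization makes the integrated score
invariant to per-method affine rescaling, which is testable and true
here). Missing values are mean-imputed within method; constant methods
are dropped with a warning. The integrated score is mapped onto the
ddPCR scale by least squares and rounded, ties away from zero. ddPCR is
the anchor because molecule counting is absolute: its estimates cluster
about integers. Confidence is `1 - 2|score - round(score)|`; note it
reaches 1.0 on noise-free data only when all methods are linear in copy
number — the aCGH PC1 lives on the log2 scale, so even noise-free
cohorts have confidence slightly below 1 while the calls themselves are
exact.

# Selection test choices

* **Multi-hit codons** are classified by averaging over all minimal
  substitution pathways (Nei–Gojobori-style), excluding pathways through
  stop codons when avoidable; fractional counts result.
* **Site denominators** for the Jukes-Cantor correction come from the
  per-codon degeneracy tally (changes to stops count as nonsynonymous),
  averaged over the sequences; correction is applied per cell of the
  2×2 table, with a flag to disable it.
* **Fisher exact, two-sided**, on the corrected table rounded to
  integers (exact tests need counts; the rounding rule is declared and
  tested). The neutrality index
  $\mathrm{NI} = (P_n/P_s)/(D_n/D_s)$ is reported with a direction flag;
  NI < 1 with small p indicates positive selection on the paralogs.
* **Counting layout**: divergence cells average the proximal-vs-distal
  comparison over haplotypes; diversity cells sum the between-haplotype
  comparison over the two paralog positions. In the generator, each
  allelic substitution is placed on one haplotype at one position
  (alternating), so a haplotype's paralog comparison also crosses its
  allelic variants; the generator's truth labels record exactly the
  cells this counting recovers. The positive row correlation this
  induces makes the Fisher test conservative under neutrality (measured
  type-I error well under the nominal level), at some cost in power —
  the regime in which the test is validated (odds ratios ≥ 8) retains
  ≥ 70% power. An alternative placement homogenizing allelic variants
  across both tandem copies was rejected at design time because the
  position-summed diversity row then double-counts every variant and
  inflates type-I error.
* **Variant naming** (`diffAA()`) is 1-based from the initiator
  methionine of the reference protein, reference residue first
  (`G45R`); a premature stop is labelled `X` and flagged. The mature
  beta-defensin peptide corresponds to residues 28–64, but numbering
  stays full-length.
* **Identity** (`pairwiseIdentity()`) uses global alignment with match
  +1 / mismatch −1 / gap open −5 / gap extend −1 (declared defaults),
  gap columns counting as non-matches.

# Insertion dating choices

A diagnostic insertion must postdate the youngest divergence among
lineages lacking it and predate the oldest among lineages sharing it —
that is a marker's origin window. The duplication the insertions
distinguish is bounded below by the largest window minimum and above by
the smallest published subfamily age among the markers (an element
cannot insert before its subfamily was active). When no subfamily age is
known the smallest window maximum stands in; note this fallback is an
upper bound on the *insertions*, which only postdate the duplication —
the two upper-bound rules are not mutually consistent, and restricting
to a marker subset can therefore narrow the bracket when it switches
rules. The tension is inherited from the source logic and implemented
as stated rather than resolved. Lineages where a marker segregates are
encoded present (presence anywhere establishes the marker's age), with
the polymorphism recorded as metadata; unknown statuses are skipped,
never imputed.

The packaged worked example (`defb2lInsertionPanel()`) encodes the
SINE/LINE pair that distinguishes the tandem beta-defensin-2 paralogs:
shared with a lineage diverged ~3 Ma, absent from lineages diverged ~4
and ~10 Ma, SINE subfamily age ~9.5 Ma:

```{r dating}
duplicationBracket(defb2lInsertionPanel())
```

# Numerical and interface conventions

* In memory, intervals are `GRanges` (1-based, closed) — the container
  convention of the surrounding ecosystem; BED/bedGraph files are
  0-based half-open. The dual convention is documented here once and
  exercised by the round-trip tests.
* Every output file opens with comment lines carrying the package
  version, seed and a configuration hash; logs go to messages, results
  to files.
* Intensity matrices are written with 17 significant digits so doubles
  survive the text round trip bit-exactly.
* Viterbi decoding runs in log space; ties in `which.max` resolve to the
  lowest state index (deterministic).

# Problem sizes used in validation

The packaged validation suite simulates 50 human-config cohorts
(68 samples × ~2,500 probes) and 120 macaque-config cohorts
(16 samples × ~1,472 probes) for recovery rates, 1,000 haplotype sets
for the selection test's power and type-I error, 10,000-replicate assay
runs for estimator consistency, and exhaustive path enumeration up to
10 probes × 3 states for the HMM. These sizes give Monte-Carlo standard
errors comfortably below the margins being asserted while keeping the
suite quick to run.

# Known limitations

* Block-size recovery at the macaque scale is limited by per-probe
  correlation power at n = 16: the called block is typically about one
  probe spacing short per edge, and in low-copy-number-spread cohorts
  the call can shorten further. The human configuration (n = 68) does
  not show this.
* The HMM segments one track at a time and models no sequence features;
  it is a breakpoint refiner, not a CNV discovery engine.
* `partitionVariation()` assumes zero homoplasy between the labelled
  classes (reasonable at the observed divergence scales; the
  Jukes-Cantor correction handles multiple hits within a class).
* Real-data workflows (e.g. re-deriving the published selection result
  from archived BAC sequences) are supported by the interfaces —
  `readHaplotypeFasta()` accepts phased, paralog-labelled coding
  sequences from any source — but no external data is bundled or
  fetched.
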