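---
title: "Consensus error correction and likelihood-ratio MRD calling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus error correction and likelihood-ratio MRD calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concatMRD)
```

# The problem

Detecting molecular residual disease (MRD) from plasma means finding
tumor-derived cfDNA at allele fractions of $10^{-5}$ or below. Whole-genome
sequencing compensates shallow depth with breadth — thousands of
tumor-informed markers at 10–100 confirmed molecules each — but only if the
per-base error rate is far below the allele fractions of interest. The
package implements the computational side of a concatemer-sequencing
approach: cfDNA templates are circularized and amplified by rolling-circle
amplification, so a single read pair carries several tandem copies of one
template, and errors can be removed *within* a single read.

# Consensus calling ("repeat confirmation")

Alignments of one read pair are grouped into tandem-copy groups by
reciprocal span overlap (default $\ge 0.9$, configurable): true copies of
one template align to essentially the same interval, while chimeric or
off-target segments do not. Within a group, a position is **repeat
confirmed** when

* only base calls with Phred quality strictly above 24 are considered,
* at least 2 usable copies cover the position, and
* *all* usable copies agree on the base.

A confirmed non-reference base is a presumed template variant; any
disagreement between copies marks a PCR or sequencing error and the
position is discarded. Confirmed reference and variant calls both count
toward **molecule depth**; unconfirmed positions count toward nothing.
Molecules are deduplicated by their fragment endpoints (chrom, start,
end) — the unique-molecule identifier — and conflicting confirmed calls
between duplicates are conservatively demoted to unconfirmed.

Two independent copies reduce an error rate $\varepsilon$ per copy to the
coincidence floor $\varepsilon^2/3$ (both copies must err at the same
position *to the same base*); with three copies, $\varepsilon^3/9$. The
test suite verifies both the complete removal of distinct-position errors
and the quantitative coincidence floor on synthetic reads.

Design choices where the grouping rules were open:

* **Template span**: copies may disagree slightly on their endpoints; the
  modal (most frequent) span defines the molecule, ties broken by order
  after a deterministic sort — output is invariant to input record order.
* **Position-level support**: the ≥2-copy requirement applies at each
  position, not merely to the molecule, which is the stricter reading.
* **Paired-end caveat**: under paired-end 150 bp sequencing, read 1 and
  read 2 of a short single-copy library molecule can masquerade as two
  independent repeats. The default counts copies from both mates (matching
  how paired-end data are ordinarily processed); `strict_single_mate =
  TRUE` requires ≥2 copies within one mate, emulating long single-end
  reads, at the cost of discarding genuinely paired evidence.
* Only substitutions are confirmed; indels and structural variants are out
  of scope throughout.

# The typed error model

Residual background is summarised per collapsed substitution class
$v \in \{$C-T, C-G, C-A, A-T, A-G, A-C$\}$ (purine-reference changes are
reverse-complemented onto this set). For each class,

$$ e_v = \frac{\text{variant molecules observed}}
             {\text{molecules interrogated}} $$

over retained positions. Before counting, three filters are applied, in
this order: positions carrying ≥2 variant molecules are dropped entirely
(such positions are excluded from MRD calls too, and are dominated by
germline/clonal-hematopoiesis signal, not error); the C-T channel at CpG
sites is excluded on either strand (deamination background); and
blocklisted population variants (exact chrom/pos/ref/alt) are excluded
from their channel. A confirmed molecule at a C/G reference position is
counted in the denominators of all three C-* classes (and symmetrically
for A/T); this convention is stated rather than inferable, and the
estimator documents it.

A class with no observed variant molecule reports $e_v = 0$ by default;
the likelihood handles this exactly (see below). An optional conservative
floor $e_v = 1/(3\,d_v)$ can be enabled instead. Position subsampling
(`sample_positions`) mirrors estimating on a random subset of the genome;
the tests check that disjoint subsamples scatter only by binomial noise.

# The MRD likelihood-ratio test

Marker observations are aggregated per class into counts $c_v$ and depths
$d_v$. The model is

$$ c_v \sim \mathrm{Binomial}(d_v,\; p_v), \qquad p_v = \mathrm{VAF} + e_v, $$

with log-likelihood (up to a constant)

$$ \ell(\mathrm{VAF}) = \sum_v \big[ c_v \ln p_v + (d_v - c_v)\ln(1-p_v) \big]. $$

Marker sites with ≥2 variant molecules are excluded (count *and* depth)
before aggregation in a low-burden sample — a single tumor molecule is
the expectation at these allele fractions, while recurring molecules
indicate germline/CHIP contamination. When more than 10% of covered
markers carry ≥2 molecules, a high-burden flag can lift the exclusion
(`high_burden_mode = "auto"`); the 10% trigger is a package heuristic and
is configurable, since no principled constant exists for "exceedingly
high" burden.

**Point estimate.** $\widehat{\mathrm{VAF}}$ maximises $\ell$ subject to
$\mathrm{VAF} \ge 0$. The score
$\sum_v (c_v - d_v p_v)/(p_v(1-p_v))$ is strictly decreasing on the
feasible interval, so the solution is the unique root, found by
safeguarded 1-D root-finding to $10^{-12}$ relative tolerance and clipped
to 0 when the score at $0^+$ is non-positive. If some class has
$e_v = 0$ with $c_v > 0$ the score diverges at $0^+$ and the root is
interior; no artificial floor on $e_v$ is needed.

**Decision.** The null hypothesis — all variant molecules are error —
fixes $\mathrm{VAF}=0$ on the *boundary* of the parameter space, so the
null distribution of
$\Lambda = 2\,[\ell(\widehat{\mathrm{VAF}}) - \ell(0)]$ is the mixture
$\tfrac12\delta_0 + \tfrac12\chi^2_1$. The caller rejects when
$F_{\chi^2_1}(\Lambda) > 0.98$, i.e. a mixture p-value below
$\tfrac12(1-0.98) = 0.01$ and a nominal specificity of 99%. The cutoff is
parameterised as $1 - 2(1-s)$ for nominal specificity $s$.

**Confidence interval.** The 95% likelihood-ratio interval collects the
non-negative VAF values with
$2[\ell(\widehat{\mathrm{VAF}}) - \ell(\mathrm{VAF})] < 3.841$ (the
$\chi^2_1$ 0.95 quantile), located by monotone root-finding on each side
of the MLE: two-tailed for positive calls (whose lower bound is then
always above 0), a one-tailed upper bound for negative calls. The MLE and
both bounds agree with a brute-force grid scan at $10^{-8}$ resolution in
the tests.

# The Monte-Carlo power engine

Each replicate draws, per marker site $i$ of class $v$, a molecule depth
$d_i$ (fixed at the expected depth by default, or Poisson) and a count

$$ c_i = \min\!\big( \mathrm{Bin}(d_i, \mathrm{VAF}) +
   \mathrm{Bin}(d_i, e_v),\; d_i \big), $$

then applies the ≥2-molecule exclusion and the LR test. Detection rate is
the fraction of replicates called positive; specificity is evaluated at
$\mathrm{VAF} = 0$. Both depth laws are implemented because the
molecule-count distribution per site is not uniquely determined by the
description being emulated; the two agree closely at the depths of
interest and the fixed law is the default.

Implementation note: at the rates of interest
($p \sim 10^{-7}$–$10^{-5}$) the engine samples the *total* number of
variant molecules over a block of site–depth trials
($S \sim \mathrm{Binomial}(N, p)$) and scatters them uniformly without
replacement — exactly equivalent to per-site binomials, but touching only
the handful of non-zero sites. This keeps $10^4$ replicates of a
$10^4$-marker test in a few seconds. Replicates are driven by one seeded
RNG stream in fixed-size chunks (rather than per-replicate substreams);
results are bit-reproducible for a given seed and chunking is internal.

Default problem sizes: 10,000 replicates for detection-rate estimates and
5,000 per condition for the specificity surface. These give Monte-Carlo
standard errors of ~0.2 and ~0.15 percentage points near the values of
interest, and run on a laptop-class single core in seconds; much larger
replicate counts change the estimates by less than their standard error.

**A discreteness note on null specificity.** With a uniform error rate
the LR statistic is a function of the total count $C$ alone, so the null
specificity is exactly $P(C < c^\ast)$ with
$C \sim \mathrm{Binomial}(nd, e)$ and $c^\ast$ the smallest integer count
clearing the cutoff. Because $c^\ast$ is an integer, the realised
specificity moves in discrete jumps around the nominal 99% as $nd\,e$
varies: across depths 10–100× it stays between roughly 98.8% and 99.9%
at the error rates studied, with its minimum — 98.75% by exact
enumeration, reproduced in the test suite — at 20× with
$e = 2.8\times10^{-5}$, where the mean error count (5.6) sits least
favourably between integer thresholds. The boundary-null construction is
conservative everywhere else.

# Marker selection

**Plasma-paired (WBC-free) filtering.** Tumor-specific markers are
usually obtained by subtracting white-blood-cell (WBC) variants from the
tumor variant list. The WBC-free workflow subtracts a post-treatment
plasma sample instead: modelling the variant-molecule count at a site as
Poisson with mean $d \cdot \mathrm{cVAF}$, a germline variant
(cVAF 0.5 or 1) at 40–60× is observed in ≥2 unique molecules with
probability $1 - e^{-30}\cdot 31 \approx 1$, while a residual somatic
variant (cVAF < 0.1%) reaches 2 molecules with probability
$\approx 1.7\times10^{-3}$. Removing tumor variants observed in ≥2 plasma
molecules therefore strips germline (and high-frequency CHIP)
contamination while sacrificing a negligible fraction of somatic markers;
CpG C-T variants are removed as well. If the filter removes more than 95%
of the tumor list the function warns: that pattern indicates a
high-tumor-fraction plasma, where most true tumor variants recur and the
workflow's premise fails. The synthetic-cohort tests verify that the
WBC-paired and plasma-paired marker sets produce identical MRD calls and
tightly correlated cVAF estimates.

**Profile-constrained subsampling** draws exactly $n$ markers whose class
composition follows a target profile (largest-remainder quotas, uniform
within class), used to emulate tracking a tumor-like mutation spectrum
with germline SNPs. The packaged default profile
(`synthetic_tumor_profile()`: C-T–enriched) is a synthetic stand-in, not
a measured tumor spectrum; analyses of real data should supply their own
fractions.

**Titration SNP selection** applies five criteria in order (heterozygous
in the test individual and absent in the background; depth 20–100× for
all individuals; undiluted VAF 0.4–0.6; not in a repeat region nor a CpG
C-T; not seen in multiple plasma samples) and reports per-criterion
removal counts. "Absent in the background" is interpreted as hom-ref
genotype *and* zero background alt molecules.

**Depth-equivalent variant counts.** To compare samples sequenced to
different depths at a fixed molecule budget, the number of drawn variants
is scaled to the 60× reference point, $v_i = (60/d_{p_i})\cdot n$,
rounded to the nearest integer (so 2,000 markers at 30× become 4,000).
The sample's genome-wide mean confirmed molecule depth is used for
$d_{p_i}$. The mismatched-tumor specificity procedure draws $v_i$
variants from a pool of *other* patients' tumor variants (drawing errors
if the pool contains the tested patient's own variants), repeats the MRD
test, and reports $1 - \mathrm{FP}/\text{draws}$ per sample and level.

# What the synthetic data do and do not show

The fixture generator emulates: tandem-copy read pairs with independent
per-copy errors and shared template variants (two-point Q20/Q37 quality
distribution to exercise the strict Q>24 filter); endpoint duplicates for
deduplication; plasma pileups under exactly the observation model of the
simulator, with optional germline sites at cVAF 0.5/1; and multi-patient
cohorts with disjoint marker sets and truth labels.

It does **not** model: alignment ambiguity or mapping error, GC and
fragmentation biases, strand-specific damage beyond the CpG C-T channel,
context-dependent (96-channel) error spectra, CHIP variants as a distinct
population, or realistic fragment-length biology. Passing tests therefore
demonstrate the correctness and calibration of the *algorithms* under
their stated model, not assay performance on real plasma; per-sample
error models should always be estimated from the sample itself.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally, 1-based at VCF
  boundaries; alleles are uppercased on input.
* Quality filtering is strictly greater-than (Q>24): a Q24 base is
  ignored.
* MLE root-finding tolerance $10^{-12}$ relative; CI roots to machine
  precision on an interval bounded by $[0, 1 - \max_v e_v)$.
* A marker set whose every site has zero depth raises an explicit error
  (no silent negative); an empty marker set is an error; markers simply
  absent from the pileup contribute zero depth.
* $e_v = 0$ with $c_v = 0$ contributes nothing; $e_v = 0$ with $c_v > 0$
  makes $\ell(0) = -\infty$ and the sample positive at any cutoff.
* Sums of the two binomials are truncated at the site depth (a
  vanishing-probability event at the rates of interest, handled for
  correctness).
* Largest-remainder rounding everywhere an integer allocation is needed
  (profile quotas, depth-equivalent counts), making draws reproducible
  bit-for-bit for a given seed.
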