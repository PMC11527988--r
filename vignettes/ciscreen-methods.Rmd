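---
title: "Methods: directional cis-regulatory pathway tests and upstream divergence screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional cis-regulatory pathway tests and upstream divergence screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscreen)
```

## The scientific problem

In an F1 hybrid between two mouse lineages, both parental alleles of every
gene sit in the same nucleus and are exposed to the same trans-acting
environment. Any reproducible expression difference between the two alleles
therefore reflects genetic variation acting in *cis*. A single gene with
allelic imbalance says little about evolution; but when the genes of one
functional pathway show allelic imbalance that is predominantly in the
*same direction* — one lineage's alleles consistently driving expression up
— that coordination across unlinked loci is unlikely under neutrality and
flags the pathway for selection-focused follow-up. `ciscreen` implements
this expression-based screen, the read-mapping quality control it requires,
and a sequence-based follow-up: a divergence-versus-polymorphism contrast
in transcription-factor binding sites upstream of the pathway's genes,
computed from wild-population VCFs.

Everything is testable end to end because the package ships a synthetic-data
module that generates genomes, annotations, binding sites, population VCFs
and allele-count tables with known ground truth.

## Per-gene allelic imbalance

For gene $g$ with replicate counts $(x_{gi}, n_{gi} - x_{gi})$ for the two
alleles, we test $H_0{:}\ \pi_g = 1/2$ for the allele-1 read fraction. RNA-seq
counts are overdispersed relative to the binomial, so the test is a
beta-binomial likelihood-ratio test: a single intra-class correlation
$\rho$ is estimated genome-wide by the method of moments (each gene's pooled
fraction supplies the mean; the residual second moments are pooled across
genes with a correction for the degrees of freedom absorbed by the per-gene
means), and each gene is then tested by maximising the beta-binomial
likelihood over $\pi_g$ with $\rho$ fixed, comparing against $\pi_g = 1/2$
via a $\chi^2_1$ deviance. When $\hat\rho \le 0$ the model collapses to the
binomial and the exact two-sided binomial test on pooled counts is used
instead. The reported effect is the Haldane-corrected log ratio
$\ell_g = \log_2\frac{\sum_i x_{gi} + 0.5}{\sum_i (n_{gi}-x_{gi}) + 0.5}$,
oriented so that positive values mean the first-named allele is higher.
Genes with fewer than 10 reads total across all replicates and alleles are
excluded before testing.

This stage deliberately replaces a generic count-regression fit with a test
specific to the quantity the screen needs — a calibrated per-gene p-value
and a signed estimate for the allelic fraction. Any externally produced
per-gene table with the same columns can be substituted.

Simulations at the default conditions (2,000 genes, depth 500 per allele,
5 replicates, dispersion 0.05) show the null rejection rate at
$p < 0.05$ within [0.03, 0.07] and the median $\hat\ell$ for genes with a
planted $\ell = 1$ within $\pm 0.15$ of 1; both are asserted in the test
suite.

## The sign statistic and the pathway resampling test

Each tested gene receives a sign statistic

$$ s_g = \begin{cases} \ell_g & \text{if BH-adjusted } p_g < \alpha \\ 0 & \text{otherwise,} \end{cases} $$

with $\alpha = 0.05$ by default. For a gene set $T$ with $n$ members in the
tested universe, the observed statistic is $S_{\mathrm{true}} = \sum_{g \in T} s_g$.
Significance is empirical: $B = 10{,}000$ times, $n$ genes are drawn without
replacement from the full tested universe (zeros included) and their $s$
summed; the two-sided p-value is the proportion of resamples with
$|S_{\mathrm{resample}}| \ge |S_{\mathrm{true}}|$, ties counting as extreme.
The plain proportion can be exactly zero; an optional add-one smoothed
estimator $(1+k)/(1+B)$ is available but off by default. Terms with fewer
than 10 genes carrying a nonzero $s$ are dropped before testing, and the
surviving terms are Benjamini-Hochberg corrected. The resampling pool is
the full universe of genes with usable data (those surviving the low-count
and mapping-bias filters); the focal term's own genes are not excluded from
the pool — with thousands of genes the difference is negligible, and a flag
would only complicate the contract.

Directional reports summarise a set as the percentage of (significant)
genes whose effect points each way and their ratio; the same operation
applies unchanged to any signed-effect/adjusted-p table, e.g. a
knockdown-versus-control differential-expression table.

## Mapping-bias quality control

Allele-specific counts are vulnerable to reads that map more reliably to one
allele's sequence. The QC simulates error-free reads uniformly from each
allele's transcripts (about 200 per transcript per replicate, 2 replicates)
and looks each read up in an exact substring index over the concatenated
two-allele transcript set. A read maps if it occurs at exactly one
location, or at exactly two locations that are the two orthologous copies of
its own gene — shared sequence between true homologs still maps uniquely
per locus, as in best-match alignment to a diploid reference. Any other
multi-location match is ambiguous and discarded. Reads are simulated and
matched in the sense orientation only; with both the reads and the index
built from the same strand of the same transcript models, reverse-complement
hits cannot arise. Mapping fidelity is the percentage of simulated reads
that map, per gene and allele; genes whose absolute fidelity difference
between alleles exceeds 5 percentage points (strictly) are removed.

## TPM normalisation

Counts are divided by transcript length in kb and scaled so each sample
sums to $10^6$. All-zero samples are flagged and left at zero; a missing
length for an expressed gene is an error rather than a silent drop.

## Upstream windows and representative transcripts

"Upstream" is strand-relative: for a transcription start site $t$ (1-based)
the window is $[\max(0, t-1-w),\ t-1)$ on the plus strand and
$[t,\ \min(L, t+w))$ on the minus strand, in 0-based half-open coordinates,
with $w = 50$ kb by default and clipping at chromosome edges. The TSS is
taken from one representative transcript per gene: among transcripts whose
spliced CDS is a valid ORF (starts ATG, ends in a stop, length a multiple
of three, no internal in-frame stop), the longest CDS wins, with ties broken
by lexicographically smallest transcript id for determinism. Genes with no
valid ORF are excluded. Binding-site intervals are intersected with the
window as a union of positions (overlapping sites count once), and the
window partitions exactly into in-site and out-of-site positions.

## Pseudogenomes and the divergence/polymorphism contrast

From each population VCF, every individual yields two haploid pseudogenomes
against the reference: one resolving heterozygotes to the alternate allele,
one to the reference allele. Only bi-allelic SNVs are substituted (indels
are skipped with a warning — position-wise classification needs a fixed
coordinate frame); missing genotypes leave the position uncalled for that
individual. For a focal-versus-sister comparison, a position is
*fixed-divergent* ($D$) when all called focal haplotypes share one base, all
called sister haplotypes share one base, and the two differ; *polymorphic*
($P$) when two or more bases segregate within either population; invariant
otherwise. Positions with fewer than two called haplotypes in either
population are unclassifiable and skipped. Counts are accumulated inside
and outside each regulator's in-window site positions, separately under the
two heterozygote modes, and averaged — the per-mode classification is
averaged (not re-classified after averaging), so half-integer counts are
possible and expected.

Only positions carrying a VCF record in either population can be
non-invariant, so the production path classifies just those candidates; the
test suite asserts exact equality with an exhaustive every-position scan on
a 100 kb fixture.

## The regulator screen

Per regulator, each (gene, category, comparison) triple contributes one
observation of normalised divergence $D_u/P_u$ (observations with
$P_u = 0$ are dropped rather than pseudocounted; a `pseudocount` argument
exists for sensitivity analysis). A two-factor ANOVA with interaction is
fitted — binding-site identity (in/out) crossed with membership in the
focal gene set — using the focal-versus-sister comparisons as replicates,
and the interaction p-value is reported with BH correction across
regulators. The odds ratio is the classic interaction contrast of cell
means, $(\bar m_{\mathrm{in,set}}/\bar m_{\mathrm{out,set}}) /
(\bar m_{\mathrm{in,other}}/\bar m_{\mathrm{out,other}})$; this is a
declared definition, not a claim about how any particular published OR was
computed. The response is analysed on the raw ratio scale by default
(`log_response` is available; the OR is always reported on the ratio
scale). $D$-only and $P$-only variants divide the counts by category length
in bp instead of forming the ratio. An interaction sum of squares that is
numerically zero relative to the data reports $p = 1$ rather than a
degenerate F ratio.

## What the synthetic data emulate — and what they do not

The generator plants known truth at every level:

* **Allele counts.** Gene-level negative-binomial counts
  (var $= \mu + \alpha\mu^2$, $\alpha = 0.05$) whose total mean
  $2 \times \mathrm{depth}$ is split between alleles as
  $2^d/(1+2^d)$, so a planted $d$ gives expected allelic ratio exactly
  $2^d$. Defaults: 2,000 genes; a 60-gene pathway of which two thirds
  favour allele 1 at $d = 1$ and one third favour allele 2 — so the
  expected directional ratio among significant pathway genes is 2, the
  regime the screen is meant to detect; depth 500 per allele; 5 replicates.
* **Genome and annotation.** One chromosome; genes tiled with spacing
  $> 2w$ so windows never overlap (this keeps every position's gene
  assignment, and hence the counting oracle, unambiguous); alternating
  strands; per gene one single-exon transcript with a valid ORF plus,
  cyclically, a spliced second transcript that is either longer-and-valid
  or longer-but-broken, so transcript selection is exercised in both
  directions.
* **Binding sites.** Each regulator receives the same number of
  equal-length sites per window, placed with jitter inside per-regulator
  sub-slots, so different regulators' site sets are *disjoint*. A planted
  enrichment is then attributable to exactly one regulator and the others
  are exactly null in-site. Real ChIP compilations overlap heavily; that
  realism is deliberately traded for an unambiguous null.
* **Population variation.** Within-population polymorphisms are drawn per
  population at 0.025/bp with Hardy-Weinberg genotypes (conditioned to
  segregate — at least one alternate allele and one homozygous-reference
  individual — so a "polymorphic" site can never masquerade as a fixed
  difference under either heterozygote mode), and explicit heterozygotes
  exercise both pseudogenome modes. Fixed differences are drawn
  *independently per sister population* at 0.004/bp (times the enrichment,
  default 3, inside focal-regulator sites at pathway genes), with the
  derived allele on the sister lineage. The contrast is symmetric in which
  lineage carries the derived allele, and this choice makes each
  focal-versus-sister comparison an independent replicate of the stated
  rates — planting shared focal-lineage alleles instead would make the six
  "replicates" copies of one realization and invalidate the ANOVA's
  error estimate. The polymorphism:divergence ratio of ~6:1 matches the
  wild-mouse regime in which within-population diversity far exceeds
  between-subspecies fixed differences; it is also the regime in which the
  shared (focal-side) component of $P_u$ leaves the $D/P$ observations
  nearly uncorrelated across comparisons, keeping the F-test calibrated.

Not emulated: linkage disequilibrium (the statistics are per-position, so
LD is irrelevant to what is tested), coalescent demography, indels,
sequencing errors or fragment-level read simulation, GC/length bias, and
overlapping regulator sites. Passing tests therefore demonstrate the
correctness and calibration of the *statistics and plumbing*, not
robustness to every property of real data.

## Problem sizes used by the tests and acceptance script

Simulation-based checks run at desk scale, chosen to preserve the
statistical regime of the full-size screen: the expression-side checks use
the default 2,000-gene universe; the population-genomic recovery checks use
24 genes with 24 kb windows and 400 bp of sites per regulator per window
(sites ~1.7% of the window, as the 50 kb screen has sites in the low
percent range; expected per-comparison counts per category,
$D \approx 1.6$-$4.8$ and $P \approx 20$, match the scale at which the
ratio's distribution is well behaved), with 20 independent simulation
repeats for recovery rates. The exhaustive-scan equivalence check uses a
~100 kb fixture so the brute-force oracle stays fast.

## Numerical choices and degenerate inputs

* Likelihood maximisation over the allelic fraction uses golden-section
  search on $[10^{-6}, 1-10^{-6}]$ with tolerance $10^{-9}$; the LRT is
  clamped at zero so optimizer jitter can never produce a negative deviance.
* Resampling ties are compared with a $10^{-12}$ slack so floating-point
  noise cannot drop a tied resample.
* The Fisher odds ratio applies the Haldane $+0.5$ to every cell only when
  some cell is zero; a zero margin returns `NA`.
* Empty gene-set collections, windows without variants, all-zero samples
  and terms with no universe overlap all return well-formed empty/zero
  results with a warning or log message rather than erroring.
* Every generator draw runs under seeds derived from the single master
  seed, and emitted files are byte-identical across runs of the same
  configuration (asserted in the tests).

## Known limitations

* The genome-wide overdispersion is a single shared $\rho$; genes with
  atypical allelic variance are approximated. With one replicate the test
  reduces to the exact binomial, which ignores biological replication
  entirely (as any single-replicate analysis must).
* The ANOVA treats comparisons as exchangeable replicates and ignores the
  residual correlation induced by shared focal-population polymorphism;
  under the default rates this inflation is small (measured null rejection
  ~0.07-0.09 at nominal 0.05) but it grows if divergence is dense relative
  to polymorphism.
* The screen's OR definition is one reasonable interaction contrast among
  several; comparisons across analyses should use the same definition.
* The mapping QC models mappability of error-free reads only; it cannot
  flag biases that arise from sequencing error interacting with variant
  positions.
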