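---
title: "Detecting artificial selective sweeps between inbred lines with sweepHKA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificial selective sweeps between inbred lines with sweepHKA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepHKA)
```

## The problem

When an inbred line is derived from a base population by phenotype-driven
selection — the canonical example being the Goto-Kakizaki (GK) diabetic rat,
bred from glucose-intolerant Wistar founders — the loci that drove the
selection are expected to sit in genomic segments where one founder haplotype
went to fixation. Relative to the control line, such segments are enriched
for **fixed differences** (every animal homozygous for the same non-reference
allele while the control line matches the reference) and depleted of
**polymorphism**. `sweepHKA` detects these putative artificial selective
sweep (PASS) regions from a joint multi-sample VCF of the two lines, and
carries the supporting analyses through to a candidate gene list.

## The scan statistic

For two populations A and B, every retained variant site is classified into
one of eight mutually exclusive classes (fixed difference in A or in B,
polymorphic in one or both, shared fixed alternate, monomorphic reference,
or uninformative). A site is retained only when at least `minCalledA`
(default 10 of 12) samples in A and `minCalledB` (default 9 of 11) in B have
a fully called diploid genotype; this guards against sites that merely look
fixed because low-coverage animals dropped out. "Called" means a non-missing
GT — read depth is deliberately not consulted, since the retention filter
exists to exclude missing calls, not to re-do genotype QC.

The genome is scanned in 50-kb windows advanced in 10-kb steps (anchored at
coordinate 0 on each chromosome; terminal windows are truncated). Each
window contributes a 2x2 table

$$\begin{pmatrix} F_A & P_A \\ F_B & P_B \end{pmatrix}$$

of fixed and polymorphic site counts per population, and the null hypothesis
of homogeneity, $P_A/F_A = P_B/F_B$, is tested in the spirit of the
HKA test's fixed-versus-polymorphic contrast. Two test routes are provided:
Fisher's exact test (default) and Pearson's chi-square without continuity
correction. The exact test is the default because inbred lines leave very
few polymorphic sites per window, which is exactly the regime in which the
chi-square approximation is least trustworthy.

Numerical conventions, fixed here because degenerate windows are common:

* a table with a zero row or zero column carries no information about the
  ratio and is assigned p = 1;
* such untestable windows are excluded from the Bonferroni family, so the
  correction multiplies by the number of *tested* windows;
* significance is strict (`p_adj < alpha`, default 0.05); a tie at alpha is
  not significant;
* direction matters: a significant window is a PASS candidate only when the
  excess fixation is in the selected line, operationalized as
  $F_A P_B > F_B P_A$ (odds ratio toward A) together with
  $F_A > k\,F_B$ (default fold requirement $k = 1$, tunable via
  `minFRatio`). The published description of the requirement ("far more
  fixed differences in the selected line") is qualitative; this pair of
  inequalities is the package's fixed operationalization.

Selected windows are merged per chromosome with bedtools-style bookended
merging (distance 0), yielding disjoint PASS regions annotated with the
number of merged windows and the minimum adjusted p.

## Supporting statistics

Three per-window (non-overlapping 10-kb) tracks reproduce the usual
sweep diagnostics:

* **Tajima's D** per population, with the 1989 constants. Conventions: the
  haploid sample size of a window is twice the *minimum* called-sample count
  across its retained sites; per-site heterozygosity uses each site's own
  called allele frequencies; windows with no segregating site (or fewer than
  4 haplotypes) are reported as `NA` rather than 0, and excluded from
  summaries. Sweeps depress diversity and skew the residual spectrum toward
  rare variants, so D inside swept regions should sit below D outside.
* **Weir–Cockerham Fst** between the two lines, per site from the 1984
  variance components (summed over alleles, so multiallelic sites
  contribute), aggregated both as the ratio-of-sums ("weighted") estimate
  and as the mean of per-site estimates. Negative per-site estimates are
  retained unclamped, as is standard for this estimator. Both variants are
  emitted because "mean Fst" plots and VCFtools-style weighted estimates
  differ exactly where sites are sparse.
* **Fixed-variant density** per kb and population; truncated terminal
  windows use their actual length.

## Codon-level effects and SAAC genes

Fixed variants of each population are annotated against a gene model
(GFF3/GTF CDS features; one transcript per gene, the longest CDS, a common
gene-based simplification). SNVs in CDS are classified by substituting the
alternate base into the reference codon in transcript orientation and
translating with the standard code — SYNONYMOUS, NONSYNONYMOUS, STOPGAIN,
STOPLOSS, with `G86R`-style amino-acid-change notation; a variant that
retains a stop codon is synonymous. CDS indels are FRAMESHIFT when the
length change is not a multiple of 3, NONFRAMESHIFT_INDEL otherwise. SNVs
within 2 bp of a CDS edge are flagged SPLICE_REGION but excluded from the
amino-acid-changed definition. A gene is *amino acid changed* in a
population when it carries at least one amino-acid-altering fixed variant
there; the **SAAC** (specific amino-acid-changed) sets are the two set
differences. The test suite verifies every CDS SNV call against an
independent oracle that applies the variant to the whole CDS and diffs the
translated proteins.

## Expression integration

Raw counts are TPM-normalized, transformed to `log2(TPM + 1)` (a variance
stabilization conventional for regularized t testing; raw-TPM mode is a
flag), and tested per age stage with a Bayes-regularized paired t statistic:
the per-gene SD of paired differences is shrunk toward a background SD
estimated as a running mean over `window = 101` genes ranked by mean
expression, with `v0 = 10` prior pseudo-observations:

$$\sigma_p^2 = \frac{v_0\,\sigma_0^2 + (n-1)\,s^2}{v_0 + n - 1},
\qquad t = \frac{\bar d}{\sigma_p/\sqrt n},\qquad
\mathrm{df} = v_0 + n - 1.$$

The denominator and degrees of freedom use $v_0 + n - 1$ rather than the
$v_0 + n - 2$ seen in some regularized-t formulations: with this convention
the prior vanishes cleanly — at $v_0 = 0$ the statistic, p-value and df are
*exactly* the classical paired t-test — which makes the regularization an
honest superset of the unregularized analysis and is enforced to 1e-10 in
the tests. Genes are flagged by Benjamini–Hochberg FDR < 0.05 at any stage.
The final candidate set is
`marked ∩ SAAC ∩ (PASS-overlapping ∪ differentially expressed)`,
with gene–region overlap at the 1-bp threshold.

## What the synthetic generator emulates

`simConfig()` / `simulateWorld()` build a complete seeded test world: a toy
genome (2 chromosomes x 2 Mb) with 120 protein-coding genes (1–3 CDS exons,
both strands, clean ATG…stop sequences), two diploid inbred populations of
12 and 11 samples from a shared founder pool, planted 200-kb sweeps (one per
chromosome) where founder sites become fixed in population A with
probability 0.9, a QTL catalogue covering the sweeps plus decoys, and a
paired 3-stage expression matrix with 10 planted DE genes at |log2 FC| = 2.

Choices that deserve justification:

* **Founder site density = 2.5 sites/kb.** This matches the per-kb density
  of the retained variant set in deep resequencing of an inbred rat pair
  (~7 million variants over a ~2.8-Gb genome). It also matters for power: at
  1 site/kb the expected per-window fixed count sits close to the Bonferroni
  detection boundary once residual heterozygosity is applied, and recovery
  of planted sweeps becomes erratic — an artefact of an unrealistically
  sparse toy genome, not of the method.
* **Residual heterozygosity 4% per sample per site, inbreeding coefficient
  0.85 at polymorphic sites.** Together these put per-sample homozygote
  rates in the low nineties, the regime reported for inbred rat lines.
  Note the noise is applied uniformly — including to planted fixed sites —
  so roughly $1 - 0.96^{23} \approx 61\%$ of planted fixed differences
  survive observation as fixed; the scan must (and does) detect sweeps
  through that erosion.
* **Sweep residuals carry rare alleles** (alt frequency ~U(0.04, 0.22)
  versus U(0.2, 0.8) outside), emulating the rare-variant skew of post-sweep
  recovery; this is what makes Tajima's D inside sweeps visibly negative.
* **NB dispersion 0.1** for expression — within-line biological variability
  of technical-replicate-like inbred animals; pairs share a lognormal
  library factor so that pairing is informative.
* **Planted coding variants**: every sweep gene receives one guaranteed
  amino-acid-changing fixed-in-A SNV (verified at generation time by the
  translate-and-diff oracle), and two background genes receive fixed-in-B
  ones, so SAAC set logic is exercised on every world.
* Sites are simulated independently (no linkage); the scan statistic is a
  per-window count, so haplotype structure would add realism the tested
  statistics cannot see.

What passing on this generator does **not** show: robustness to linkage
disequilibrium structure, to calling artefacts correlated with mappability,
to reference bias, or to population stratification within a line — real
data properties the generator does not emulate.

## Problem sizes used in the checks

The bundled checks run the complete pipeline on the default 2 x 2 Mb world
(~10,000 variant sites, ~400 scan windows), verify family-wise error control
on 50 seeded sweep-free 1-Mb genomes, verify sweep recovery (per-interval
Jaccard >= 0.5, no stray calls beyond one window) on 10 seeded default
worlds, and compare the exact test against full hypergeometric enumeration
for every 2x2 table with row sums up to 12. These sizes keep the whole suite
a few minutes long while leaving each property comfortably away from its
decision boundary.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
w <- simulateWorld(cfg, dir = "world")
res <- runSweepPipeline(vcf = w$paths$vcf, popmap = w$paths$popmap,
                        fasta = w$paths$fasta, gff = w$paths$gff,
                        qtlBed = w$paths$qtlBed, counts = w$paths$counts,
                        pairing = w$paths$pairing,
                        markedGenes = w$paths$marked, outdir = "out")
res$pass                     # two PASS regions, one per planted sweep
res$integration$candidates   # marked SAAC genes backed by PASS or DE
```

## Known limitations

* Classification is diploid-only; haploid or polyploid GT fields are
  rejected rather than coerced.
* One transcript per gene: genes whose transcripts disagree on a variant's
  consequence are summarized by their longest CDS only.
* Two populations fixed for *different* alternate alleles fit neither
  fixed-difference definition and are set aside as uninformative; a
  three-way divergence analysis is out of scope.
* The Bonferroni family is the set of testable windows of one scan; if you
  scan several datasets, correct across scans yourself.
* Fst and Tajima's D are descriptive tracks here; no significance is
  attached to them.
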