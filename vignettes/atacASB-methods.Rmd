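---
title: "Detecting allele-specific TF binding from ATAC-seq footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific TF binding from ATAC-seq footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacASB)
```

## The problem

A transcription factor (TF) bound to open chromatin shields its recognition
site from the Tn5 transposase, leaving a local depletion of cut sites — a
footprint — inside an otherwise accessible region. At a heterozygous SNP
inside a TF motif, the two alleles of the same cell population are assayed
in the same library under identical technical conditions. If the variant
weakens (or strengthens) TF binding, the footprint depth differs between
the reads carrying the reference and the alternative base. atacASB detects
this allelic difference, scores the predicted motif disruption, and
connects candidate regulatory SNPs to target genes and allele-specific
expression.

Because the signal is a *within-locus contrast between alleles*, the
approach is insensitive to Tn5 sequence preference, to the intrinsic
footprint shape of a TF family, and to copy-number imbalance — all of which
affect both alleles equally at a single locus.

## Site geometry

Around every motif match containing a heterozygous SNP we partition the
neighbourhood into:

* the **footprint** `a`: the motif-match span itself;
* two **shoulders** `b` of `shoulder` bp (default 10) on either side,
  excluded from the model — they absorb the fuzzy footprint boundary and
  TF-to-TF variation in effective footprint width;
* two **flanks** `c` of `flank` bp (default 50) beyond the shoulders,
  representing locally accessible background.

The defaults are a compromise: shoulders much wider than ~10 bp discard
signal, much narrower ones let smeared footprint edges contaminate the
flanks; 50 bp flanks stay inside a typical peak while giving the background
cell roughly four times the bases of a 10–15 bp motif. Both are
configurable everywhere they appear.

Cut sites are computed from alignments with the standard ATAC offset: +4 bp
for forward-strand reads, −5 bp from the last aligned base for
reverse-strand reads, so each coordinate marks the centre of a transposition
event. Reads marked duplicate or with mapping quality 0 are dropped.
Each read is assigned to an allele by its base at the SNP (base quality ≥
20 by default); mismatching or low-quality bases stay unassigned and are
tallied but never modelled.

## The count model

For one candidate site let `y` be the number of cut sites in a cell of the
design: region (`x_r` = 0 footprint, 1 flank) by allele (`x_a` = 0
reference, 1 alternative) by replicate. We model

    log E(y) = b0 + b_r x_r + b_a x_a + b_int x_r x_a

with a negative-binomial (NB2) distribution to absorb overdispersion
between replicates. `b0` is the log footprint depth on the reference
allele, `b_r` the log flank-to-footprint ratio (the footprint strength),
`b_a` a global allelic coverage imbalance, and `b_int` — the parameter of
interest — the allelic difference in footprint strength. The null
hypothesis is `b_int = 0`; a positive estimate means the variant allele has
a relatively deeper footprint (gain of binding), a negative one a loss.
Replicates enter as independent observations (4 rows per replicate); no
library-size offset is applied by default because both alleles come from
the same library and the offset cancels from the interaction.

### Fitting

Coefficients are estimated by iteratively reweighted least squares with a
log link. With a single replicate the model is saturated: fitted means
equal the observed counts and `b_int` is the log cross-ratio
`log((y_a,ref * y_c,alt) / (y_c,ref * y_a,alt))`; the dispersion is then
unidentifiable and the Poisson limit is used. Estimated dispersions below
1e-8 likewise collapse to Poisson. Sites where one allele has no phased
coverage, or where a whole design cell margin is zero (complete separation,
so the interaction is infinite), are reported with a reason and excluded
rather than given a fabricated finite estimate.

### Dispersion: common across sites by default

With the three replicate libraries typical of ATAC designs, a site
contributes only `4R − 4 = 8` residual degrees of freedom. Estimating the
NB dispersion per site from 8 df makes the downstream Wald test unusable:
the normal-reference test is strongly anticonservative (we measure ~14%
rejections at a nominal 5% with naive per-site maximum likelihood, ~8%
even with the Cox–Reid adjustment), while widening the reference to a
t-distribution restores calibration at a severe cost in power. We therefore
estimate a single **common dispersion** shared by all candidate sites, by
maximising the sum of per-site Cox–Reid adjusted profile likelihoods —
pooling hundreds of residual degrees of freedom, as established count-model
packages do for small-replicate designs. This is a plain pooled estimate,
not empirical-Bayes shrinkage: no site-specific estimates are moderated
toward a prior. Cut-site dispersion at a given locus is dominated by
library-level technical variation, which is shared across loci, so a
common value is the right first-order model; a per-site mode
(`dispersion = "site"`) remains available and then uses a t reference with
the site's own residual df.

### Testing

The default test is Wald: `z = b_int / se(b_int)` with the standard error
from the expected information at the estimated dispersion, referred to a t
distribution whose degrees of freedom are those behind the dispersion
estimate. With the common dispersion pooled over hundreds of sites this is
effectively the standard normal, and the test holds its nominal level (the
acceptance suite verifies 5% ± 1.5% on 2,000 null sites). A
likelihood-ratio test (`test = "lrt"`) is available and agrees with Wald on
well-powered data. P-values are adjusted with Benjamini–Hochberg across all
sites with a converged fit in the dataset.

## Motif disruption

Motif count matrices (JASPAR pfm format) become position-specific scoring
matrices by `log2((count + pc_b) / (total + pc) / background_b)` with a
total pseudocount of 0.8 split proportionally to the background
(uniform by default) — the common JASPAR convention. Both haplotypes of
each open-chromatin region are scanned on both strands; the match threshold
is the smallest log-odds score whose exceedance probability under the
background model is at most 1e-4, computed by exact dynamic-programming
enumeration of the score distribution (discretised to 1e-3 log2 units).
This mirrors the p-value semantics of standard motif scanners without
importing their full machinery. When both strands pass at one locus only
the higher-scoring strand is kept (ties to `+`) so a physical site is
counted once; an exhaustive both-strands mode supports verification against
a naive scan.

For each (SNP, match) pair with the SNP inside the match span, the
disruption score is `deltaPSSM = PSSM(ref) − PSSM(alt)` on the
motif-aligned haplotype windows (reverse-complemented for minus-strand
matches). Only the focal SNP is substituted when building the alternative
window; neighbouring heterozygous SNPs inside one window are left on the
reference haplotype — a deliberate simplification, acceptable at typical
het-SNP densities and flagged as a limitation below.

## Second-round filter

A call survives the empirical filter only if all of the following hold:

* `q < 0.05` (Benjamini–Hochberg);
* `|deltaPSSM| > 5`;
* **sign consistency**: `b_int × deltaPSSM < 0`. A gain of binding on the
  variant allele (`b_int > 0`) must pair with the variant allele scoring
  higher (`deltaPSSM < 0`), and vice versa;
* allelic **magnitude** `|log2((A_ref/A_alt) / (C_ref/C_alt))| ≥ 1`, where
  `A`/`C` are footprint/flank counts summed over replicates with a
  pseudocount of 1. The magnitude cut quantifies the otherwise vague
  requirement of a "high-magnitude" allelic difference; 1 log2 unit (a
  two-fold allelic change in the flank-normalised footprint ratio) is the
  default and can be lowered to 0 to disable the gate. It is reported as a
  separate column so users can re-threshold without refitting.

Every excluded call keeps machine-readable reason codes (`fdr`, `delta`,
`inconsistent`, `magnitude`, `unconverged`).

## Target genes, eQTL overlap and allele-specific expression

A regulatory SNP within 1 kb (inclusive) of any transcription start site is
classified as a promoter variant and assigned the closest gene (ties broken
by distance, then lexicographic gene id, for determinism); distance is
measured to the TSS position regardless of gene strand. The remaining SNPs
are enhancer candidates: every chromatin-interaction record whose anchor
contains the SNP contributes the genes of the paired anchor, unioned over
records. eQTL overlap is matched by rsID when available, otherwise by exact
position. Enrichment of regulatory SNPs among eQTLs is tested with a
Pearson chi-square on the 2×2 table, without continuity correction by
default.

Allele-specific expression at coding het SNPs of target genes uses the
exact binomial test against Binomial(N, 0.5), two-sided by the
minimum-likelihood ordering. A gene is ASE-positive when any of its SNPs
has `p < 0.05`; replicate libraries are summed before testing. No
multiple-testing correction is applied across genes by default (a BH option
exists), matching the plain-threshold convention for this confirmatory
step.

## The simulator

`simulate_dataset()` generates every pipeline input with known truth: a
uniform-background chromosome with one strong planted motif instance per
site (97% consensus per column, so the planted SNP changes the score by
more than 5 log2 units), a heterozygous SNP inside each motif span, count
tables drawn from exactly the NB interaction model above, and — in
read-level mode — coordinate-sorted SAM records whose shifted,
allele-assigned cut sites reproduce the drawn counts identically. Cut
positions are placed uniformly within their region, which is free of
consequence because the model conditions only on region totals. At ASB
sites the sign of the true interaction is set opposite to the planted
deltaPSSM, alternating gain and loss, so simulated truth is
sign-consistent by construction.

Defaults (`sim_config()`): 100 sites, 30% ASB, effect 1.5, flank mean 50
cuts per allele per replicate, footprint depth 2, dispersion 0.1, 3
replicates — a deep modern ATAC experiment on a cell line, matching the
three-library designs the model is meant for. The generator shares the
model family with the fitter by design, which makes parameter recovery a
meaningful test of the inference; it does *not* emulate Tn5 sequence bias,
mapping bias toward the reference allele, copy-number imbalance, or
correlated neighbouring sites. Passing tests therefore demonstrate the
statistical machinery, not robustness to those real-data artefacts (the
first two are mitigated by the within-locus design; the last two are out
of scope).

Problem sizes in the test suite (2,000 null sites for calibration, 500
sites for effect recovery, a 100-site end-to-end run) were chosen so the
Monte-Carlo error of each check is small relative to its tolerance while
the whole suite stays convenient to run routinely.

## Numerical choices and degenerate inputs

* IRLS convergence at 1e-10 on the max coefficient change; dispersion
  updates alternate with coefficient updates until joint convergence.
* The dispersion search is on `log(theta)` over `[1e-4, 1e8]`; hitting the
  upper bound is treated as Poisson.
* Empty count cells are fitted as NB zeros without pseudocounts; only
  structural degeneracies (dead allele, zero cell margin) exclude a site.
* The PSSM enumeration threshold returns `Inf` when no score reaches the
  requested p (short motifs cannot be rarer than `4^-L` under a uniform
  background); callers then find no matches rather than spurious ones.
* All internal coordinates are 0-based half-open; VCF positions are
  converted on input (1-based) and output follows each format's convention.

## Known limitations

* One focal SNP per motif window; nearby het SNPs are not jointly phased.
* The common dispersion assumes exchangeable technical variation across
  sites; strongly site-specific overdispersion (e.g. CNV boundaries) is
  better served by `dispersion = "site"` at a power cost.
* rsID resolution, LD structure, and live database retrieval are out of
  scope; annotation joins operate on user-supplied flat tables.
* The binomial ASE test inherits reference-mapping bias from the supplied
  allelic counts; counts should come from a bias-aware counter when that
  matters.
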