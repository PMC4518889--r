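---
title: "Methods: variant-aware probe masking and the eQTL direction diagnostic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-aware probe masking and the eQTL direction diagnostic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmask)
```

# The artifact and the correction

A microarray probe reports hybridization of cDNA complementary to a ~25 nt
reference-genome sequence. A genome variant under the probe weakens binding,
so the probe under-reports expression in precisely the samples that carry
the variant. Because carrying the variant is a genotype, the artifact is
statistically indistinguishable — within one experiment — from a *cis*-acting
eQTL where the variant allele lowers expression. The correction implemented
here is deliberately conservative and requires no expression data at all:
any probe whose footprint intersects any variant in the supplied VCF(s) is
removed from its probeset before summarization, and probesets losing all
probes are removed from the platform annotation.

Two assumptions matter. First, the variant catalogue is taken at face
value: a probe is removed even when its SNP sits near the probe's end where
hybridization may be barely affected; position-within-probe weighting is
deliberately not modeled, trading some probes for the guarantee that
surviving probes are bias-free. Second, only footprint-bearing variants in
the VCF can be corrected; unlisted variants, copy-number changes and
systemic strain differences in gene families remain uncorrected.

# Coordinate and filtering conventions

* VCF positions are 1-based; probe BED intervals are 0-based half-open. A
  variant at POS with REF of length $L$ occupies $[POS-1, POS-1+L)$: SNPs
  one base, deletions the REF span, insertions their single anchor base.
  Overlap is single-base, strand-agnostic interval intersection.
* MAF is resolved from `INFO:AF` (summed over ALT alleles, folded as
  $\min(AF, 1-AF)$), then from GT allele counting with missing calls
  excluded, else the record is skipped (and tallied) whenever a positive
  threshold is in force. The threshold is inclusive; `maf_min = 0.05` is
  the conventional population filter and the default in `run_equalize()`.
* Records with FILTER other than `PASS`/`.` are skipped by default
  (`pass_only = TRUE`); the flag exists because variant callers disagree
  about what a failed filter means for a site's existence.
* Multi-allelic records are one variant: any alternate allele makes the
  site untrusted for hybridization.
* Indels are accepted by default (their whole REF footprint can disturb
  binding); `snv_only = TRUE` restricts to SNVs.
* Chromosome dialects (`chr1` vs `1`) are reconciled explicitly via
  `normalize_chrom()`; the readers warn when probe and variant sets share
  no chromosome names rather than silently intersecting nothing.

# The eQTL scan

Per probeset and locus, ordinary least squares of log2 expression on the
additively coded genotype (0/1 in a backcross, 0/1/2 in a population
design), intercept included, two-sided $t$ on $n-2$ degrees of freedom.
Additive OLS is the minimal model consistent with regressing expression on
genotype, and for binary codes it is exactly the pooled-variance two-sample
t-test (asserted to $10^{-10}$ in the test suite). Missing genotypes are
dropped pairwise per locus, never by deleting a sample globally.

* The candidate eQTL is the locus with the smallest p; exact ties break by
  genomic order (chromosome, position, locus id) so results are
  deterministic.
* *cis* mode restricts eligible loci to the TSS chromosome within
  `cis_window_bp` (default 1,000,000 bp) of the TSS, **bounds inclusive** —
  a locus at exactly 1 Mb is eligible. The window is a half-width, in bp.
* Degenerate fits: constant genotype or $n < 3$ makes a locus untestable
  (probesets with no testable locus are omitted with a message); constant
  expression gives slope 0, $p = 1$; an exact fit with nonzero slope
  (residual sum of squares at the scale of machine epsilon times the total
  sum of squares) is flagged degenerate and reported at the smallest
  positive double rather than 0, so $-\log_{10} p$ stays finite.
* Best-locus p-values receive Benjamini–Hochberg q-values (`bh_fdr()`
  validates and delegates to `stats::p.adjust`; the test suite checks the
  step-up definition independently).

# The direction diagnostic

At each candidate eQTL the allele effect is
$d = \bar y_{g=0} - \bar y_{g>0}$ (log2 units). Grouping code 0 against
carriers extends the backcross homozygote-versus-heterozygote contrast to
0/1/2 codes without a dose model; positive $d$ means reference-type
homozygotes express more. Under no bias the expected fraction of positive
$d$ is 50 %; `direction_bias()` tests the observed split with
`stats::binom.test`, whose two-sided convention — summing the probabilities
of all outcomes at most as likely as the one observed — is the exact
definition intended here (verified against enumeration for all $n \le 20$).
Exact ties $d = 0$ carry no direction information: they are excluded from
the trials and tallied, and the reported `fraction_positive` is over
non-tied results. The diagnostic can be restricted to `q_value <= fdr_max`
since reports in the field sometimes consider only significant eQTL; the
default uses all candidates.

For run comparisons, $\Delta = -\log_{10}p_{\text{corrected}} +
\log_{10}p_{\text{uncorrected}}$ per shared probeset; `fraction_decreased`
counts $\Delta < 0$ (an exact 0 is "not decreased"). The reported Pearson
correlation is between uncorrected strength and the *loss* of strength
$-\Delta$: "strong uncorrected results tend to lose the most" is then a
positive correlation. This pairing is one of several the summary statistic
could use; it is a documented package choice. With fewer than three shared
probesets, or zero variance on either axis, the correlation is reported as
not computable rather than invented.

# What the simulator emulates — and what it does not

`sim_config()` defaults describe a desk-scale backcross eQTL study: 100
samples, 20 loci, 1000 probesets × 12 probes (a common probeset size on
IVT-era platforms), probe noise sd 1.0 log2 units, probeset baselines
$\mu_s \sim N(8, 1)$ log2 — typical intensities on these arrays. Backcross
genotypes are iid Bernoulli(0.5) per cell, the design expectation of 50 %
heterozygotes; the population design draws per-locus MAF uniformly (default
0.05–0.5) with Hardy–Weinberg 0/1/2 codes.

The platform generator lays non-overlapping 25-bp probes on a 100-bp pitch
along 5 synthetic chromosomes and plants exactly
`round(p_probe_hit × n_probes)` single-base variants at uniform offsets
within their probes. Probe values follow

$$y_{p,i} = \mu_s + \beta_s\, g_i\,[s\ \text{true eQTL}]
 - \delta\,[p\ \text{hit}]\,[g_i > 0] + \varepsilon,\qquad
 \varepsilon \sim N(0, \sigma),$$

where $g_i$ is the sample's code at the probeset's **cis locus**, defined
as the genotyped locus nearest the probeset's TSS on its chromosome (ties
to the lower coordinate). Anchoring both the true effect and the bias to a
cis locus is what makes the injected artifact look like a cis-eQTL to the
scan, which is the phenomenon under study. The attenuation $\delta$
(`bias_delta`, log2 units) applies in full to any carrier by default; a
dose-proportional option exists (`dosage_bias`) because no dose model is
implied by the mechanism. Probesets are summarized as the arithmetic mean
of member probes — full normalization pipelines (RMA and kin) are out of
scope, and the mean keeps the direction arithmetic transparent: masking a
probe simply removes its term from the average.

The simulator does **not** model hybridization thermodynamics, probe GC or
position-within-probe effects, array spatial artifacts, batch effects,
linkage between loci (codes are iid across loci, so there is no LD), or
correlated noise between probes of a probeset. Passing tests therefore
demonstrate that the masking and scanning machinery is correct and that the
direction diagnostic behaves as designed under the stated generative model;
they do not certify effect sizes on any real platform.

All randomness flows from the single `seed`: the platform, genotype and
expression stages draw from fixed offsets of it, so every output is
reproducible byte for byte and independent of call order.

# Numerical and scale choices

The test suite and acceptance script run entirely on synthetic data at the
following sizes, chosen to make binomial noise small relative to the
quantities checked while keeping a full run under a minute: overlap-engine
equivalence against a brute-force all-pairs oracle at 1000 probes × 500
variants; masking invariants over 100 random fixtures; slope recovery
(true $\beta = 1$, $n = 100$, noise sd 1) over 200 probesets with a ±0.1
band on the mean estimate; direction fractions over 1000 probesets judged
within 3 binomial standard errors of 50 %; heterozygosity over 50,000
genotype cells. The injected-bias demonstration uses `p_probe_hit = 0.3`,
`bias_delta = 1.0`: an average probeset then loses 0.3 of a log2 unit in
carriers, several times the probeset-level noise
($\sigma/\sqrt{12} \approx 0.29$), so the uncorrected direction fraction
saturates well above the 55 % property bound while the masked rerun returns
to balance.

# Known limitations

* Masking cannot recover information: probesets reduced to one or two
  probes are noisier afterwards, and fully masked probesets are gone.
  `min_probes` exists for users who prefer to prune harder; the default (1)
  keeps every probeset with any clean probe.
* The annotation dialects are a documented generic TSV and a simplified
  PGF/CLF text pair (probeset→probe hierarchy plus probe coordinates);
  vendor binary formats and atom/block hierarchy levels are out of scope.
* Control probesets are whatever the annotation says: nothing special-cases
  AFFX-style controls — they pass through untouched unless their probes
  intersect variants.
* The scan fits no covariates, permutation thresholds, interactions or
  mixed models; it is the minimal per-locus additive regression with
  deterministic best-locus selection.
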