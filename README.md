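# snpmask

Variant-aware microarray probe masking and eQTL bias diagnostics.

## The problem

Expression microarrays measure transcripts with short (~25 nt) probes
designed against a reference genome, and summarize an ensemble of probes
into one probeset value per gene. When a sample's genome differs from the
reference under a probe — a strain-specific SNP, an indel — hybridization
weakens and that probe under-reports expression in exactly the samples
carrying the variant. In genetic experiments this artifact is confounded
with genotype: a gene whose probes sit on population- or strain-associated
variants looks like it has a *cis*-acting expression QTL even when its true
expression is identical across genotypes. The effect is severe in crosses
between divergent strains (e.g. a *Mus spretus* × *Mus musculus* backcross,
where hundreds of thousands of probes can intersect strain SNPs) and present
in human studies wherever population SNP frequencies differ.

`snpmask` removes the artifact at its source, with no need for replicate
parental expression data: any probe whose genomic footprint intersects a
variant in a supplied VCF is dropped from its probeset, probesets losing
every probe are dropped from the annotation, and the rewritten annotation
files feed any downstream normalization pipeline.

## What it computes

* **Masking.** Probe intervals (BED, 0-based half-open) are intersected with
  variant footprints (VCF; a variant at POS with REF length *L* occupies
  `[POS−1, POS−1+L)`). Variants pass an inclusive minor-allele-frequency
  filter, MAF = min(AF, 1−AF) from `INFO:AF` or GT allele counting. Any
  single-base overlap removes the probe; a per-probeset report accounts for
  every removal.
* **eQTL scan.** For each probeset, expression *y* is regressed on the
  additively coded genotype *g* at each eligible locus (OLS with intercept,
  two-sided *t* on *n*−2 df; for a backcross's binary genotype this is the
  pooled two-sample t-test). The strongest locus is the candidate eQTL
  (genome-wide, or a *cis* window of ±1 Mb around the TSS, bounds
  inclusive); best-locus p-values get Benjamini–Hochberg q-values.
* **Direction diagnostic.** At each candidate eQTL, the allele effect
  *d* = mean(*y* | *g* = 0) − mean(*y* | *g* > 0) in log2 units. Without
  probe bias, *d* > 0 for ≈50 % of genes; an excess is the signature of
  hybridization bias, tested with an exact two-sided binomial test against
  0.5.
* **Run comparison.** Per probeset, Δ = −log10 *p*(corrected) − −log10
  *p*(uncorrected); the share of probesets that decreased in significance
  and the Pearson correlation between uncorrected strength and loss of
  strength.
* **Simulation.** A generator produces the full input set — platform
  annotation, probe BED, variant VCF, backcross (Bernoulli 0.5) or
  Hardy–Weinberg population genotypes, and probe-level expression with an
  injectable attenuation `bias_delta` applied to variant-containing probes
  in variant-carrying samples — so every pipeline stage can be validated
  end to end.

## Worked example

Inject a 1.0-log2 attenuation into 30 % of probes in a simulated 100-animal
backcross with no true genetic effects, then mask and rescan:

```r
library(snpmask)

cfg <- sim_config(n_samples = 100, n_probesets = 1000, p_probe_hit = 0.3,
                  bias_delta = 1.0, seed = 42)
bx <- run_bias_experiment(cfg)
bx
#> <bias_experiment>
#>   masking: 3600 / 12000 probes removed, 0 / 1000 probesets dropped
#>   uncorrected direction fraction: 0.945 (binomial P = 3.44e-210)
#>   corrected   direction fraction: 0.506 (binomial P = 0.728)
#>   92.2% of shared probesets decreased in significance after masking
```

Before masking, 94.5 % of candidate eQTL show higher expression in the
homozygous (variant-free) group — a massive spurious excess over the 50 %
a null experiment should give, entirely manufactured by the probe
attenuation. After removing the 3600 variant-intersecting probes and
re-summarizing the surviving probes, the fraction returns to 50.6 %
(binomial P = 0.73, indistinguishable from balance), and 92 % of probesets
drop in significance because their inflated signals were artifacts:

```r
glance(bx$comparison)
#> # A tibble: 1 × 4
#>   n_shared fraction_decreased pearson_r pearson_p
#>      <int>              <dbl>     <dbl>     <dbl>
#> 1     1000              0.922     0.992         0

autoplot(bx$uncorrected)   # allele-effect histogram, shifted right
autoplot(bx$comparison)    # significance change vs uncorrected strength
```

The same operations run on real files: `run_equalize()` takes a probe BED,
one or more VCFs and an annotation (generic TSV or a simplified PGF/CLF
text pair) and writes the masked annotation, the per-probeset report and a
hit-list BED; `run_eqtl()` scans expression/genotype TSVs. A thin
command-line wrapper with the same behavior ships in `inst/cli/snpmask.R`
(subcommands `equalize`, `eqtl`, `simulate`, `bias-eval`).

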