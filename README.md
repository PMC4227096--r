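# msccflow

Genome-wide DNA methylation, alternative splicing and behavioral analysis
for two-group (drug vs. vehicle) mouse studies, built around the
**methyl-sensitive cut-counting (MSCC)** assay. The package is aimed at
epigenomics analysts who need a transparent, fully testable reimplementation
of this analysis stack, exercisable end-to-end on synthetic data with known
ground truth.

## What it computes

**Site methylation from MSCC.** MSCC sequences 18-bp tags from two
libraries per sample: the HpaII library (tags from *unmethylated* `CCGG`
sites, where the enzyme cut) and the inverse library (tags from
*methylated* CmCGG/ChmCGG fragments). After rescaling the inverse library
by the spike-in standard ratio *s* = Σh<sub>std</sub>/Σv<sub>std</sub>, the
methylation level of a site with counts (h′, v′) is

&nbsp;&nbsp;&nbsp;&nbsp;m̂ = v′ / (h′ + v′),

and only sites with more than 40 combined raw reads enter downstream
analyses.

**Differentially methylated units.** The genome is scanned with 200-bp
windows overlapping by 50 bp (step 150) plus known CpG islands as units;
units with more than 3 sequenced CpGs in both groups are compared by a
paired Student t-test across sites, and called at |Δm̄| > 0.25 and
P < 0.05.

**Exon skipping.** Percent-spliced-in Ψ is inferred from junction reads
under the two-inclusion-junction model — a junction read is inclusion-type
with probability f(ψ) = 2ψ/(1+ψ) — with a uniform prior on a 2001-point
grid. Differential events are scored by the Bayes factor (independent vs.
shared ψ) and called at BF ≥ 1000; ΔΨ is treatment − control.

**Integration and validation arithmetic.** Promoter methylation changes
(|Δm| ≥ 0.25, within 2 kb upstream of a TSS) against log₂ expression
changes via the Pearson correlation test; relative qPCR expression via
2^−ΔΔCt; HpaII-qPCR methylation fractions via 2^(Ct_mock − Ct_HpaII).

**Behavior.** Conditioned-place-preference scores (drug-side time / total
apparatus time), the >540-s unconditioned-preference screen, and paired
post- vs. pre-conditioning t-tests per group.

A synthetic-data generator (toy genome + annotations, context-stratified
Beta methylomes with planted DMR units, negative-binomial MSCC counts with
library-efficiency imbalance and spike-ins, coupled expression tables,
binomial junction reads, Dirichlet CPP sessions) provides ground truth for
every stage.

## Worked example

Simulate five CCGG sites at known methylation levels, sequence them through
the two-library count model, and call methylation with spike-in
normalization and the depth filter:

```r
library(msccflow)
cfg <- sim_config(seed = 11)
truth <- data.frame(site_id = sprintf("s%03d", 1:5),
                    true_m = c(0.05, 0.25, 0.50, 0.75, 0.95))
smp <- simulate_mscc_counts(data.frame(site_id = truth$site_id,
                                       m = truth$true_m), cfg, seed = 11)
calls <- mscc_methylation(smp$counts, smp$spikeins)
merge(truth, calls, by = "site_id")
```

```
  site_id true_m     m raw_depth passes_filter
1    s001   0.05 0.029        35         FALSE
2    s002   0.25 0.089        34         FALSE
3    s003   0.50 0.489        82          TRUE
4    s004   0.75 0.755        57          TRUE
5    s005   0.95 0.967        61          TRUE
spike-in scale s = 1.0035
```

The passing sites recover their true levels to within binomial sampling
noise at this depth; the two shallow sites (34–35 reads) are kept but
flagged as failing the >40-read filter. Scoring a skipping event with 200
junction reads per group:

```r
bf <- psi_bayes_factor(37, 163, 151, 49)   # (incl, excl) per group
# psi_a = 0.105, psi_b = 0.606, delta_psi = 0.501, BF = 1.06e+29
cpp_score(450, 300, 150)                                        # 0.5
relative_expression_ddct(c(12,12), c(10,10), c(18,18), c(14,14))$fold  # 4
```

The Bayes factor overwhelmingly favors group-specific Ψ; ΔΨ ≈ 0.50 with
positive sign means more exon inclusion under treatment.

## The analysis workflow

`analysis/01_simulate_data.R` … `07_score_behavior.R` are thin numbered
drivers that run the whole study on synthetic data — simulation,
methylation quantification (including a raw-FASTQ tag-counting round
trip), annotation and TSS meta-profile, the DMR scan with recovery against
the planted truth, Ψ/Bayes-factor scoring, methylation–expression
integration, and CPP scoring — writing tables, BED/BEDGraph tracks and
figures under `results/`. Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

`run_demo(seed, dir)` chains the same pipeline inside one function and is
byte-reproducible for a fixed seed. The methods vignette
(`vignettes/mscc-methylome-workflow.Rmd`) documents the models,
parameters, conventions and limitations.

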