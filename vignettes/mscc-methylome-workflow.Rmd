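---
title: "Methods: MSCC methylation, differential methylation, exon skipping and CPP scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSCC methylation, differential methylation, exon skipping and CPP scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccflow)
```

msccflow implements the computational core of a two-group (drug vs. vehicle)
mouse study that combines genome-wide DNA methylation profiling by
methyl-sensitive cut counting (MSCC) with transcriptome readouts
(expression tables, exon-skipping junction counts), qPCR validation
arithmetic, and conditioned-place-preference (CPP) behavioral scoring. This
vignette is the package's account of the models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical conventions adopted where the
method description leaves room.

## The MSCC measurement model

MSCC interrogates every HpaII recognition site (`CCGG`) in the genome with
two sequencing libraries. The *HpaII library* captures 18-bp tags released
where the enzyme cut, i.e. from **unmethylated** sites; the *inverse
library* captures tags from fragments the enzyme could not cut, i.e. from
**methylated** (CmCGG or ChmCGG) sites — the assay cannot distinguish
methylation from hydroxymethylation and neither does the package. For a
site with normalized counts $h'$ (HpaII) and $v'$ (inverse), the
methylation level is the methylated-fragment fraction

$$\hat m \;=\; \frac{v'}{h' + v'} \in [0,1].$$

Two corrections surround this ratio:

* **Spike-in normalization.** Both libraries receive the same spike-in
  standard DNA, so any difference in their summed standard counts reflects
  library size/efficiency rather than methylation. The package rescales the
  inverse library onto the HpaII library by
  $s = \sum_\text{std} h / \sum_\text{std} v$, leaving $h$ untouched
  ($v' = s\,v$). $\hat m$ is invariant to common rescaling of both
  libraries, so normalizing one library onto the other with a single summed
  ratio is the minimal-assumption estimator; a zero spike-in total in
  either library is an error because normalization is then impossible.
* **Depth filter.** A site enters downstream analyses only when its
  combined raw reads exceed `min_depth = 40` (strictly; 40 reads fail).
  The method description does not say whether the threshold applies per
  library or combined; the combined reading is implemented because the
  combined depth governs the variance of $\hat m$. Sites with zero depth
  carry no information and are dropped (tallied), not reported as
  $\hat m = 0$.

At the read level, tags are assigned by exact matching of a read's first
18 bases against a precomputed tag library: for a `CCGG` whose first `C`
sits at 0-based position $p$, the plus-strand tag is the 18-mer starting at
$p+1$ and the minus-strand tag is the reverse complement of positions
$p-15 \dots p+2$. Tags occurring at more than one (site, strand) location
are ambiguous and never counted; truncated flanks near contig ends simply
contribute no tag for that side. Mismatch-tolerant mapping is an alignment
concern out of scope here; the count-table entry path makes the
quantification usable without the read path.

## Annotation and meta-profiles

Sites are assigned one gene feature with precedence
promoter > exon > intron > intergenic, where the promoter is the
`promoter_bp = 2000` bases upstream of the TSS in transcription
orientation. Neither the promoter width nor the "upstream of TSS" window
used for integration is quantified in the original method description;
2 kb is the conventional choice and both are exposed as parameters. CpG
island (CGI) context is island / shore / open sea with the conventional
2 kb shore. Signed TSS distances are negative upstream, so a site 500 bp
ahead of a plus-strand TSS and a site 500 bp genomically *after* a
minus-strand TSS both sit at $-500$.

The TSS meta-profile bins every (site, gene) pair within ±10 kb into
100-bp bins of signed distance — a site near two TSSs contributes to both
(meta-profile convention), while feature assignment uses only the nearest
gene (ties by smallest |TSS distance|, then lexicographic gene id). Empty
bins are explicit `NA`s; the smoothed curve is a centered moving average
over `smooth_k = 5` bins that ignores missing bins, and `smooth_k` must be
odd so the window is symmetric.

## Differential methylation: the unit scan

The genome is scanned with 200-bp windows overlapping by 50 bp — adjacent
windows *share* 50 bp, i.e. step 150 (the alternative 50-bp-step reading is
selectable but not default) — plus every known CGI as one additional unit.
Only full windows are enumerated. A unit is testable when it retains more
than 3 (i.e. ≥ 4) sequenced CpGs, counted **after** intersecting the sites
that pass the depth filter in both groups.

Within a unit the two groups are compared by a paired Student t-test across
sites: $d_i = m^B_i - m^A_i$, $t = \bar d / (s_d/\sqrt n)$, $df = n-1$,
two-sided. There is no replicate structure (each group is one pooled
sample), so pairing across sites is the only consistent reading of
"paired". A unit is called when $|\bar d| > 0.25$ **and** $p < 0.05$ —
the original rule uses raw P values; a Benjamini–Hochberg column is
emitted for the user but does not gate significance. The delta sign
convention is treatment minus control throughout.

Zero-variance pairings are possible in principle (identical differences at
every site); the package flags them as degenerate with $p = 1$ when
$\bar d = 0$ and $p = 0$ otherwise. The all-identical check tolerates
floating-point noise ($s_d \le 10^{-12}\max(1, |\bar d|)$), since exact
constant offsets between float vectors rarely produce an exactly zero
standard deviation.

## Exon skipping: Psi and the Bayes factor

Percent-spliced-in ($\Psi$) is estimated from junction reads under a
deliberately small read model: the inclusion isoform spans **two**
junctions and the exclusion isoform one, so a random junction read is
inclusion-type with probability

$$f(\psi) = \frac{2\psi}{1+\psi},$$

and inclusion reads are $\mathrm{Binomial}(I;\, I+E,\, f(\psi))$. With a
uniform prior on $\psi$, the posterior is evaluated on a fixed uniform grid
of 2001 points: the reported $\hat\psi$ is the posterior mean, the 95%
credible interval comes from posterior quantiles, and the closed form
$\tilde\psi = (I/2)/(I/2+E)$ (inverting $f$) is reported alongside. The
full isoform-assignment sampler of mixture-of-isoforms approaches is
intentionally not reproduced; this is the smallest model that yields
$\Psi$, $\Delta\Psi$ and a Bayes factor under the documented junction
geometry, with no read-length or insert-length corrections.

Differential skipping compares the evidence for independent group-specific
$\psi$ values against a shared $\psi$:

$$\mathrm{BF} = \frac{\int L_A(\psi)\,d\psi \cdot \int L_B(\psi)\,d\psi}
                     {\int L_A(\psi) L_B(\psi)\,d\psi},$$

computed by trapezoid quadrature on the same grid with log-space
accumulation. Binomial coefficients cancel between numerator and
denominator. Identical counts always give $\mathrm{BF} \le 1$
(Cauchy–Schwarz), and the statistic is exactly symmetric under group
exchange. Events are called at the conservative threshold
$\mathrm{BF} \ge 1000$ with at least `min_reads = 20` junction reads per
group (the upstream filter's exact settings are not documented; 20 is the
package default, configurable). $\Delta\Psi$ is the difference of posterior
means, treatment minus control, so positive values mean more exon
inclusion under treatment.

## Integration and qPCR arithmetic

Methylation–expression integration collects one point per (site, nearest
gene): sites within the 2 kb upstream window, passing the depth filter in
both groups, with $|\Delta m| \ge 0.25$ (per-site points, mirroring the
original presentation; a per-gene aggregated mode exists but is not
default). Expression change is $\log_2$ of the FPKM ratio with a
pseudocount of 1 (configurable; the original is silent). The association is
the Pearson correlation with the classical t-transform P value.

The validation arithmetic is implemented exactly:
$2^{-\Delta\Delta C_t}$ for relative expression (with a two-sample Student
t-test on replicate $\Delta C_t$ values) and
$2^{C_t^{\text{mock}} - C_t^{\text{HpaII}}}$ for the HpaII-qPCR
methylation fraction. Fractions above 1 are assay noise and are reported
as-is with a warning flag, never clamped.

## CPP scoring

The CPP score is the drug-paired-side share of session time. The
denominator includes the passage by default ("total time in the
apparatus"); whether printed group tables include passage time is not
stated in the original, so a compartments-only mode is provided. Animals
with a strong unconditioned preference — strictly more than 540 s in either
compartment during the 900-s pre-conditioning session — are excluded.
Per group, post- vs pre-conditioning scores are compared by a paired
two-sided t-test (same animals in both phases; the original names only
"Student's t-test").

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth. What it emulates, with defaults:

* **Genome** (`generate_genome`): 2 chromosomes × 200 kb, 40 three-exon
  genes, 30 CGIs of 0.5–1.5 kb with 60% placed over promoters; `CCGG`
  planted at 2/kb background and an extra 10/kb inside islands (mirroring
  the empirical enrichment of CCGG in CG-dense sequence), with spontaneous
  background `CCGG`s scrubbed first so density is controlled. The recorded
  site list is obtained by re-scanning the final sequence.
* **Methylome** (`simulate_methylome`): per-site true methylation is Beta
  by context — islands $\mathrm{Beta}(0.5, 10)$ (hypomethylated), open sea
  $\mathrm{Beta}(10, 0.5)$ (hypermethylated), shores $\mathrm{Beta}(2,2)$
  (intermediate) — reproducing the canonical island < shore < open-sea
  ordering and the TSS hypomethylation dip. Group B equals group A except
  in planted units. Because the ground truth must contain the planted
  shift exactly (recovery is asserted against it), baselines inside
  planted units are resampled from the feasible range rather than shifted
  and clipped; clipping remains as a defensive guard.
* **Counts** (`simulate_mscc_counts`): per-site depth is negative binomial
  (mean 60, size 20) — overdispersion is realistic and exercises the depth
  filter; the inverse count is binomial in the true $m$; each library is
  then scaled by a global efficiency factor (deterministic rounding), which
  is exactly the distortion spike-in normalization corrects. Spike-in
  standard counts are Poisson around 500 per standard (20 standards),
  scaled by the same factors. Read qualities, adapter content and
  alignment errors are *not* simulated; the optional raw-read mode emits
  perfect 18-bp tags.
* **Expression** (`simulate_expression`): per-gene
  $\log_2 \mathrm{FC} = \text{slope} \times \overline{\Delta m}_\text{promoter} + \varepsilon$
  with slope $-2$ and $\varepsilon \sim N(0, 0.5)$; baseline FPKM is
  log-normal. The slope magnitude is a package choice (no value is
  published); only the *sign* of the recovered correlation is asserted.
* **Junction reads** (`simulate_junction_reads`): binomial at
  $f(\psi) = 2\psi/(1+\psi)$ — the same geometry the estimator assumes, so
  these tests validate inference, not model misspecification.
* **CPP sessions** (`simulate_cpp_sessions`): each 900-s session is split
  (drug side, saline side, passage) by a Dirichlet draw with concentration
  7. The baseline drug-side share (0.28) and the conditioning effect
  (+0.57 for the morphine group post-phase) reproduce the published group
  means (0.286 → 0.856), and concentration 7 matches the printed SDs
  (≈ 0.13–0.16). One caveat is inherited from the source: with a
  saline-side share near 0.5 and that much between-animal spread, the
  >540 s screen occasionally excludes simulated animals even though the
  original cohort reported none; the demo pipeline therefore only tests
  groups that keep ≥ 2 animals after screening. Pooled methylomes are
  modeled per group, not per animal — the study pooled DNA from six mice
  per sample and publishes no per-animal variance to calibrate against.

## Validation studies and problem sizes

The `study_*` functions re-run each stage at fixed study conditions and are
what the test suite and the acceptance script execute:

* methylation recovery: 10⁴ sites at depth ~60 (RMSE ≤ 0.075; the bound is
  the binomial sampling floor $\sqrt{\max m(1-m)/60} + 0.01$), plus the
  efficiency-imbalance study (normalized mean bias within ±0.02,
  unnormalized visibly biased low);
* DMR recovery: 50 planted Δm = 0.30 units among 5 000 nulls, 6 sites per
  unit (sensitivity ≥ 0.70 — losses come from depth-filter attrition and
  the strict 25% cutoff against Δ̂ noise — and ≤ 2% null calls);
* Psi: mean absolute posterior-mean error over ψ = 0.1 … 0.9 at 200 reads;
  Bayes-factor power at ΔΨ = 0.5 with 500 reads/group and the null call
  rate over 100 replicates;
* integration: 100 replicates of the 200-gene coupling study (negative r
  with p < 0.01);
* behavior: type-I error of the paired test over 1 000 null replicates and
  power at n = 6 with the configured effect;
* the end-to-end demonstration (`run_demo`) on the default 2 × 200 kb
  genome, run twice to confirm byte-identical outputs.

These sizes keep any single study under a couple of minutes on one core
while leaving Monte-Carlo error well inside the asserted margins. Passing
them shows the estimators and tests recover what the generator planted
under the generator's assumptions; it does not certify performance on real
data, where tag mapping is mismatch-tolerant, depth is not negative
binomial per site, methylomes vary between animals, and splicing reads do
not follow the two-junction geometry exactly.

## Known limitations

* Exact-match tag counting only; no mismatch tolerance.
* One pooled methylome per group; no biological replicates, hence no
  between-animal variance in the DMR test (the paired t is across sites).
* The Psi model ignores read length, insert size and other event types
  (A5SS, A3SS, RI, MXE).
* No multiple-testing gate on DMR calls (by design, mirroring the original
  rule); the BH column is informational.
* Expression enters as FPKM tables; differential-expression calling from
  read counts is out of scope.
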