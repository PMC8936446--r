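---
title: "Strand-specific analysis of CPD repair: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific analysis of CPD repair: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandrepair)
```

## The biological problem

UV light produces cyclobutane pyrimidine dimers (CPDs) at adjacent
pyrimidines (TT, TC, CT, CC). In budding yeast these lesions are removed by
two nucleotide excision repair subpathways: global genomic NER (GG-NER,
Rad16-dependent), which acts everywhere but is slowed inside nucleosomes,
and transcription-coupled NER (TC-NER, Rad26-dependent), which acts only on
the transcribed strand (TS) of active genes, where a stalled RNA polymerase
flags the lesion. CPD-seq maps individual lesions at single-nucleotide,
strand-specific resolution: the library protocol cleaves DNA at each CPD, so
the 5′ end of each sequenced read sits immediately 3′ of the lesion on the
opposite strand.

`strandrepair` implements the analysis used to quantify strand-specific
repair from such data — dipyrimidine-filtered lesion calling, metagene bin
profiles of the fraction of CPDs remaining, the log2 TS/NTS asymmetry
statistic, single-nucleotide TSS-aligned profiles, bulk-repair (alkaline
gel) quantitation used to rescale sequencing data, and survival statistics —
together with a parametric simulator that provides ground truth for every
stage. Chromatin regulation enters through the Set2 histone
methyltransferase (H3K36 methylation), which promotes TC-NER of the TS and
suppresses cryptic antisense TC-NER of the non-transcribed strand (NTS);
the simulator's genotype presets encode exactly this qualitative genetics so
the package's statistics can be validated by parameter and sign recovery.

## Lesion calling conventions

All internal coordinates are 0-based; BED-like inputs and bedGraph outputs
are 0-based half-open; annotation readers accept standard columns.

For a read aligned on strand $r$ with 5′ terminus at position $p$, the
candidate lesion lies on the *opposite* strand in the two bases immediately
upstream of $p$ in read orientation:

* $r = +$: damaged strand is −, genomic positions $(p-2,\,p-1)$, the
  dinucleotide read 5′→3′ on the minus strand is
  $\mathrm{comp}(b_{p-1})\,\mathrm{comp}(b_{p-2})$, stored at $p-1$;
* $r = -$: damaged strand is +, positions $(p+1,\,p+2)$, dinucleotide
  $b_{p+1} b_{p+2}$, stored at $p+1$.

A lesion is always keyed by the 5′-most base of its dinucleotide on the
damaged strand, the single convention shared by the simulator, the lesion
caller and all metrics. Reads whose inferred dinucleotide is not a
pyrimidine dimer, contains N, or falls off the chromosome are discarded and
tallied by reason (`infer_lesions()` attaches the tally as a QC attribute).
Duplicate reads are kept by default — recurrence at damage hotspots is
signal — and deduplication is opt-in. No mapping-quality cutoff is applied
by default; both defaults are surfaced in the QC output rather than silently
assumed.

Two boundary positions are physically undetectable under this convention:
a plus-strand lesion at position 0 and a minus-strand lesion at the last
position of a chromosome would require a read 5′ end outside the
chromosome. `lesions_to_reads()` (the simulator's inverse map) drops and
tallies them, which is why track/read round trips are exact on interior
positions.

## The repair fraction and its two scalings

For any strand-qualified region the *fraction of CPDs remaining* is the
pooled lesion count at the repair timepoint divided by the pooled 0 hr
count. Pooling counts across genes before the ratio (rather than averaging
per-gene ratios) is the default because per-gene counts are sparse and
their ratios unstable; a per-gene-mean mode is available
(`bin_profile(..., mode = "per_gene_mean")`).

Sequencing libraries are depth-normalized, so the genome-wide ratio of raw
counts carries no information about absolute repair — if both libraries are
thinned to the same depth the raw genome-wide fraction is ≈ 1 regardless of
how much repair occurred. Two anchors restore the absolute scale:

* **Gel scaling** (`gel_scale()`): the bulk fraction of CPDs remaining
  measured by T4 endonuclease V digestion and alkaline gel electrophoresis.
  Every regional fraction is multiplied by
  $s = F_{\mathrm{gel}} / (N_t / N_0)$ so the genome-wide scaled fraction
  equals the gel value exactly.
* **Intergenic-median scaling** (`intergenic_median_scale()`): when
  comparing two libraries without a gel anchor, the median over the 12
  flank-bin ratios (6 flanking bins × both strand roles) of test/reference
  is set to exactly 1, using intergenic DNA as an internal control.

The asymmetry statistic $\log_2(F_{TS}/F_{NTS})$ is invariant under any
common scale factor, so scaling choices cannot change it; negative values
mean faster TS repair (active TC-NER).

## Metagene geometry

Each gene body $[\mathrm{TSS}, \mathrm{TES})$ is divided into 6 sextiles in
gene orientation; when the length is not divisible by 6 the first
`length mod 6` bins receive one extra bp (deterministic, TSS-first). Three
167-bp flanking bins tile outward flush from the TSS (upstream) and from
the TES (downstream). Flank bins are taken regardless of overlap with
neighboring genes, matching common practice for compact genomes; an
exclusion flag was considered and deliberately not made the default since
the reference analyses apply none. Genes with body < 6 bp or missing
coordinates are excluded and counted. Single-nucleotide TSS profiles span
−200..+1000 bp in gene orientation (minus-strand genes mirrored), with an
11-nt centered moving average by default; smoothing is applied to the
pooled numerator and denominator counts, not to the per-offset ratios —
equivalent to a count-weighted fraction and much stabler where per-offset
counts are ~1.

## The simulator

The generator is the package's ground truth and its defaults are the study
conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `chrom_length` | 200 kb | compact yeast-like genome, desk-scale |
| `n_genes` | 55 | ~55% genic fraction at 1–3 kb per gene |
| `base_composition` | A/T 0.31, C/G 0.19 | yeast-like AT-rich composition |
| `induction_prob` | TT 0.12, TC 0.06, CT 0.06, CC 0.03 | per-site lesion probability; preserves the TT > TC ≈ CT > CC photoproduct preference at desk-scale counts |
| `k_gg` | 0.35 /hr | linker-DNA GG-NER rate (≈ 50% bulk repair at 2 hr) |
| `k_tc` | 0.55 /hr | additional TC-NER rate on the TS |
| `k_anti` | 0.35 /hr | antisense TC-NER on the NTS of SRAT genes (set2-like genotypes only) |
| `nuc_amplitude`, `nuc_repeat` | 0.4, 165 bp | nucleosomal suppression of GG-NER, cosine-shaped around each dyad |
| `first_dyad_offset` | 75 bp | +1 nucleosome dyad position |
| `srat_fraction` | 0.15 | fraction of genes carrying a Set2-repressed antisense transcript |
| `depth` | 2e5 | per-library binomial thinning target |

Repair is first-order: a lesion at position $x$ on strand $s$ survives to
time $t$ with probability $e^{-k(x,s)t}$,

$$k(x,s) = m(x)\,k_{gg}\,g_{gg} + k_{tc}\,g_{tc}\,[s = TS]
         + k_{anti}\,g_{anti}\,[s = NTS \text{ of an SRAT gene}],$$

with $m(x) = 1 - A\,c(x)$ and $c(x)$ the cosine-interpolated dyad proximity
(1 at the dyad, 0 at the linker midpoint). The genotype multipliers
$(g_{gg}, g_{tc}, g_{anti})$ are (1, 1, 0) for WT, (1, 0.4, 1) for `set2`,
(0, 1, 0) for `rad16`, (0, 0.4, 1) for `rad16set2` and (1, 0, 0) for
`rad26`. The residual TS efficiency 0.4 in set2-like genotypes encodes
"impaired but not abolished" TC-NER; it is arbitrary within that constraint
and configurable. The magnitude of antisense TC-NER is not quantified by
published data; `k_anti` defaults to the GG-NER rate and no claim of
fidelity is made for it. Timepoints are simulated by nested thinning, so
lesion totals are monotone non-increasing in time for every seed.
All randomness flows from one integer seed through derived per-stage
streams.

What the simulator deliberately omits: read-level sequencing error and
alignment ambiguity, 6-4 photoproducts, replication and cell-cycle effects,
sequence-context repair biases beyond the dinucleotide, and transcription
dynamics (a gene's TS role is static). Passing tests therefore demonstrate
that the estimators recover the truth of *this* generative model at desk
scale, not that real libraries are free of those complications.

## Validation scenarios and numerical choices

* **Asymmetry direction** (200 kb, depth 2e5, 3 seeds): all six body-bin
  log2 TS/NTS values are negative in WT and strictly closer to zero under
  the `set2` preset; expected magnitudes are
  $-k_{tc} t \log_2 e \approx -1.6$ and $-0.4\,k_{tc} t \log_2 e \approx
  -0.63$ at $t = 2$ hr.
* **Rate recovery** (10 seeds, depth 1e5): this scenario sets
  `nuc_amplitude = 0` and `intergenic_min = 1100` so that flank bins are
  purely intergenic and the pooled-decay estimator
  $\hat k = -\ln(F)/t$ targets exactly $k_{gg}$ (intergenic) and
  $k_{gg} + k_{tc}$ (TS). With modulation on, the TS estimand would be
  $\bar m\,k_{gg} + k_{tc}$ — a property of the model, not an estimator
  error — so the recovery check isolates the estimator.
* **Nucleosome periodicity** (400 kb, 110 genes, amplitude 0.5, repeat
  165 bp, 5 seeds averaged): the NTS TSS profile is detrended by
  subtracting a one-repeat moving average, and the period is scored by the
  smoothed autocorrelation at each candidate lag plus its second harmonic.
  The harmonic term sharpens the peak against broadband counting noise;
  with it, the detected lag is stable within 165 ± 5 bp. Under the
  `rad16` preset GG-NER is off, the NTS fraction is flat and no
  periodicity is detected.
* **Bootstrap CIs** for the SRAT contrast resample genes within groups
  (default 1000 draws, seeded); the percentile interval's coverage is
  checked against a normal-theory oracle on Gaussian cells.
* **Gel quantitation**: the number-average length treats lane intensity as
  mass-proportional ($I_i/L_i \propto$ molecule number), the standard
  quantitation for stain-intensity densitometry, and ladder calibration is
  log-linear in migration distance. Negative lesion estimates are floored
  at zero with a warning, never silently.
* **t-tests** default to the Welch variant; the degenerate all-constant
  case returns $p = 1$ by convention. The null-calibration check uses
  10 groups per arm, where the Welch test's finite-sample size is close to
  nominal. No multiple-testing correction is applied by default (matching
  the source analyses); Holm correction is available.

Undefined quantities are kept undefined: bins with zero 0 hr counts and
log-ratios of zero or missing fractions propagate `NA` rather than being
clipped, and tables show the gaps.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(genotypes = c("WT", "set2"), timepoint = 2,
                  scaling = "gel", seed = 1, out_dir = "run1")
manifest <- run_pipeline(cfg)
```

The pipeline simulates one genome, runs a CPD-seq experiment per genotype,
writes bin tables, asymmetry tables, TSS profiles, gene-by-bin matrices
(TSV and CDT for tree-view heatmap browsers), gel curves and a JSON
manifest recording every seed, scale factor and file. The problem sizes
used in the shipped tests (40–400 kb genomes, 8–110 genes, depths up to
2×10⁵) were chosen so any scenario completes in seconds on one CPU while
leaving every estimator comfortably above its noise floor.

## Known limitations

* The offset convention between read 5′ ends and lesion positions has
  dialects across protocols; the default here is the two-bases-upstream,
  opposite-strand rule documented above, and worked 7-mer examples are
  embedded in the unit tests.
* Pooled fractions weight genes by lesion content, so highly damaged genes
  dominate; use the per-gene-mean mode when genes should count equally.
* The SRAT gene set, transcription rates and expression fold-changes are
  simulator covariates, not measured ones; stratified analyses on real
  data require externally supplied gene lists.
* Mitochondrial or plasmid contigs, if present in real data, should be
  excluded before track construction; the package operates on whatever
  chromosome set the tracks declare.
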