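---
title: "Methods: scoring a corepressor module across three omic layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring a corepressor module across three omic layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepressmap)
library(dplyr)
```

corepressmap re-implements, as one tested pipeline, the inference chain used
to map a deacetylase-containing corepressor module (an HDAC3–PROX1-like
pair) onto the transcription factor that recruits it (an HNF4α-like factor)
and onto the genes it represses. The chain has four statistical stages, each
with its own model and printed thresholds, plus a synthetic-data generator
that makes the whole chain testable without any external data. This
vignette explains the models, the defaults and why they hold, the numerical
choices, and what the synthetic benchmark does and does not demonstrate.

## 1. Interactome scoring from cross-linked ChIP-MS

The input is a peptide-level intensity table from bait (tagged-protein) and
control (tagged-GFP) immunoprecipitations. Scoring proceeds:

1. **iBAQ quantification.** Protein abundance is the summed observed
   peptide intensity divided by the count of theoretically observable
   peptides — tryptic fragments (cleavage after K/R except before P, zero
   missed cleavages) of 6–30 residues. The digest parameters follow the
   iBAQ convention and are exposed (`digest_min_len`, `digest_max_len`);
   the cleavage rule is the only biology in the denominator, so it is
   implemented exactly and property-tested.
2. **log2 + median centring.** Each sample's observed log2 values are
   centred on zero, removing loading differences between IPs.
3. **Downshifted-Gaussian imputation** (`width = 0.25`,
   `downshift = 2.0`). Missingness in IP proteomics is missing-not-at-random:
   low-abundance peptides drop out first. Missing cells are therefore drawn
   from `Normal(mu - 2*sigma, (0.25*sigma)^2)` per sample — a narrow
   distribution in the low tail of that sample's observed values.
   Imputation is column-wise by default (the idiom these width/downshift
   units come from); a pooled-distribution mode is available via
   `per_sample = FALSE`. The draw is seeded and bit-reproducible.
4. **Differential enrichment.** Per protein, a two-tailed two-sample t-test
   with pooled (homoscedastic) variance on the imputed log2 values; the
   volcano axes are the log2 bait/control difference and raw −log10 P.
   Benjamini–Hochberg adjusted P-values are reported alongside because no
   multiple-testing correction is part of the printed gate.
5. **Interactor gate.** `is_interactor` requires ≥10-fold linear enrichment
   (inclusive) *and* raw P < 0.01 (exclusive). Both knobs are parameters;
   a laxer P < 0.05 variant exists in the field and is one flag away.
6. **Nuclease classes.** Interactions that retain ≥8-fold enrichment after
   Benzonase (a promiscuous nuclease) digestion of the cross-linked
   chromatin are `direct`; interactions enriched untreated but collapsing
   below 8-fold after Benzonase are `dna_bridged` — the bait and prey were
   held together by DNA, not protein contact. Proteins absent from the
   treated stratum are `indeterminate`, never silently dropped. Each
   nuclease stratum is scored against its own controls.

Testing on imputed (not observed-only) values is deliberate: the stated
workflow imputes before testing, and the calibration tests confirm the
composite procedure keeps its nominal type-I error at the simulated
missingness level (~15%). Proteins observed in under half the samples of
both arms are flagged `low_detection` but retained.

## 2. Cistrome algebra

Peaks are fixed intervals (0-based half-open everywhere; BED I/O is native
in that convention and 1-based tables convert at the boundary). Signal is
rpm = reads × 10⁶ / library size; browser-track RPTM is 10 × rpm.

* **Filtering**: keep peaks with rpm above the per-factor cutoff (2 for the
  PROX1-like factor, 1.5 for the HDAC3-like one) and more than threefold
  over input. The fold-over-input gate uses the input rpm as-is
  (an optional pseudocount parameter exists, default 0, so the printed rule
  applies verbatim).
* **Co-binding**: a peak is co-bound when a partner-factor peak overlaps at
  least 50% of *its* length and the partner signal there is at least 1 rpm.
  The overlap fraction is evaluated from both sides and a peak co-bound
  from either side joins the co-bound class; with called-peak inputs the
  partner signal at a query peak is the overlapping partner peak's rpm.
  Ties go to the maximally overlapping partner, then lexicographic id.
  Venn counts are reported in the A-side convention (each co-bound region
  counted once from the A side), stated in the output header.
* **Third-factor intersection**: the C cistrome is pre-filtered (>2 rpm,
  threefold over input) and additionally stripped of knockout-persistent
  peaks (KO rpm ≥ 50% of control rpm cannot be specific C binding; the
  ratio is a config key). Class-wise bound fractions are compared with
  Pearson's χ².
* **Knockout dependency**: fold decrease = (control rpm + 0.1)/(KO rpm +
  0.1); `lost` at ≥2-fold (inclusive). The 0.1 rpm pseudocount guards
  empty knockout peaks and is scale-invariant because rpm itself is.
  Peak intensity means rpm over the fixed called interval; peaks are never
  re-called in the knockout.
* **Correlation**: Pearson r of the two factors' rpm over the merged union
  peak set.

## 3. Motif enrichment between peak classes

Scanning uses position probability matrices with log2-odds scores against a
background model (uniform by default), over 200 bp windows centred on peak
midpoints, both strands, all offsets; `N` scores −∞ and edge windows are
clipped with a warning. The hit threshold defaults to 80% of a motif's
maximal score — per-motif thresholds of the original discovery tool are not
published, so frequencies are threshold-dependent and only class
*contrasts* are asserted. Three idealised motifs ship for the synthetic
genome (a DR1-type direct repeat for the recruiting factor, a DR2-type
repeat, and a CCAAT-box-like palindrome); real JASPAR text is read with
`read_jaspar()`. Class frequencies are compared by Pearson's χ² without
continuity correction, switching to Fisher's exact test with a warning when
any expected cell drops below 1.

## 4. Expression coregulation and the association test

The differential-expression engine is an explicit stand-in: log2 CPM with a
pseudocount of 1 (library size = column sum) and a per-gene Welch t-test.
A full isoform-level quantification engine is out of scope; the scientific
content carried forward is the printed gate — |fold| ≥ 1.7 (inclusive) and
P < 0.05 — and the coregulation logic. The stand-in sits behind one
function (`de_test()`) so a different engine can be swapped in without
touching anything downstream.

Genes passing the gate in *both* perturbations split by sign agreement into
`correlated` and `anti_correlated`; overlap significance uses Fisher's
exact test (no single canonical test exists for such an overlap; this is
a package choice, recorded here). The cross-omic association asks whether genes near
knockout-dependent co-bound sites are preferentially coregulated: genes link
to peaks either by nearest TSS within 100 kb or by the strand-aware window
\[TSS − 50 kb, TES + 2 kb\] (closed boundaries, midpoint anchor,
multi-gene links allowed; the window convention is the default for the
association). The 2×2 table — has/lacks a dependent co-bound link ×
coregulated/unchanged — is tested with the χ² test with Yates continuity
correction. The universe is coregulated genes plus genes failing the gate
in **both** arms; single-arm passers are ambiguous and excluded, and
anti-correlated genes are excluded from "coregulated" by default
(`include_anti_correlated` reverses that), since the biological claim
concerns co-repression.

Small-sample utilities mirror the remaining printed statistics: a two-sided
Wilcoxon–Mann–Whitney (exact below a combined n of 20 without ties, normal
approximation with tie correction otherwise) for binding-strength
comparisons, and a one-tailed pooled-variance t-test for sequential-ChIP
(reChIP) enrichment over IgG.

## 5. The synthetic study and its defaults

`sim_config()` fixes the whole synthetic dataset from one seed. Its
defaults *are* the emulated study conditions and are not tuned per run:

| parameter | default | meaning |
|---|---|---|
| `n_proteins`, `n_true_interactors`, `n_dna_bridged` | 2000 / 50 / 20 | spiked interactome |
| `interactor_effect` | 16 | linear bait enrichment of true interactors |
| `n_bait_samples`, `n_control_samples` | 11 / 13 | IPs per nuclease stratum |
| `missingness_steepness`, `missingness_midpoint` | 0.8 / 24 | logistic MNAR on log2 intensity (~15% missing) |
| `genome` | chr1 60 Mb + chr2 40 Mb | toy genome |
| `n_peaks_per_factor`, `peak_width` | 1000 / 200 bp | cistrome scale |
| `frac_cobound` | 0.4 | A/B peaks planted at shared C-motif loci |
| `dependency_effect` | 4 | fold collapse of dependent peaks in the C knockout |
| `read_depth` | 50 | mean ChIP reads per peak (library 10⁷) |
| `n_genes` | 2000 | transcriptome |
| `coupling_pi` | 0.6 | P(gene near a dependent site is planted co-upregulated) |
| `de_effect`, `dispersion` | 2 / 0.05 | planted fold change; NB dispersion |
| `n_samples_expression` | 2/3/3/3 | control_A / KO_A / control_B / KD_B replicates |

Where the emulated study design fixes a value (sample sizes, 16-fold
spikes among 2000 proteins, depth-50 dependent peaks collapsing fourfold,
coupling 0.6), the default is that value. Where it does not, the choice is
an engineering one made once: peptide intensities are log-normal
(protein mean log2 ~ N(27, 2), peptide ionisation ~ N(0, 1), replicate
noise ~ N(0, 0.5)); missingness parameters give a realistic ~15% missing
rate concentrated at low abundance; ChIP reads are Poisson (counts over
fixed small windows), expression counts negative-binomial (where
over-dispersion actually matters); and the toy genome is kept large
relative to the 50 kb linking windows so that dependent co-bound sites sit
near a minority (~20%) of genes — on a small dense genome the windows
would cover most genes, the CPM renormalisation would absorb the planted
fold changes, and the association contrast would vanish, which is a
property of the geometry rather than of the method.

Co-bound A/B peaks are jittered ≤ peak_width/5 around their shared locus so
pairwise overlap stays above 50% by construction; DR1 consensus sequence is
planted at C-motif loci and DR2 consensus at A-only loci. All co-bound
peaks are the dependent set (recruitment by C is what co-binding means in
this design), so dependency specificity is measured on the factor-only
peaks.

**What passing tests show — and do not show.** The generator matches the
*statistical structure* the analysis assumes: MNAR missingness, Poisson /
negative-binomial counting noise, motif-nucleated co-binding, coupled
upregulation. It does not emulate peptide misidentification, protein
inference ambiguity, read mappability or GC structure, peak-calling
artefacts, correlated replicates, or batch effects. Recovery results
(e.g. interactor sensitivity ≥ 0.9 at the default conditions) therefore
validate the implementation and the thresholds' internal logic on data
satisfying the model's assumptions — they are not performance claims about
any real dataset.

## 6. Numerical and calibration notes

* All randomness flows through one seeded entry point per stage (a fixed
  offset per generator under the master seed), so identical configs give
  bit-identical files and the pipeline manifest is byte-reproducible.
* Gates at printed values are inclusive on the fold side
  (≥ log2(10), ≥ 2-fold decrease, ≥ log2(1.7), ≥ 50% overlap, ≥ 1 rpm,
  ≥ 8-fold retention) and exclusive on the P side (< 0.01, < 0.05), and
  unit tests pin each boundary.
* Degenerate inputs are defined, not NaN: identical arms give t = 0 and
  P = 1; an all-tied rank-sum gives P = 1; zero within-arm variance with
  unequal means gives P = 0; a degenerate 2×2 margin is an error.
* The Yates-corrected χ² and Fisher's exact test are conservative discrete
  tests; null calibration therefore asserts their rejection rate does not
  *exceed* nominal. The interactome's pooled t-test is calibrated on the
  nose (null rejection ≈ 0.052 at α = 0.05 over 500 seeded replicates,
  imputation included), and is checked two-sided. The expression stand-in's
  Welch t at 3 replicates per arm on heavy-tailed counts is mildly
  conservative (≈ 0.035 at α = 0.05); its calibration check is one-sided
  against exceeding nominal.
* The Yates statistic follows `chisq.test`'s convention of truncating the
  correction at |O − E|; the textbook closed form agrees whenever
  |O − E| ≥ 0.5, which the oracle tests enforce.
* Welch power at the expression defaults is modest by design honesty: at a
  true 2-fold change, dispersion 0.05 and 3 replicates per arm, the
  gate's Monte-Carlo ceiling is ≈ 0.64 sensitivity (and lower in the
  2-replicate arm), so coregulated-gene recovery is partial; the
  association test remains decisive because the called set is almost pure.
  The tests assert that computed regime rather than an unattainable one.
* Test-suite problem sizes (e.g. 120–500 proteins or genes per calibration
  replicate, 20 association seeds) are chosen so the full suite exercises
  every stage at the default conditions at least once while staying
  desk-scale.

## 7. Known limitations

* Cross-factor signal at a peak is the partner peak's rpm, not re-counted
  coverage; with fixed-width synthetic peaks these coincide, with real
  ragged peaks they differ slightly.
* The DE stand-in has no dispersion shrinkage; its power at n = 2–3 per arm
  is correspondingly low, which the study design itself shares.
* Motif hit fractions depend on the 80%-of-max threshold; only contrasts
  between peak classes, not absolute frequencies, are meaningful.
* The interactome t-test assumes equal arm variances (that is the printed
  procedure); strongly heteroscedastic arms would mis-calibrate it, and the
  Welch variant used in the expression module is the obvious swap-in.
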