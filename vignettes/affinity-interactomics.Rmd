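---
title: "Quantitative affinity interactomics with affinomap: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative affinity interactomics with affinomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affinomap)
```

# The measurement model

The holdup assay measures, at equilibrium, the fraction of a prey molecule
depleted from solution by a bait-saturated resin relative to a control
resin. Because the immobilized bait is in large excess over every prey in a
dilute extract, each prey independently follows the single-site binding
isotherm, and the depleted fraction — the binding intensity, BI — relates
to the equilibrium dissociation constant by the hyperbola

$$\mathrm{BI} = \frac{[\mathrm{bait}]}{[\mathrm{bait}] + K_d},
\qquad
K_d = [\mathrm{bait}]\,\frac{1-\mathrm{BI}}{\mathrm{BI}}.$$

Affinities are reported as $pK = -\log_{10} K_d$ (molar), so pK 4
corresponds to 100 uM and differences in pK are proportional to binding
free-energy differences. All package internals carry molar concentrations;
conversion from uM/nM happens at the I/O boundary only, which removes a
whole class of silent unit bugs from the pK transforms.

Measurements below a panel's BI detection threshold carry no quantifiable
affinity. `censor_affinity()` assigns them the threshold's own hyperbolic
pK with a `censored` flag, interpretable as an upper bound on the true
affinity. Two conventions are fixed deliberately: a value exactly at the
threshold is censored (deterministic tie-breaking), and raw negative BI
(expected measurement noise) is clamped to zero and flagged, while BI >= 1
is rejected as physically impossible rather than clamped.

# Native-holdup proteomics

`nhu_depletion()` reproduces the standard analysis of a single-point
native-holdup mass-spectrometry experiment at 10 uM estimated bait
concentration:

1. **Median normalization.** Every sample is rescaled by one factor so its
   median detected intensity matches the grand median, correcting minor
   loading differences. The step is idempotent. It presumes *sparse*
   binding: when only a few percent of proteins are depleted, the sample
   median is carried by non-binders and the factor is unbiased. (See the
   synthetic-data section for why this matters to the generator design.)
2. **Low-decile imputation.** Missing intensities are replaced by uniform
   draws from the pool of detected values at or below the lowest decile of
   the *entire* dataset (not per sample), reflecting that label-free MS
   missingness concentrates near the sensitivity floor. Detected cells are
   left bit-identical; the draw is deterministic given `seed`.
3. **Depletion test.** An unpaired two-tailed equal-variance t-test on
   log2 intensities, bait arm versus control arm, with injection
   replicates treated as exchangeable. The log2 fold change converts to
   BI as $\mathrm{BI} = 1 - 2^{\mathrm{log2fc}}$ — the group-mean log2
   form matches the log2-domain test and is robust to replicate skew —
   and then to a censored apparent pK.
4. **Significance gate.** A protein is called a partner when
   `pvalue <= p_cap` (default 0.05) *and* `bi >= bi_threshold` (default
   0.128). The gate is conjunctive and both knobs are recorded on the
   result. Note the default BI threshold corresponds to a Kd of ~68 uM
   (pK ~4.17) at 10 uM bait.

The gate's false-positive behavior depends directly on analytical
precision. With 3 + 3 replicates, the t-test alone admits 2.5% of
non-binders in the depleted direction at `p_cap = 0.05`; whether the BI
gate tightens this depends on the intensity noise. At 15% CV the threshold
sits ~1.1 standard errors from zero and the realized false-call rate is
~2%; at injection-replicate precision (~5% CV) it falls below 0.1%. Users
analyzing noisier data should lower `p_cap` or raise `bi_threshold`
accordingly.

`compare_experiments()` implements cross-experiment recall with the
convention that a partner significant in one experiment counts as
recovered in the other if it is significant there, *or* depleted above the
BI threshold while sub-significant — treating measured depletion as true
for partners under the statistical threshold. The strict
significant-only definition is available via `recovered = "significant"`.
Affinity agreement is summarized by the Pearson correlation of pK values
over partners significant in both experiments, an ordinary least-squares
fit with a pointwise 95% confidence band, and a correlation p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.
`interactome_similarity()` applies the same statistic across bait pairs.

# Titration fitting with partial activity

Titration holdup varies the effective bait concentration by mixing
bait-saturated and control resin in proportions (`make_dilution_series()`).
`fit_titration()` fits

$$\mathrm{FB}(c) = a\,\frac{c}{c + K_d}$$

where the amplitude $a \in (0, 1]$ is the *active fraction*: a fitted
$a < 1$ means only part of the prey population is binding-competent, a
phenomenon observed for multidomain preys in cell extracts. Initialization
is scale-free ($a_0$ = max observed FB clipped into (0, 1]; $K_{d,0}$ =
the concentration whose response is nearest $a_0/2$), bounds are
$K_d \in [10^{-12}, 10^{-2}]$ M and $a \in (0, 1]$, and the loss is
unweighted least squares on replicate means (replicate SDs may be passed
as weights). Standard errors come from the curvature at the optimum
(Levenberg-Marquardt via minpack.lm). Curves whose responses never exceed
`min_signal` (default 0.05) are reported as "no detectable binding" rather
than fit; fitting noiseless hyperbolic data with the free-amplitude model
returns $a = 1$ to numerical precision.

# PxxP motif discovery

SH3 domains bind proline-rich motifs in intrinsically disordered regions.
`scan_prms()` reports *every* (possibly overlapping) match of the class 1
consensus `[RK]..P..P` (7 residues) and class 2 consensus `P..P.[RK]`
(6 residues), where `.` means any residue including P/R/K; a window
matching both classes yields two records, and tandem overlapping motifs
are all counted. By default every residue of the core must lie inside the
disorder mask (`require_disorder = TRUE`); masks are consumed as input
from any disorder predictor and are not re-derived. Coordinates are
1-based inclusive throughout, matching biological variant nomenclature.

`design_peptide()` produces the 15-mer synthesis window centered on the
core midpoint (ties toward the N-terminus, so a 15-mer carries the core
midpoint at position 8), truncating — never shifting — at protein termini,
with truncation flagged.

# Fragmentomic profiling

Plate-format holdup against the synthetic peptide panel is read out by
intrinsic Trp fluorescence with fluorescein and mCherry as internal
standards. `plate_to_bi()` divides the Trp sample/control ratio by the
*geometric mean* of the two standard ratios — the symmetric treatment of
two independent loading controls — and clamps the resulting depletion into
[0, 1). `build_profile()` applies the censoring rule at the panel
threshold (default `bi_threshold = 0.02` at 4 uM bait, i.e. a detection
limit of ~196 uM Kd, pK 3.71, consistent with panels whose binders span
low-micromolar to a few hundred micromolar affinities) and fixes the panel
order so profiles of different baits are comparable dimension by
dimension.

Error propagation sets what such plates can resolve: with
$\mathrm{BI} = 1 - r$ for corrected ratio $r$,
$\sigma_{pK} \approx 0.434\,\sigma_r / \mathrm{BI}$, so a 2% per-channel
noise (about 3.5% on the six-channel corrected ratio) gives a +-0.15 pK
3-sigma envelope only for BI above ~0.3 (Kd below ~8 uM at 4 uM bait);
weaker binders carry proportionally larger pK uncertainty. The package's
tests assert recovery bounds on exactly the range this arithmetic
supports.

`compare_fl_vs_motifs()` contrasts intact-protein (native holdup) and
best-motif (fragmentomic) affinities per protein: Pearson correlation,
mean/median of $pK_{FL} - pK_{best\,motif}$, and the fraction of proteins
binding strictly stronger as the intact protein. Best-motif selection uses
uncensored motifs only; proteins whose motifs are all censored are counted
separately rather than silently dropped.

`specificity_logo()` weights each binder by its pK margin above the
detection threshold — proportional to its binding free-energy margin, the
natural "affinity-weighted" scheme — and normalizes every position to sum
to one, so uniformly rescaling all margins leaves the logo unchanged.

# Variant affinity distances

Variant impact is quantified in the panel's pK space:
$d = \sqrt{\sum_i (pK_{WT,i} - pK_{var,i})^2}$, which aggregates
binding-energy perturbations across the interactome. Censored entries are
substituted by the detection pK, so whenever a censored value enters the
sum only a *lower bound* of the distance is obtained (`is_lower_bound`).
Dimensions censored in both profiles carry no information about either
value and contribute zero — not a threshold-minus-threshold residue — so a
profile's distance to itself is exactly zero even on partially censored
panels.

`classify_variant()` separates three regimes: **LOF** when at least
`lof_fraction` (default 0.9) of the WT-detectable motifs lose detectable
binding; **PAP** (perturbed affinity profile) when binding is broadly
retained but the distance exceeds a noise distance; **WT-like** otherwise.
No numeric PAP cutoff is inherited from any published analysis — the noise
distance is derived from data, by default as 1.5x the largest pairwise
distance among replicate WT profiles
(`noise_distance_from_replicates()`), and both thresholds are recorded in
the output.

# PSSM-based motif conservation

The binding-motif PSSM is the canonical pseudocount log-odds matrix over
the 15-mer frame (consensus core at positions 7-10): with $c_{ij}$ the
count of amino acid $i$ at position $j$ among the $m$ training motifs,
pseudocount $B = 5$, and background frequency $D_i$,

$$P_{j,i} = \ln\!\left(\frac{(c_{ij} + B/20)/(m + B)}{D_i}\right).$$

The smoothed frequencies reconstitute exactly:
$\sum_i e^{P_{j,i}} D_i = 1$ at every position, a property the tests
exercise. The default background is the average eukaryotic proteome
composition (`aa_background()`). Alignment gaps and unknown residues score
the position minimum, since a gap cannot support a motif.

Ortholog motif instances are scored as the ratio to the human reference's
raw score (`normalized_score()`); the human window itself scores 1.
A non-positive human reference score makes the ratio uninterpretable and
is flagged undefined rather than guessed. Conservation is evaluated on the
ordered taxonomic scheme Mammalia < Vertebrata < Eumetazoa < Unicellular
(eukaryotes), with the human reference as the implicit innermost tier: a
level needs at least `min_orthologs = 3` sequences, is conserved when its
mean normalized score exceeds 0.5, and the conservation depth is the most
distal conserved level ("human-only" when none is). Depth requires
conservation at the named level itself, not at every intermediate level;
intermediate gaps are reported so stricter monotone rules can be applied
downstream.

# What the synthetic data emulates — and what it does not

Every generator is a pure function of its configuration and `seed`
(`set.seed(seed)` is called internally), so reruns are byte-identical.

* `generate_proteome()` draws background-composition sequences with one
  contiguous disordered stretch, implants class 1/2 cores inside it in 25%
  of proteins (the proteome-wide PRM-carrying baseline), and makes a
  sparse 3% of proteins true binders — matching the prevalence of a real
  native-holdup screen, where ~200 of ~6,400 assayed proteins bind.
  Keeping these two rates distinct is essential: median normalization is
  only unbiased under sparse binding, and an early draft that conflated
  them produced a visible depletion bias. Motif Kds are log-uniform over
  0.5-300 uM; the full-length protein Kd is the best motif Kd divided by
  an avidity factor log-uniform in [1, 10], emulating the observation that
  intact proteins bind several-fold stronger than their isolated motifs.
  Abundances are log-normal (sdlog 1.5).
* `simulate_nhu_ms()` multiplies abundances by $1-\mathrm{BI}$ in the bait
  arm, applies multiplicative log-normal noise (default CV 15%), and
  deletes values with a logistic missing-not-at-random model in log10
  intensity — the behavior the low-decile imputation rule presumes.
* `simulate_fragment_holdup()` gives each well a loading factor shared by
  all three channels (which the internal-standard correction must remove)
  plus 2% per-channel noise.
* `simulate_titration()` adds Gaussian noise (sd 0.03) to the
  partial-activity isotherm, the scale of densitometry replicates.
* `simulate_orthologs()` encodes a planted conservation depth by
  *destroying* the motif (background windows) beyond the planted level and
  applying a flat 5% non-core substitution rate at conserved levels. The
  flat rate is deliberate: scaling substitution with taxonomic distance
  can push a "conserved" deep level below the 0.5 score definition,
  making the planted label internally inconsistent.
* `simulate_variant_profile()` constructs the three variant classes:
  benign = WT plus 0.05 pK replicate noise; PAP = a -0.8 pK shift on 60%
  of detectable binders plus noise; LOF = all binding lost. Values falling
  below the detection pK re-censor, so PAP variants can genuinely lose
  their weakest motifs, as real perturbed domains do.

The generators deliberately do **not** emulate peptide-to-protein
inference, spectral processing, batch effects, correlated noise between
proteins, real disorder predictors, plate-recycling drift beyond a
per-well scalar, or phylogenetic correlation structure among orthologs.
Passing the recovery tests therefore demonstrates that the *statistical
pipeline* is correct and well-calibrated under its stated assumptions, not
that those assumptions hold for any particular instrument or organism.

# Problem sizes and numerical choices

The package's own verification uses a 2,000-protein simulated extract for
the native-holdup recovery check (planted binders in the quantifiable
0.5-34 uM window, recovered within +-0.3 pK for >= 80% with Spearman
>= 0.9 against truth), 200 simulated titration curves (median
|log10 Kd| error <= 0.1, median active-fraction error <= 0.05), 100
ortholog sets (>= 95% planted-depth recovery), and 30 constructed variant
profiles (100% class recovery). These sizes give stable statistics while
keeping the whole suite fast enough to run routinely.

Other numerical conventions: BI/Kd round-trips are exact to 1e-12
relative error over BI in (0.001, 0.999); equal-variance t-tests with zero
pooled variance return p = 1 for equal means and the smallest
representable positive double otherwise; the titration fit warns when the
Kd estimate sits at a parameter bound (data not bracketing the Kd); and
degenerate inputs (empty panels, all-censored profiles, fewer than three
shared partners) are flagged rather than silently propagated.

# Known limitations

* The hyperbolic model is single-site and non-cooperative; avidity,
  oligomerization, and multi-motif synergy are outside its scope and
  surface only as full-length-versus-motif pK differences.
* Raw p-values are thresholded without multiple-testing correction,
  mirroring standard holdup-proteomics practice; the false-positive rate
  therefore depends on analytical precision as quantified above.
* Censored distances are lower bounds; comparing variants with very
  different censoring patterns compares bounds, not exact distances.
* The conservation scheme treats ortholog sets as given (prediction and
  alignment happen upstream) and scores levels independently, without a
  phylogenetic model.
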