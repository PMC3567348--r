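---
title: "Chemical-genetic fitness profiling with fitscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-genetic fitness profiling with fitscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscreen)
```

# Scope

`fitscreen` implements the computational core of a functional toxicogenomic
screen in budding yeast. Four analyses are covered, each usable on its own:

1. **Growth kinetics** — plate-reader OD time series to background-corrected
   curves, area-under-curve (AUC) total-growth measures, dose-response
   inhibition profiles, ICx estimates and pooled-variance group comparisons.
2. **Differential strain sensitivity analysis (DSSA)** — pooled
   deletion-strain barcode-array intensities to per-gene
   sensitive/resistant calls with q-values and fitness scores.
3. **Gene-set enrichment** — hypergeometric over-representation against a
   fixed annotation universe or a user-defined reference set.
4. **Reporter PELI analysis** — real-time GFP stress-reporter time courses
   to induction factors, the Protein Expression Level Index, and
   activation calls.

A fifth module generates seeded synthetic inputs with the statistical
structure the analyses assume, so every stage can be exercised against
ground truth.

# Growth kinetics

Raw plates arrive as a wide table (`time_min` plus one column per well) with
a well map assigning strain, dose, replicate and role. Correction subtracts
the per-time-point mean of the blank wells from every sample well; negative
corrected values are floored at zero and flagged rather than rejected,
because blank drift routinely exceeds the early-time signal of a dilute
inoculum. Total growth is the trapezoidal AUC in OD·h over the 24 h window.

Replicate handling follows the assay's reporting convention: curves are
averaged across replicates for display, but all statistics (standard
errors, t-tests) are computed on per-replicate AUC values, which is what
biological-replicate error bars describe.

Growth inhibition at dose $d$ is $1 - \overline{AUC}(d)/\overline{AUC}(0)$.
The ICx is found by piecewise-linear interpolation of inhibition against
$\log_{10}$ dose between the two positive doses bracketing $x/100$. No
published formula exists for this interpolation in the assay literature we
mirror, so the simplest monotone scheme on the natural (logarithmic) dose
axis was chosen; the zero dose cannot sit on a log axis and instead anchors
the baseline. When the target inhibition lies outside the measured range
the nearest dose is returned with an `extrapolated` flag — an estimate that
should be treated as a bound, not a value.

Group comparisons use the two-sided pooled-variance (equal-variance)
Student t-test. Degenerate inputs are given explicit conventions: zero
pooled variance with equal means returns $p = 1$; with unequal means,
$p = 0$. Sequential-dose significance testing (each dose against the next)
is provided by composing `compare_groups` over adjacent doses; no
multiplicity correction is applied there because the mirrored reporting
convention applies none.

Dose units convert as $\mathrm{mg/L} = \mu M \times M / 1000$ with $M$ the
molar mass in g/mol (252.31 for benzo[a]pyrene, the package's worked
example: 330 µM ↔ 83.26 mg/L, 82.5 µM ↔ 20.82 mg/L).

# Differential strain sensitivity analysis

The DSSA input is an `array_experiment`: probe-level intensities across
arrays, a probe→gene map with *null features* (probes matching no strain
barcode), and per-array condition metadata. The stages are:

**Preprocessing.** Intensities above the saturation ceiling are winsorized
to the ceiling and flagged — saturation compresses log-ratios, and clipping
preserves rank without letting saturated probes fake small ratios. Signals
are $\log_2(x + 1)$ transformed (the pseudocount of one signal unit avoids
$-\infty$ on empty probes and is negligible against typical signals in the
thousands). The median of each array's log2 null features is subtracted, so
chip background sits at zero on every array, and the null-feature MAD
(scaled by 1.4826 to estimate a Gaussian SD) is retained as the array's
background scale.

**Pairing.** Each treatment array is matched to *every* control array of
the same generation arm, so three biological replicates against twelve
controls give 36 treatment–control pairs per condition. Pairing across
generation arms requires an explicit override.

**Pair normalization.** Within a pair, $M = \log_2 t - \log_2 c$ and
$A = (\log_2 t + \log_2 c)/2$; a robust lowess fit of $M$ on $A$ (span 0.4,
3 robustifying iterations — conventional MA-normalization defaults) is
subtracted, removing intensity-dependent trends. Below 30 genes a lowess
fit is not meaningful and the global median is subtracted instead, flagged.

**Alpha-outlier calling.** Within each normalized pair, the median and
MAD×1.4826 of the m-values define a robust Gaussian reference null; each
gene receives a two-sided p-value, Benjamini–Hochberg q-values control the
per-pair false discovery rate, and genes with $q \le \alpha$ (default 0.05)
are called with the sign of their deviation. The robust center and scale
make the null insensitive to the (sparse) true signal. If every m-value is
identical the scale is zero and no outliers exist.

**Effective pairs.** Pairs with abnormally high residual variance (robust
scale² of their m-values) are excluded by the Tukey upper fence
$Q_3 + 1.5\,\mathrm{IQR}$ over the group's pairs — the programmatic
equivalent of discarding box-plot outliers by inspection. A lag-1
autocorrelation of the per-pair scales is reported so serial patterns in
variability can be reviewed, but it never excludes automatically: that
judgment is left to the analyst.

**Binomial aggregation.** Per gene, the dominant sign is the strict
majority sign over effective pairs (an exact tie yields no call — the
same-sign requirement has no natural tie-break, and refusing to call is the
conservative choice). A pair is a success when the gene is called there
with the dominant sign; with $k$ successes over $m$ effective pairs the raw
p-value is the exact upper binomial tail $P(X \ge k \mid m, \pi_0)$, and
q-values over all genes control the FDR at 0.05. The null success
probability $\pi_0$ defaults to the per-pair call level (0.05): under the
null, a gene is called in a pair with probability at most the level at
which the per-pair FDR is controlled. An empirical alternative (the
observed mean per-pair call rate) is available for screens whose per-pair
calibration is in doubt. In **strict** mode (the default classification) a
call additionally requires success in *all* effective pairs
simultaneously; the non-strict tail-only mode is kept because the strict
rule's all-or-nothing character makes it fragile at large $m$, and the two
modes bracket reasonable readings of the same-sign-in-all-pairs rule.
Benjamini–Hochberg is the default q-value method because it is
deterministic and assumption-light; a pi0-adaptive estimate can be layered
on by the user but is not the default.

**Fitness scores.** The per-gene score is the mean adjusted log2 signal
over exposed arrays minus the mean over control arrays. Negative scores
mean the deletion strain lost abundance under exposure — the deleted gene
is needed for tolerance (*sensitive*); positive scores mean *resistant*.
Labels are assigned from the score's sign for called genes, so the label
and score can never disagree.

**Summaries.** Per-condition sensitive/resistant counts, union counts over
all conditions, genes recurring in at least three conditions, and the
overlap between generation arms are exported as plain tables.

# Gene-set enrichment

Over-representation uses the upper hypergeometric tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeometric}(N, K, n)$, computed with
R's `phyper`. Two reference modes are supported: the fixed annotation universe, and a
user-defined reference set in which $N$ is the reference size,
with category sizes and observed counts intersected into the reference.
Raw p-values at a 0.01 threshold are reported without cross-category
correction, matching the screening convention mirrored here; a BH column is
emitted for readers who want it but is not used for filtering. Test-set
genes absent from the reference are dropped and counted in a message —
silent coercion would change $n$ invisibly.

Annotations travel as GMT files (one category per line). The package ships
a reconstruction of a 123-ORF stress-response reporter library and its GO
categories under `inst/extdata/`; files are suffixed `_synthetic` because
membership beyond the published counts was completed with placeholder
choices. The worked example — both 3-member categories fully contained in a
24-ORF activated set against the 123-ORF reference — depends only on the
published sizes and reproduces $p = 0.0067$, printed as 0.007.

# Reporter PELI analysis

Reporter plates carry paired OD and GFP channels on a shared grid (default
every 5 min over 2 h). The chain is:

1. **Medium correction**: the per-time mean of the medium-control wells
   matched to each well's chemical condition (same dose, falling back to
   dose-0 medium wells) is subtracted from both channels. Corrected values
   are floored at $10^{-4}$ of the channel's dynamic range and flagged;
   early-time OD sits so close to the medium background that occasional
   negative differences are expected measurement noise, not errors.
2. **Per-cell expression**: $P = \mathrm{GFP_c} / \mathrm{OD_c}$ pointwise.
3. **Plate normalization** (optional): $P$ divided by the per-time median
   $P$ of designated internal-control wells. This is the simplest scheme
   that cancels any plate-wide multiplicative factor exactly; it is
   skipped, with a warning, when no internal controls are designated.
4. **Induction**: $I(t) = P_{\mathrm{experiment}} / P_{\mathrm{vehicle}}$,
   vehicle matched by ORF and replicate (replicate-averaged vehicle when
   replicate ids differ).
5. **PELI**: the trapezoidal integral of $I$ over the recorded window
   divided by the window length — a time-average, so a vehicle-vs-vehicle
   series gives PELI exactly 1. This reading of the integral-over-exposure
   definition is the only one under which the signal-to-noise activation
   cutoff of 1.5 is meaningful as a fold-change-like quantity.
6. **Calls**: replicate PELIs are summarized as mean ± sample SD (sample,
   not population, since triplicates estimate a population), and an ORF is
   *activated* when the mean exceeds the cutoff (default 1.5). The call is
   on the mean, not per-replicate votes, matching the mean ± SD reporting
   convention.

Exports are the ln(I) heat-map matrix with rows grouped by stress category,
and per-dose rank profiles (PELI descending, ties broken lexicographically
by ORF so ranking is deterministic).

# Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions; their defaults are
fixed design choices, not tuning knobs.

**Pooled screen** (`simulate_pool_screen`). A pool of 4,000 strains (2,000
null features) emulating a genome-scale deletion collection at reduced
size. Starting abundances are lognormal (sdlog 0.5), a realistic pool
imbalance. Competitive growth over $g \in \{5, 15\}$ generations multiplies
strain $i$ by $2^{g(1-s_i)}$: $s_i > 0$ is a fitness deficit (expected
sensitive call), $s_i < 0$ a gain. Abundances renormalize to relative
abundance (they sum to one before hybridization). Hybridization is a
saturating Michaelis-type map — signal
$= A\,a/(a + h)$ with asymptote $A = 16384$ and half-saturation $h$ at four
times the mean relative abundance — times lognormal measurement noise
(sdlog 0.1, a ~10% CV typical of replicate barcode hybridizations). Null
features are lognormal background (median 64, sdlog 0.4 on the natural
log). The default saturation ceiling sits at $0.41A$, near the upper
percentiles of the simulated signal distribution, so a small fraction of
probes (~1–2%) genuinely exercises the winsorization path. Dose scaling of
the selection coefficient is proportional by default
($s_{\mathrm{eff}} = s\,d/d_{\max}$); a threshold mode applies full $s$ at
any positive dose, emulating the sharp threshold response regime where
call counts do not vary with dose.

What this does *not* model: probe cross-hybridization, spatial artifacts,
biological replicate-to-replicate variation beyond measurement noise, and
any mechanistic toxicant chemistry. Passing recovery tests therefore show
the inference chain is correct and calibrated under its own assumptions,
not that real arrays meet those assumptions.

**Reporter plates** (`simulate_reporter_plate`). Logistic OD growth
(per-minute rate 0.008 — a ~90 min doubling time, carrying capacity 1.2,
inoculum 0.3, i.e. early-exponential cultures); vehicle GFP proportional
to OD (1000 fluorescence units per OD); experiment GFP scaled by the ORF's
true induction profile $I^*(t)$ (constant by default, arbitrary profiles
supported); both channels sit on medium backgrounds (0.04 OD, 50 GFP) with
2% multiplicative Gaussian noise. The ground truth is the time-average of
$I^*(t)$, which the zero-noise pipeline reproduces to $10^{-9}$.

**Dose-response growth** (`simulate_growth_doseresponse`). Curves share a
logistic time shape; the plateau is scaled by the Hill fraction
$f(d) = d^h/(d^h + \mathrm{IC}_{50}^h)$, so the true ICx has a closed form
($\mathrm{IC}_{20} = \mathrm{IC}_{50} (0.2/0.8)^{1/h}$; defaults
$\mathrm{IC}_{50} = 600$, $h = 2$, hence true IC20 = 300). The AUC-based
inhibition read by the pipeline differs from the plateau inhibition by a
small factor from the inoculum's contribution to the integral (<3% at the
defaults), which is part of what the recovery tolerance absorbs.

# Numerical and design choices

* All quadrature is trapezoidal on the recorded grid; no smoothing or
  resampling is applied before integration.
* Robust location/scale are median and MAD×1.4826 throughout.
* q-values are Benjamini–Hochberg; tie handling and monotonicity follow
  `p.adjust`.
* ICx interpolation is linear in $(\log_{10} d, \mathrm{inhibition})$;
  with a non-monotone profile the first bracketing interval in dose order
  is used.
* Lowess trend values are mapped back to the observations by linear
  interpolation of the fitted curve (`approx`, ties averaged, range rule
  at the extremes).
* Zero-variance degeneracies (identical replicate groups, constant
  m-values, zero internal-control expression) are explicit errors or
  explicit conventions rather than NaN propagation; each is documented on
  its function.
* Simulation problem sizes used by the test suite (4,000-strain screens,
  five seeds for the recovery study; 2,000-strain null screens; 10 seeds
  for IC20 and reporter recovery) keep the full suite under a few minutes
  while leaving the planted-effect recovery comfortably measurable; the
  generators accept full-scale parameters (4,757 strains, 18,000 null
  features) when more is wanted.

# Known limitations

* The alpha-outlier reference null is Gaussian; heavy-tailed pair noise
  would make per-pair calls anticonservative, though the binomial
  aggregation across 36 pairs buffers gene-level calls considerably.
* Strict mode's all-pairs requirement becomes very stringent as the number
  of effective pairs grows; at $m = 36$ it is close to demanding a
  noise-free gene. Non-strict mode is the recommended screen-level
  default and is what the recovery characteristics are stated for.
* The enrichment module deliberately performs no GO-graph propagation;
  categories are taken exactly as annotated in the GMT.
* CEL-file (raw array image) parsing is out of scope; the array reader
  starts from probe-level intensity tables.
* `run_pipeline` is a thin file-in/file-out orchestration of the module
  functions; it is a convenience, not a workflow engine.
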