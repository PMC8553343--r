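---
title: "Methods: dual-channel fluorescence pre-screening of resection margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel fluorescence pre-screening of resection margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginscreen)
```

# The screening problem

Intraoperative assessment of resected tumor margins by frozen section is
accurate but slow, so when many biopsies arrive at once only a few are
sectioned. A dual-activatable fluorescent molecular rotor offers a fast
gross pre-screen: it reports hypoxia-induced nitroreductase activity in
a green detection channel and elevated cytoplasmic viscosity in a red
channel, two independent hallmarks of tumor tissue. Specimens are
incubated with the probe, imaged in both channels, and triaged *before*
any sectioning: margins that light up in neither channel can be
deprioritized, and the rest flagged for priority pathology review.

`marginscreen` implements the quantitative side of that workflow:
probe calibration, image quantification, threshold derivation, triage
classification, and evaluation against H&E pathology, plus synthetic
generators that make every stage testable end to end.

# Models and procedures

## Förster–Hoffmann viscosity calibration

Molecular rotors lose fluorescence to intramolecular rotation; viscous
media restrict the rotation and restore emission. Empirically the
intensity follows a power law in solvent viscosity $\eta$:

$$\log_{10} I_f = c + x \log_{10}\eta .$$

`fit_forster_hoffmann()` estimates $(x, c)$ by ordinary least squares of
$\log_{10} I$ on $\log_{10}\eta$ and reports the Pearson correlation of
the log–log pairs. Base-10 logarithms are used throughout (the
convention in which these plots are drawn as lg *I* vs lg *η*), and the
published correlation coefficient for such calibrations is read as
Pearson's $r$ of the log–log pairs, not $r^2$. Plain unweighted OLS is
deliberate: the calibration is a small, clean spectrometer series and
nothing in the procedure calls for robust or weighted fits.
`invert_viscosity()` applies the closed-form inverse
$\eta = 10^{(\log_{10} I - c)/x}$, which the tests verify is an exact
round trip on the fit's domain.

## Nitroreductase titration and limit of detection

Over the enzyme's working range (0–9.0 µg/mL) probe intensity is linear
in concentration, $I = k\,\mathrm{conc} + b$, fit by OLS on the linear
scale (`fit_titration()`). The detection limit follows the standard
3-sigma rule,

$$\mathrm{LOD} = 3\sigma / k,$$

with $\sigma$ the standard deviation of blank replicates and $k$ the
calibration slope. Two conventions are worth stating because the rule
itself does not fix them:

- $\sigma$ is computed as the $n-1$ sample standard deviation
  (`blank_sigma()`). Whether a published $\sigma$ is a blank SD or a fit
  residual SD is often unstated, so `compute_lod()` also accepts an
  externally supplied $\sigma$ directly.
- LOD values are stored at full precision in both µg/mL and ng/mL
  (ng/mL = 1000 × µg/mL) and rounded only at display time, to 1 decimal
  in ng/mL (`format_lod()`). With the canonical calibration
  ($k = 11166.424$ per µg/mL, $\sigma = 77.883$) this renders as
  `r format_lod(compute_lod(11166.424, 77.883))` ng/mL.

`fold_enhancement()` reports the intensity ratio between the most and
least viscous conditions of a series — the ethanol-to-glycerol contrast,
about 18-fold for this probe.

## Image quantification

Specimens are imaged as paired single-channel 8-bit grayscale TIFFs
(gray levels 0–255). `segment_samples()` defines foreground as pixels
whose **per-pixel maximum across the two channels** exceeds a background
threshold: a specimen bright in only one channel — precisely the
prospective "suspiciously positive" case — must still be detected, so
neither channel alone may veto a pixel. Foreground is split into
connected components under 8-connectivity (diagonal specimen pixels
belong together; 4-connectivity is available), components below a
minimum area are discarded as debris, and regions are numbered in
reading order of their bounding-box corners so labels are deterministic.

The per-specimen statistic is the **maximum** gray level over the region
in each channel (`measure_sample()`), not a mean or median, and no
background subtraction is applied before taking it — the screening
statistic is deliberately the brightest pixel the specimen produced.
Defaults `bg_threshold = 30` and `min_area = 50` px are pragmatic
choices for imagery whose specimens sit far above a dim background; both
are exposed because real acquisitions vary. Whether a published
per-specimen maximum was taken over a drawn ROI or the full specimen
footprint is typically unstated; the region-based maximum is used here,
and a label-image override lets callers impose their own ROIs.

`pearson_colocalization()` computes the standard pixelwise Pearson
coefficient between two channels over an optional mask, the statistic
used to demonstrate organelle-level overlap of the two signals.

## Centroid threshold and triage rule

Training data are paired cancerous/noncancerous specimens of one cancer
type. Their per-specimen maxima form a scatter in the
(nitroreductase, viscosity) plane, and the decision point is the
**K-means centroid of that scatter**. A design question the method
leaves open is what k to use and whether the classes are clustered
jointly; because a *single* threshold pair per cancer type is what the
procedure produces, the package adopts the only reading consistent with
that: k = 1 over all training points jointly, i.e. the grand
componentwise mean, reported to 1 decimal (`derive_threshold()`). The
general `lloyd_kmeans()` (k-means++ seeding, Lloyd iterations,
empty-cluster re-seeding to the farthest point, deterministic under a
seed) is exported so the sensitivity of the threshold to k can be
explored, but k = 1 is the default and the documented interpretation.

The triage rule is a quadrant rule around the threshold
$(t_{\mathrm{ntr}}, t_{\mathrm{vis}})$: a channel is *high* when the
specimen's maximum is **at or above** the threshold. Both high → `++`
(definitely positive), exactly one high → `+` (suspiciously positive),
neither → `-` (negative). The tie convention (≥, not >) is a deliberate
choice the rule itself does not fix: a pre-screen must err toward
flagging tumor, so a specimen sitting exactly on the threshold is called
high. The rule is monotone — raising either intensity never moves a call
toward `-` — and partitions the 0–255 grid into exactly three regions,
both verified exhaustively in the tests.

Thresholds are cancer-type- and instrument-specific (different cameras,
exposure settings and organs shift the gray-scale distributions), so
they are always inputs — derived from training data or supplied as a
fixed pair — never constants of the package.

## Evaluation against pathology

H&E staining of permanent sections is the ground truth (`P`/`N`).
Screen-positive is {`++`, `+`}: any strong channel flags the specimen.
`confusion_summary()` reports TP/FP/TN/FN and sensitivity, specificity,
PPV and NPV. Two points of interpretation:

- A claim of perfectly "screening tumor-free samples from positive
  ones" can be read as specificity (TN/(TN+FP)) or as NPV
  (TN/(TN+FN)) — the clinically load-bearing number if a negative
  pre-screen is to end the case. Both are computed rather than guessing
  intent; on a cohort where all tumor-free margins fall in `-` and all
  tumor-involved ones screen positive, both are 1.
- Rates with zero denominators are reported as `NA` with a warning,
  never silently coerced to 0 or 1.

`group_crosstab()` gives the 3×2 triage-by-pathology table; its
marginals are tested to agree with the confusion counts on thousands of
fuzzed cohorts.

# The synthetic-data generators

The generators define the study conditions under which the package is
validated; they are first-class, tested code.

- **Viscosity series** (`gen_viscosity_series()`): intensities on the
  Förster–Hoffmann line with multiplicative Gaussian noise
  $I = 10^{c + x\log_{10}\eta}(1+\varepsilon)$,
  $\varepsilon \sim N(0, \texttt{rel\_noise})$. The default grid is 8
  log-spaced viscosities from ethanol (1.2 cP) to glycerol (945 cP) at
  ~20 °C — solvent handbook constants of the implementation, overridable.
  The default slope is not invented: `default_fh_slope()` solves
  $I(945)/I(1.2) = 18$, anchoring the generator to the probe's printed
  18-fold enhancement, so the noise-free default series reproduces that
  ratio by construction.
- **Titration** (`gen_ntr_titration()`): a line with slope 11166.424
  intensity units per µg/mL plus additive $N(0, 77.883)$ noise, and
  blank replicates from $N(\mathrm{intercept}, 77.883)$ — the canonical
  calibration numbers as defaults. Gaussian noise is used throughout the
  generators: it is the simplest model consistent with summarizing blank
  variation by a single SD.
- **Tissue images** (`gen_tissue_image()`): Gaussian background plus
  non-overlapping axis-aligned elliptical blobs (bounding-circle
  separation with a 2 px gap, 1000 placement attempts before a named
  error) whose pixels are $N(\text{class mean}, \text{class SD})$ per
  channel. The truth table records each blob's class and planted
  per-channel maximum read off the final quantized image, so
  "segmentation + measurement recovers the planted maximum *exactly*"
  is a meaningful test.
- **Margin cohorts** (`gen_margin_cohort()`): paired training specimens
  and an H&E-labeled test set with class-separated per-channel maxima.
  Defaults mirror the hepatocellular design: 9 training pairs and a
  35-piece test set (9 `P`, 26 `N`), positives around (200, 200) and
  negatives around (120, 120) gray levels with SD 10.

Intensities are quantized to integers and clipped to [0, 255] only at
the image and cohort level, mirroring 8-bit cameras; spectra stay
real-valued. An 8-bit dynamic range is an assumption, not a measured
fact about any particular imager — it is adopted because thresholds
near 160 only make sense on a 0–255 scale.

**What the generators do not emulate:** optics (PSF, blur),
photobleaching, spectral bleed-through between channels, illumination
gradients, specimen-shape irregularity, or inter-patient heterogeneity
beyond a shared class SD. Passing tests therefore demonstrate that the
*analysis* is correct under its stated statistical assumptions — not
that the probe or the imaging protocol achieves those statistics on real
tissue, which only the wet-lab data can show. In particular the 100%
specificity of the synthetic cohort is a property of the configured
class separation (8 SD between class means); real patient cohorts must
be evaluated through the same pipeline via the external-CSV inputs.

# Numerical and interface choices

- **Determinism.** Every generator takes a seed and scopes the RNG to
  the call (`withr::with_seed`), so results are bit-reproducible and do
  not disturb the caller's RNG stream. The pipeline fans one global seed
  out to per-stage sub-seeds by fixed offsets, so toggling one stage
  never perturbs another's draws; two runs from the same config and seed
  produce byte-identical artifacts.
- **Lloyd's algorithm.** k-means++ seeding; convergence when the largest
  centroid shift drops below `tol` (default 1e-8) or after `max_iter`
  (default 100); assignment ties break to the lowest cluster index;
  an emptied cluster is re-seeded to the point farthest from its
  assigned centroid. Inertia is recorded after every assignment step,
  and its monotone decrease is asserted in the tests.
- **Degenerate inputs** fail loudly and specifically: zero variance in
  log-viscosity or concentration is a degenerate fit, a constant channel
  over a colocalization mask is a degenerate input, a zero-slope law is
  non-invertible, and records missing a call or label are named in the
  error.
- **Interfaces.** Tables are plain CSV, images single-channel 8-bit
  grayscale TIFF (`<stem>_ntr.tif` / `<stem>_vis.tif`), emission series
  two-column CSV with a one-line metadata header, configs flat YAML, and
  reports JSON. `run_pipeline()` is driven entirely from R — the
  exported stage functions plus a persisted config already give
  script-level reproducibility, so no shell wrapper is shipped; the
  pipeline accepts externally measured intensity CSVs so the identical
  code path runs on real cohort tables.

# Problem sizes

The test suite runs the full pipeline on the default 35-specimen cohort
and 192–256 px images with 4–6 blobs, exhaustively enumerates all 65,536
8-bit intensity pairs for the triage rule, checks Lloyd's algorithm on
100 random instances plus an exhaustive two-cluster oracle at n = 8–10,
and fuzzes the evaluation identities on 1,000 random cohorts — sizes
chosen so the whole suite completes in well under a minute while still
covering every contract.

# Limitations

- The k = 1 centroid reading of the threshold, the ≥ tie convention,
  and the blank-SD interpretation of σ are documented choices where the
  underlying procedure is ambiguous; alternatives are reachable through
  the exported parameters (`k`, user-supplied σ, fixed thresholds).
- Thresholds transfer neither across instruments nor across cancer
  types; derive them per setting.
- Specificity/NPV on synthetic cohorts characterize the pipeline, not
  the probe. The package ships no patient data.
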