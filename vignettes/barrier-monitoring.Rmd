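---
title: "Methods: epithelial impedance fitting and stripping-voltammetry quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epithelial impedance fitting and stripping-voltammetry quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episens)
```

## The barrier model

A polarized epithelial monolayer on a permeable support is modelled as a
medium resistance in series with two parallel RC elements, one for each
membrane face of the cell layer:

$$Z(\omega) = R_{media} + \frac{R_1}{1 + j\omega R_1 C_1}
                        + \frac{R_2}{1 + j\omega R_2 C_2}$$

with resistances in Ω·cm², capacitances in µF/cm² and $\omega = 2\pi f$.
The two barrier readouts are the transepithelial electrical resistance,
$TEER = R_1 + R_2$, and the cell-layer capacitance, the series
combination $1/C_{cell} = 1/C_1 + 1/C_2$. Both are invariant under
relabelling the two RC elements, which is important because the model
itself is label-symmetric: `circuit_params()` therefore enforces a
canonical order in which element 1 carries the smaller time constant
$\tau = RC$.

The model uses the capacitive sign convention, $\mathrm{Im}\,Z \le 0$,
and Nyquist exports plot $-\mathrm{Im}\,Z$ against $\mathrm{Re}\,Z$, the
standard presentation in which each RC element traces a semicircle.

Assumptions worth stating: ideal capacitors (no constant-phase
elements), no Warburg diffusion branch, and exactly the two-element
topology. Real spectra from rougher electrodes often need CPEs; this
package deliberately does not model them (see Limitations).

## CNLS fitting

`fit_circuit()` minimizes the weighted sum over frequencies of
$|Z_{obs} - Z_{model}|^2$, with real and imaginary parts entering as
separate residuals (complex nonlinear least squares). Design choices:

* **Weighting** (`weighting`): default `modulus` — each residual is
  divided by $|Z_{obs}|$. An epithelial spectrum spans well over a
  decade of magnitude between 10 Hz and 100 kHz; unweighted residuals
  would let the low-frequency points dominate. `unit` and
  `proportional` (per-component scaling) are available for comparison.
* **Positivity** is structural: the optimizer works on
  $\log$-transformed parameters, so no bound constraints are needed and
  relative steps are natural across the decades spanned by R and C.
* **Optimizer**: Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`), relative tolerance `1e-10`, at most 1000
  iterations.
* **Termination on degenerate manifolds.** When the two time constants
  are (nearly) equal, the individual $R_1/R_2$ split is unidentifiable:
  the objective has a flat valley along which a noise-free fit keeps
  improving geometrically without ever satisfying a relative-reduction
  test. A run that hits the iteration cap with a weighted residual
  below $10^{-5}$ of the data norm (relative RMS, i.e. two orders below
  any plausible instrument noise) is treated as converged; anything
  else raises a typed non-convergence error carrying the best-so-far
  parameters.
* **Identifiability flag**: a fitted time-constant ratio below 3 sets
  `identifiable_split = FALSE`. In that regime only TEER and $C_{cell}$
  should be reported — and both remain well determined: at
  $\tau_1 = \tau_2 = \tau$ the model collapses to a single arc with
  $TEER = R_1 + R_2$ and $C_{cell} = \tau / TEER$.
* **Standard errors** come from the Jacobian at the optimum (linearized
  covariance, delta method back from the log scale). They describe the
  single-spectrum fit; scatter across replicate inserts is a separate
  aggregation (`aggregate_replicates()`, sample SD with $n-1$).

Starting values (`initial_guess()`) read the spectrum's shape:
$R_{media}$ from $|Z|$ at the top of the band, $R_1 + R_2$ from the
low-frequency plateau (split 50/50), and the capacitances from the
$-\mathrm{Im}\,Z$ apex via $\omega RC = 1$, with the two time constants
placed $0.3\times$ and $3\times$ around the apex so the optimizer starts
with distinct elements. Spectra too short to support the heuristic fall
back to fixed physiological defaults with a warning.

## Peak extraction

Stripping voltammograms are reduced to one number, the
baseline-corrected oxidation peak height. The baseline is a straight
line fitted to the outer 15 % of points at each end of the scan
(`flank_fraction`), where no stripping peak is expected — the simplest
model consistent with single-peak traces; the source instrumentation's
own baseline handling is not documented, so this is a declared
convention. `find_peak()` then takes the maximum corrected current in a
search window (defaults: Cu 0.0–0.2 V, Zn −0.55 to −0.35 V, around the
observed oxidation potentials) and requires it to exceed a prominence
threshold of 3× the robust flank-noise estimate (scaled MAD of the
flank residuals), so a blank trace reports `found = FALSE` rather than
a spurious peak.

Consequences tested as properties: the height estimate is invariant
under adding any straight line to the trace, linear in the peak
amplitude, and the peak potential is located to within one scan step.

## Calibration and detection limit

`fit_calibration()` is ordinary least squares of the mean replicate
peak current on $\log_{10}$ of molar concentration (the axes
convention of the published calibration plots; natural log was
rejected). Replicates are averaged before regression; their scatter
feeds the per-point relative standard deviation, reported as the
maximum over points. The detection limit is the literal
$3\sigma_{blank}/m$. Note the unit subtlety: with the slope in A per
decade the ratio is formally in decades; the field quotes the number on
the mol/L scale, and `lod()` returns the literal value and leaves the
interpretation to the caller rather than asserting a unit it cannot
justify.

Inverting the curve (`predict_concentration()`) flags estimates outside
the calibrated range (default panel $10^{-11}$–$10^{-6}$ M) as
extrapolation instead of refusing them.

## Transport readouts

`extract_transport()` maps peak extraction over the per-timepoint
apical and basolateral traces of a Transwell experiment; undetected
peaks enter as 0. The apical side is summarized as the percent decrease
from the pre-treatment value T0,
$100\,(i_0 - i_t)/i_0$ — scale-invariant by construction. The
basolateral side starts below detection in an intact barrier, so a
fold-change against T0 is undefined there; the report instead records
the timepoint at which a basolateral peak first appeared, and defines
fold-changes only when the T0 basolateral signal itself exceeds the
detection floor. A series with strictly decreasing apical and strictly
increasing basolateral signal is flagged "consistent with barrier
disruption". No permeability coefficient is computed: that would
require a mechanistic flux model the underlying experiment does not
constrain.

## What the synthetic generator emulates — and what it does not

The generators exist so the whole chain runs without instruments, with
the statistical structure the analysis assumes:

* `gen_spectrum()` evaluates the circuit model and perturbs Re and Im
  independently (default 2 % proportional Gaussian noise — consistent
  with the order of replicate scatter in this kind of measurement).
  The barrier presets are chosen so that the derived metrics equal the
  reported barrier states — pre: TEER 746 Ω·cm², post: 288 Ω·cm², both
  with $C_{cell}$ = 1.8 µF/cm² — while separating the two time
  constants by ≈3× so both elements are resolvable. The individual
  R1/R2 split is *not* constrained by those metrics; the preset split
  is synthetic.
* `gen_voltammogram()` is a phenomenological trace: Gaussian peak
  (σ default 30 mV) on a linear baseline on the protocol's potential
  grid. No deposition, diffusion or ionophore-binding physics; the
  peak height is the only carrier of information.
* `gen_calibration_set()` places peak heights on the published
  log-linear lines (Cu: $1.64\times10^{-7}x + 1.97\times10^{-6}$,
  Zn: $5.36\times10^{-7}x + 6.07\times10^{-6}$; defaults 3 replicates,
  matching "replicate measurements of unstated count" with the
  smallest conventional choice).
* `gen_egta_experiment()` encodes the observed apical time-course
  (Cu fractions 1/0.60/0.30 at 0/1/2 h, i.e. 40 % and 70 % decreases;
  Zn 1/0.55/0.46, i.e. 45 % and 54 %). The basolateral side was
  reported only qualitatively, so the presets mirror the apical losses
  (mass-conserving transfer: Cu 0/0.40/0.70, Zn 0/0.45/0.54) — a
  modelling choice, not a published value.

Every generator is a pure function of its arguments plus an optional
seed (bit-identical reruns; the session RNG stream is untouched when a
seed is given).

Because the generator and the analysis share the forward model, passing
tests demonstrate *correct inference under the stated model and noise*,
not robustness to everything real electrodes do: drift, CPE behaviour,
overlapping peaks, matrix effects and electrode fouling are all outside
the generated data, and results on real spectra/traces will be
correspondingly less clean.

## Problem sizes and numerical conventions

Simulation-based checks use 50-point log-spaced spectra (10 Hz–100 kHz),
100-seed noise ensembles and 200 random circuits for recovery
properties — sizes at which every check completes in seconds while the
Monte-Carlo medians are stable. Random circuit draws are log-uniform
over a physiological barrier range ($R_{media}$ 5–50,
$R_{1,2}$ 100–1000 Ω·cm², $C_{1,2}$ 1–10 µF/cm²), which keeps both
corner frequencies inside the measured band. Degenerate inputs are
rejected with typed errors (`episens_invalid_input`,
`episens_parse_error`, `episens_convergence_error`), which the CLI maps
to exit codes 2/2/3.

## Known limitations

* Exactly the two-RC topology: no CPEs, no Warburg element, no
  Kramers–Kronig validity testing, no multi-spectrum global fits.
* Single-peak voltammetry: no deconvolution of overlapping oxidation
  peaks, no stripping-kinetics simulation.
* The R1/R2 (apical/basolateral) attribution is a labelling convention
  on synthetic data; measured spectra identify the pair only up to the
  swap, and only TEER and $C_{cell}$ should be interpreted when the
  time constants are close.
* The LOD's decade-vs-molar unit ambiguity is inherent to the
  $3\sigma/m$ formula with a log-linear calibration; the package
  reports the literal value.
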