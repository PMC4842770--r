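---
title: "cortimap: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortimap: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortimap)
```

# What the package computes

`cortimap` is a headless, scriptable toolkit for intracranial EEG (iEEG /
ECoG) brain function mapping. Its workflow mirrors clinical practice before
epilepsy surgery: a cortical surface mesh is loaded, implanted electrode
contacts are registered onto it, per-channel functional parameters (e.g.
ERP voltages) are interpolated into surface maps, and functional
connectivity matrices (e.g. phase synchronization) are thresholded into
ball-and-stick networks. Everything renders deterministically to raster
images with no display attached, so the whole chain can run in batch.

This vignette records the models behind each step, the tunable parameters
with their defaults and units, and the decisions taken where a design was
genuinely open. Nothing stated here goes beyond what the package's test
suite and `scripts/acceptance.R` actually compute.

# Electrode registration by ray casting

## Camera model

The viewer is a perspective pinhole camera: position, focal point, view-up
vector, a vertical field of view `view_angle` (degrees), and a roll about
the view axis. A viewport click at continuous pixel coordinates $(p_x,
p_y)$ (origin at the top-left corner) maps to the ray

$$ d \;\propto\; f + \tan(\theta_v/2)\,\bigl(x_s\,r + y_s\,u\bigr),
\qquad x_s = \frac{p_x - w/2}{h/2},\quad y_s = \frac{h/2 - p_y}{h/2}, $$

with $(r, u, f)$ the right/up/forward camera basis. Two consequences are
used as test anchors: the viewport center maps exactly onto the view axis,
and the top-center pixel is elevated by exactly half the view angle.
Because $x_s, y_s$ only depend on pixel coordinates *relative* to the
viewport size, scaling viewport and click coordinates together leaves the
ray unchanged (resolution covariance). An orthographic mode is not
provided; the pinhole model matches what interactive mesh viewers do by
default.

## Surface intersection

A ray is intersected with every triangle (vectorized Möller–Trumbore) and
the hit with the smallest positive ray parameter wins; exact parameter ties
(a ray grazing a shared edge) resolve to the lowest face index, making
placement deterministic. The test suite checks 100 random rays against an
independent per-triangle plane-intersection-plus-barycentric oracle at
1e-6 mm.

## Electrode list editing

Contacts form an ordered list whose index is the list position, so indices
are contiguous `1..k` after any edit. `place_electrode()` supports
insert-after-j semantics (0 prepends), `remove_electrode()` closes ranks,
and `tune_electrode()` displaces a contact by integer multiples of a step
(default 0.1 mm — sub-millimetre tuning). Tuning deliberately does **not**
re-project onto the surface: post-implantation brain deformation sometimes
requires placing a contact off the reconstructed mesh. The default ball
style is a red sphere of radius 2 mm; the numbers are our choice, as only
the existence of the style controls is documented behaviour.

# Surface mapping

Both interpolants are normalized weighted means over the $k$ contacts, with
3D Euclidean distance $d_i$ from vertex to contact:

* **Gaussian** (`gaussian_map()`): $w_i = \exp(-d_i^2 / 2\sigma^2)$ with
  the "extent" $\sigma$ in mm (default 10). Weights are computed relative
  to the nearest contact, so small $\sigma$ cannot underflow; the map tends
  to a nearest-electrode (Voronoi) partition as $\sigma \to 0$ and to the
  global mean as $\sigma \to \infty$ (both checked numerically at
  $\sigma = 0.01$ and $10^5$ mm).
* **Linear** (`linear_map()`): $w_i = \max(0, 1 - d_i/R)$ with support
  radius $R$ in mm (default 15, about 1.5 times a typical 10 mm contact
  pitch). Vertices outside every contact's support are marked uncovered
  and excluded from range computation.

Because the weights are normalized, both maps are convex combinations:
covered vertices can never exceed the electrode-value range, and the field
is invariant to electrode ordering. Euclidean (not geodesic) distance is
used; that matches what typical renderers do and keeps the operation a
dense matrix product, but it will bleed activity across sulci on folded
anatomical meshes — a known limitation, since the bundled synthetic surface
has no folds.

Display ranges are either automatic (min/max of the plotted row, with a
degenerate constant range widened by ±1e-9) or manual with clamping.
The default color transition is a blue–white–red diverging map so red marks
high activity.

# Connectivity networks

`auto_threshold()` implements proportional thresholding: given a target
sparsity $s$ (default 0.1, configurable — no canonical value exists), the
threshold is the $\lceil s P\rceil$-th largest off-diagonal value
($P = n(n-1)/2$) minus a relative $10^{-12}$ nudge, so the strict rule
`C[i,j] > tau` used everywhere keeps exactly that many edges on tie-free
matrices (verified over 100 random matrices). Ties at the cutoff are all
kept and reported. The strict inequality also gives the documented
behaviours at the extremes: a threshold at or above the matrix maximum
(e.g. 1 for PLV) hides all connections, and $-\infty$ yields the complete
graph. Signed matrices threshold on signed values by default with an
`use_abs` option. Node strength is the summed weight of incident surviving
edges; node replotting colors balls by the strength of the *displayed*
network, which we judged the more faithful reading of "connection with
other nodes" (a flag can switch the matrix instead by recomputing with
another threshold). Asymmetry up to 1e-6 is tolerated; beyond that the
matrix is symmetrized as $(C + C^\top)/2$ with a warning, an idempotent
operation.

# The signal pipeline

Defaults follow the clinical parameterization end-to-end and are all
overridable: broad-band filter 0.5–250 Hz, epoch window −800 to +3500 ms
(4300 ms), six analysis bands (delta 1–4, theta 4–8, alpha 8–16, beta
16–30, low gamma 30–80, high gamma 80–250 Hz; the beta band is interpreted
in Hz), display threshold 0.6.

* **Filtering** — 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), the standard zero-phase practice. Ends are padded
  by odd reflection before filtering, which keeps the effective impulse
  response symmetric to ~1e-7 and passband sinusoids within 1% amplitude.
* **Epoching** — half-open sample windows
  $[t_0 + \mathrm{pre}, t_0 + \mathrm{post})$, so the duration is exactly
  `post - pre` ms and the count exactly `(post - pre) fs / 1000` samples.
  Events without room for a full window are skipped with a warning.
* **Rejection** — "apparent noise" is inherently a judgment call; the
  deterministic surrogate drops an epoch when any channel's peak-to-peak
  amplitude exceeds `amp_thresh_sd` times that channel's robust SD
  (MAD × 1.4826, pooled over all epochs). The default 6 suits smooth,
  oscillation-dominated signals. For *broadband* data the expected
  peak-to-peak of a clean epoch is itself several robust SDs (about
  $2\sqrt{2\ln N}$ for $N$ Gaussian samples, i.e. ~8 SD at
  $N \approx 2500$), so the threshold must be calibrated to the signal
  character; the synthetic case study uses 15, which cleanly separates its
  injected 25-SD artifacts from clean broadband epochs.
* **ERP** — pointwise mean over trials; the residual noise follows the
  $1/\sqrt{n}$ law (tested at n = 100 within 30%).
* **PLV** — per channel: band-pass (zero-phase), analytic signal via the
  one-sided FFT construction, instantaneous phase. The first and last 10%
  of each segment are discarded against filter/Hilbert edge effects. For
  pair $(i,j)$, $\mathrm{PLV} = |\langle e^{i(\varphi_i - \varphi_j)}
  \rangle|$. Phases from multiple trials are trimmed per trial and then
  concatenated before averaging (a `per_trial` mode averages per-trial PLVs
  instead; concatenation was chosen as the default because it weights all
  clean samples equally). The estimator is symmetric, bounded in [0, 1],
  and invariant to amplitude scaling and common phase offsets. "Phase
  synchronization" is not a single formula; PLV was chosen as the standard
  estimator that is bounded in [0, 1] and compatible with a 0.6 display
  threshold.

# Synthetic data: what it emulates and what it does not

* `make_brain_mesh()` — an icosphere ($10 \cdot 4^s + 2$ vertices) scaled
  to 140 × 170 × 120 mm. It is closed and star-shaped but has **no
  cortical folding**; passing tests therefore validate geometry and
  estimator code, not anatomical fidelity of Euclidean interpolation.
* `make_case_study_montage()` — four 16-contact strips (10 mm pitch)
  stepped along the left-lateral surface at descending heights, numbered
  1–64 in strip order, emulating a frontal-to-temporal coverage. Strip
  stepping solves the step length so consecutive chord distances equal the
  pitch to 1e-3 mm.
* `make_coupled_pair()` — the PLV validation fixture. The two channels are
  sinusoids whose phase difference is a stationary process with an
  *exactly* von Mises(0, κ) marginal, giving the closed-form population
  PLV $I_1(\kappa)/I_0(\kappa)$. The process is built by mapping a
  low-pass (8 Hz) Gaussian copula process through the von Mises quantile
  function. The narrow modulation bandwidth matters: drawing the phase
  difference independently per sample makes the signal broadband, and the
  one-sided spectral projection inside the analytic signal then distorts
  the recovered phase distribution by up to ±0.02 — the copula construction
  keeps the estimator's error below 0.01 across κ ∈ {0.5, 1, 2, 4} at
  $10^5$ samples. The wrapped-normal approximation replaces numeric
  quantile inversion for κ > 50.
* `make_erp_dataset()` — a damped 8 Hz template starting 200 ms
  post-stimulus, per-channel gains in [0.5, 1.5], white noise at the
  requested SNR, jittered inter-trial intervals long enough that every
  −800/+3500 ms window fits without overlap. Options add within-group
  shared narrowband sources (phase-locked clusters for connectivity tests)
  and injected high-amplitude artifact trials (for rejection tests). The
  default rate of 600 Hz is the smallest round rate that leaves the
  80–250 Hz band below Nyquist with margin; real clinical recordings are
  often sampled faster and decimation does not change any estimator here.

All generators are deterministic under a seed; the seed changes only the
noise realization, never the structure.

# Rendering

Rendering is a pure-R software rasterizer: perspective projection through
the same camera model as `cast_ray()` (so a rendered electrode appears
exactly where its registering click was), z-buffered triangle fill with
screen-space barycentric interpolation, Lambertian headlight shading,
spheres (UV tessellation, 16 segments) for electrode balls and 16-gon
cylinders for sticks. Opacity below 1 switches the mesh to a back-to-front
alpha-blend pass over the opaque z-buffer, which is what lets interior
(depth) electrodes show through a translucent brain. Colorbar, electrode
labels (5×7 bitmap font) and axes are 2D overlays. There is no GPU, no
anti-aliasing and no global illumination — the design goal is
*determinism*: identical scenes produce byte-identical buffers, which the
tests and the batch exporter rely on. `export_images()` writes one image
per parameter row as `prefix_NNN.png` (or 24-bit uncompressed BMP).

# Mesh decimation

"Surface fineness" is controlled by greedy quadric-error edge collapse:
per-vertex quadrics accumulated from incident face planes, candidate
positions (midpoint/endpoints) scored by quadric cost, a two-common-
neighbour link condition and a normal-flip guard protect manifoldness.
The collapse order is deterministic and independent of the target, so face
counts are monotone in the requested fraction and a 0.5 request on a
closed mesh lands within ±5% of the target. Decimated vertices stay within
2% of the bounding-box diagonal of the original surface (checked with an
exact point-to-triangle oracle). Both a fraction and an absolute face
target are accepted, since slider-style controls map to either.

# File formats

Five formats cover the tool's state; all but the mesh container are ASCII,
tab-separated, locale-independent, and canonically formatted so that
write–read–write roundtrips are byte-identical:

| format | content |
|---|---|
| `.mof` | binary mesh: 8-byte magic, uint32 V/F, float32 vertices, uint32 0-based faces, little-endian |
| `.epf` | electrode positions: `index label x y z r g b radius` per line, one comment header |
| `.cpf` | camera: position, focal point, view-up, view angle, distance, roll |
| `.txt` (params) | m × n functional parameters, rows = time stages |
| `.txt` (matrix) | n × n correlation measure, entry (i,j) = channels i↔j |

The `.epf` file is the source of truth: hand-edited coordinates are
honored on re-read. The `.cpf` reader validates that the stored distance
matches ‖position − focal‖ (1e-3 mm) and normalizes the roll to [0, 360).
The original tools' on-disk layouts are unpublished, so these dialects are
documented but make no byte-compatibility claim; OFF and ASCII PLY are
supported for interchange (no GIfTI reader is available to R here, so
GIfTI users should convert via OFF/PLY). Faces are 1-based inside R and
0-based on disk.

# Problem sizes used by the test and acceptance runs

The suites run on a deliberately desk-scale configuration: icospheres at
subdivision 2–3 (320–1280 faces), 64-channel montages, 12–20 trials at
600 Hz for the end-to-end study, $10^5$ samples for the PLV closed-form
recovery, 100 random rays/matrices for the oracle and sparsity checks, and
256×192 to 320×240 renders. These sizes were chosen so the whole
verification chain stays in the minutes range on one CPU while every
estimator still operates far from its small-sample regime.

# Known limitations

* Euclidean interpolation distances (no geodesics) — see above.
* The rejection rule is an amplitude criterion only; it will not catch
  line noise or flat channels.
* The renderer does not anti-alias and draws labels as fixed-size bitmap
  glyphs.
* MRI surface extraction, CT/MRI co-registration and vendor EEG formats
  are out of scope by design; meshes arrive via OFF/PLY/`.mof`, signals
  via tab-separated tables, coordinates via `import_coordinates()`.
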