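# cortimap

Headless brain function mapping for intracranial EEG.

Before epilepsy surgery, subdural and depth electrodes (ECoG/sEEG) are
implanted to localize epileptogenic zones and eloquent cortex. Turning those
recordings into something a clinical team can look at requires three steps
that `cortimap` makes scriptable, with no GUI or display attached:

1. **Electrode registration** — assigning each implanted contact a 3D
   coordinate on the reconstructed cortical surface. `cortimap` implements
   the classic interactive route (a viewport click becomes a camera ray,
   intersected with the triangle mesh — "ray casting") as a batch API, plus
   list editing (insert-after, sub-millimetre tuning, removal) and import of
   coordinates localized by other means through a 4×4 affine.
2. **Function mapping** — interpolating per-channel functional parameters
   (ERP voltage, entropy, whatever a table holds) onto the surface as a
   colored map. Two normalized-kernel interpolants are provided: Gaussian,
   `w_i = exp(-d_i² / 2σ²)` with σ the "extent" in mm, and linear,
   `w_i = max(0, 1 − d_i/R)` with coverage tracking. Both are convex
   combinations of the channel values.
3. **Connectivity visualization** — thresholding an n×n correlation or
   phase-synchronization matrix into a ball-and-stick network, either at a
   manual threshold (edges with `C[i,j] > τ`) or automatically at a target
   sparsity (the `⌈s·P⌉` strongest of the `P = n(n−1)/2` possible
   connections), with per-node summed connection strength for hub
   highlighting.

Around that core, the package ships the supporting pipeline of a clinical
ERP study — zero-phase Butterworth band-pass (0.5–250 Hz), stimulus-locked
epoching (−800 to +3500 ms), amplitude-based epoch rejection, trial
averaging, and phase-locking-value (PLV) connectivity
`PLV = |⟨exp i(φ_i − φ_j)⟩|` in the six canonical bands (delta 1–4 Hz
through high gamma 80–250 Hz) — five file formats (binary mesh `.mof`,
tab-separated `.epf`/`.cpf`/parameter/matrix tables), a deterministic
software renderer (PNG/BMP, byte-identical re-renders), and synthetic-data
generators so every stage is testable offline.

## Worked example

```r
library(cortimap)

# a brain-like closed surface and the four-strip, 64-contact montage
mesh <- make_brain_mesh(3)
mesh
#> tri_mesh: 642 vertices, 1280 faces
#>   extent (mm): x [-70.0, 70.0]  y [-85.0, 85.0]  z [-60.0, 60.0]
montage <- make_case_study_montage(mesh)
montage
#> electrode_set: 64 contact(s), space native

# a signal pair with known phase coupling: the PLV estimator recovers the
# von Mises closed form I1(kappa)/I0(kappa)
rec <- make_coupled_pair(kappa = 2, seed = 1)
M <- plv_matrix(rec, band = "low_gamma")
sprintf("PLV = %.3f; closed form I1(2)/I0(2) = %.3f",
        M[1, 2], besselI(2, 1) / besselI(2, 0))
#> "PLV = 0.704; closed form I1(2)/I0(2) = 0.698"

# the ERP pipeline on a synthetic 64-channel task recording
erp_rec <- make_erp_dataset(n_trials = 20, n_channels = 64, fs = 600,
                            snr = 1, seed = 1,
                            coupled_groups = list(1:16, 17:32, 33:48, 49:64),
                            artifact_trials = 2)
filt <- bandpass_zero_phase(erp_rec, 0.5, 250)
ep <- reject_epochs(segment_epochs(filt, -800, 3500), 15)
ep   # the two injected artifact trials are gone
#> epoch_set: 18 trial(s) x 64 channel(s) x 2580 samples,
#>            window [-800, 3500] ms at 600 Hz

# theta-band network at the 0.6 display threshold: exactly the
# within-strip pairs survive (4 strips x choose(16, 2) = 480 edges)
theta <- plv_matrix(ep, band = "theta")
es <- threshold_edges(theta, 0.6)
es
#> edge_set: 480 edge(s) over 64 node(s), threshold 0.6, weighted
s <- node_strength(es)
sprintf("strongest hub: channel %d (strength %.2f)", which.max(s), max(s))
#> "strongest hub: channel 17 (strength 14.03)"

# render a surface map of the ERP at +500 ms and export one image per row
erp <- average_erp(ep)
row <- erp[, round((500 + 800) * 600 / 1000) + 1]
field <- gaussian_map(mesh, montage, row, extend_sigma_mm = 10)
scene <- scene_spec(mesh = mesh, electrodes = montage, field = field)
img <- render_scene(scene, 640, 480)   # deterministic pixel buffer
write_image(img, "erp_500ms.png")
```

`demo_case_study("out/")` chains all of the above — mesh, montage,
simulated task, filtering, epoching, rejection, ERP maps for a series of
time points, and six band-wise PLV networks at the 0.6 threshold — and
writes every intermediate file plus the rendered images.

## Command line

A thin Rscript wrapper exposes the same operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cortimap", package = "cortimap"))')
$CLI convert  --in brain.off --out brain.mof --decimate 0.5
$CLI register --mesh brain.mof --camera view.cpf --pixels clicks.tsv --out montage.epf
$CLI map      --mesh brain.mof --epf montage.epf --params erp.txt --row 3 --out map.png
$CLI network  --epf montage.epf --matrix plv_theta.txt --thr 0.6 --out net.png
$CLI fixtures --demo case-study --out demo/
```

## Scope

The package deliberately does not reconstruct brain surfaces from MRI,
co-register CT/X-ray images, read vendor EEG formats, or compute graph
metrics beyond node strength — meshes arrive as OFF/PLY/`.mof`, signals and
externally computed measures as tab-separated tables. See
`vignettes/cortimap-methods.Rmd` for the models, parameter defaults and
design decisions.
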