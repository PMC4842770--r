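Package: cortimap
Title: Cortical Electrode Registration and iEEG Function Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless toolkit for intracranial EEG (iEEG/ECoG) brain function
    mapping: electrode registration on triangle-mesh cortical surfaces by
    camera ray casting, surface mapping of per-electrode functional parameters
    by Gaussian or linear interpolation, correlation-network thresholding and
    ball-and-stick visualization with node-strength scoring, compact file
    formats for meshes, electrode montages, camera views, parameter tables and
    correlation matrices, and an ERP plus phase-locking-value signal pipeline
    (zero-phase band-pass filtering, epoching, artifact rejection, trial
    averaging, band-wise phase synchronization). Includes a deterministic
    software renderer for image export and synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    png,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
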