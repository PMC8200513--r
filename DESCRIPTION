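Package: gimbaltrack
Title: Beam Geometry and 4D Dose Accumulation for Gimballed Dynamic Tumour Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the pan/tilt beam motion of a gimbal-mounted linear
    accelerator during dynamic tumour tracking. Recomputes treatment-beam
    geometry (gantry, ring and collimator angles and per-beam isocenters) on
    other respiratory phases from implanted fiducial-marker displacements (the
    rotation method), alongside the simpler whole-plan translation baseline.
    Segments respiratory traces into breathing cycles to derive exhale/inhale
    time-fraction weights, warps per-phase dose grids onto a reference anatomy
    through supplied deformation vector fields, accumulates weighted multi-phase
    dose, and evaluates organ-at-risk constraints with near-maximum
    dose-volume-histogram metrics (D0.03cc). Ships a synthetic module
    (cylindrical phantom, quasi-periodic breathing traces, ten-phase fiducial
    trajectories with rigid deformation fields, and a toy divergent-beam dose
    engine) so the whole pipeline runs end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
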