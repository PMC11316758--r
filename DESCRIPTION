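Package: beamtile
Title: Supertile Montage Planning, Throughput Modelling and Simulation for
    Beam-Deflection TEM
Version: 0.1.0
Authors@R: person("Imaging", "Tools", email = "imaging@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and analysing beam-deflection transmission
    electron microscopy (bdTEM) acquisitions. A beam-deflection TEM scans the
    illumination to several adjacent sample positions per mechanical stage
    move and de-scans each image back to the camera, acquiring a "supertile"
    of overlapping subtiles at every stage position. The package provides the
    tiling arithmetic for supertiles and section-scale montages (pitches,
    extents, spiral deflection order, stage grids, beam-boundary capacity), an
    imaging-rate accounting model (burst, montage, net and effective rates,
    duty cycle, sections per day, volume projections), a synthetic specimen
    and acquisition simulator with known ground truth (deflection-dependent
    distortion, dose-scaled shot and read noise, circular beam boundary),
    image-quality metrics (radially averaged power spectra, spectral
    signal-to-noise ratio, FFT focus score, normalized cross-correlation block
    matching), and a translation-based stitcher to close the loop on simulated
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
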