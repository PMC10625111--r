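Package: photomem
Title: Mechanics and Electrostatics of Photoswitchable Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for quantifying light-triggered changes in lipid
    membranes containing azobenzene photolipids, built around giant unilamellar
    vesicle (GUV) experiments. Implements flicker (fluctuation) spectroscopy of
    quasi-spherical vesicle contours with a Legendre-sum Helfrich mode spectrum
    to estimate bending rigidity and tension; vesicle electrodeformation
    analysis (prolate spheroid area, photo-induced relative area change,
    exponential photoswitching kinetics, reversibility statistics); specific
    membrane capacitance from the prolate-oblate critical frequency, with
    electrolyte double-layer correction and membrane dielectric constant;
    AFM height-map flattening with iterative line-wise background rejection
    and histogram-based bilayer thickness extraction; and membrane elasticity
    bookkeeping (stretching modulus, interleaflet coupling, volume-conservation
    thickness changes). Every estimator ships with a seeded synthetic-data
    generator reproducing the statistical structure it assumes, so the whole
    pipeline is validated by parameter recovery on data with known ground
    truth. Includes subpixel vesicle contour detection from phase-contrast
    style images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
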