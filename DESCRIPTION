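Package: vedbacal
Title: Calibrating Accelerometry-Derived Energy Expenditure Against Doubly
    Labelled Water in Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for estimating field energy expenditure of free-ranging
    seabirds from tri-axial accelerometry, calibrated against the doubly
    labelled water (DLW) method. Separates static and dynamic acceleration and
    computes vectorial dynamic body acceleration (VeDBA); classifies
    behaviour at 1-s resolution from Morlet continuous-wavelet spectra with
    k-means clustering, GPS speed/location rule corrections and dive-type
    assignment; filters GPS tracks, segments central-place foraging trips and
    apportions time into day and night; converts two-isotope enrichments into
    CO2 production and energy expenditure via the single-pool model;
    estimates activity-specific energy coefficients and at-sea energy by two
    subtraction methods; and fits and selects calibration regressions. A
    synthetic-deployment generator with known ground truth makes every stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
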