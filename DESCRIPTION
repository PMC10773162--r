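Package: lumenflow
Title: Hemodynamic Analysis of True/False Lumen Flow in Aortic Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantitative hemodynamic analysis of type B aortic
    dissection from time-resolved (4D-flow style) velocity fields and
    lumped-parameter modelling. Provides power-law non-Newtonian blood
    rheology, plane flow rates, true/false lumen flow distribution, the
    reverse flow index, peak velocities, wall shear rate and time-averaged
    wall shear stress, three-element Windkessel outlet calibration, a 0D
    (lumped-parameter) multi-tear dissection network simulator for
    tear-configuration experiments, CT-style lumen morphometry, and a
    synthetic-data generator emulating 4D-flow acquisitions of a two-lumen
    dissection phantom so the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
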