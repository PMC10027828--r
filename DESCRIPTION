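Package: aneuflow
Title: Pulsatile Non-Newtonian Hemodynamics in an Idealized Coiled Aneurysm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates unsteady laminar blood flow in an idealized
    two-dimensional parent vessel with a side-wall saccular aneurysm, with
    and without endovascular coiling.  Blood rheology follows a regularized
    Casson law with hematocrit-dependent coefficients; a coil pack in the
    sac is represented as a Darcy porous medium whose porosity and
    permeability derive from the coil wire geometry.  The incompressible
    Navier-Stokes equations are discretized with stabilized linear finite
    elements on triangles and integrated over several cardiac cycles under
    a pulsatile inflow waveform.  Post-processing computes wall shear
    stress, its time average (TAWSS), the oscillatory shear index (OSI) and
    wall-pressure statistics on tagged wall regions, and experiment drivers
    run hematocrit and porosity sweeps and grid-refinement studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
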