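Package: stenoflow
Title: Finite-Volume Simulation of Williamson Blood Flow and Heat Transport
    in Stenosed Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady laminar simulation of shear-thinning (Williamson) blood
    flow and one-way coupled heat transport through healthy and stenosed
    arterial segments with circular or elliptic cross-section. Provides
    parametric lumen geometries, structured staggered grids (axisymmetric
    cylindrical and masked-cell Cartesian 3D), a SIMPLE-type finite-volume
    incompressible Navier-Stokes solver with generalized-Newtonian rheology,
    a temperature solver with viscous dissipation, post-processing of the
    derived quantities commonly plotted in stenosis hemodynamics (pressure
    coefficient, dynamic pressure, cell Reynolds number, Stokes stream
    function, line profiles), parameter sweeps over Reynolds, Prandtl and
    Brinkman groups, and an analytic-oracle verification battery
    (Hagen-Poiseuille, elliptic-duct Poiseuille, one-dimensional
    generalized-Poiseuille quadrature, Couette flow with dissipation,
    grid-independence studies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
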