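Package: nanoconfine
Title: Scaling Model for Water Self-Diffusion Under Nanoscale Confinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the self-diffusion coefficient of water confined by
    solid nanostructures (nanopores, nanoparticles, carbon nanotubes,
    proteins) from geometry and force-field parameters alone. Computes
    per-atom solvent-accessible surface areas (Shrake-Rupley), evaluates
    the effective wall potential (12-6 Lennard-Jones plus a thermally
    averaged Langevin dipole-field term) along surface normals, extracts
    the characteristic confinement length delta, converts it into the
    dimensionless scaling parameter theta with curvature and
    continuum-percolation corrections, and applies the linear scaling law
    D(theta) = D_B [1 + (D_C/D_B - 1) theta]. The fully confined
    diffusivity D_C is obtained from supercooled-water thermodynamics.
    Also provides an Einstein/mean-square-displacement diffusion
    estimator for particle trajectories and a mapper converting label
    images of nanoparticle-loaded mesoporous constructs into maps of
    theta, D and transverse-relaxivity enhancement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
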