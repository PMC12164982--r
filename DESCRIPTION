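Package: piezotraj
Title: Trajectory Analysis of Interblade Handshaking in Trimeric
    Mechanosensitive Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing coarse-grained and atomistic trajectories of
    trimeric mechanosensitive channels such as PIEZO1. Detects and classifies
    transient interblade "handshake" contacts between the short and long
    membrane-parallel helices of neighbouring blades, quantifies blade
    conformation (tip-to-pore distance, blade angle, height, projected area),
    maps protein-lipid contacts, PIP2 pools, 2D lipid densities and bilayer
    height/dome depth, measures pore geometry (Heron triangle areas and
    voxel degree-of-buriedness cavity volumes), and fits electrophysiology
    response curves (Boltzmann pressure-response, Hill dose-response,
    exponential inactivation) with the surface-tension conversion. A
    synthetic-system generator produces trimeric-channel plus lipid
    trajectories with known ground truth so every analysis stage is
    verifiable without molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    bio3d
Config/testthat/edition: 3
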