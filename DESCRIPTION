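Package: metalff
Title: Automated Force-Field Parametrization for Metal Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds Amber-format force-field parameters for metal-containing
    molecules from quantum-chemical input. Bond and angle force constants for
    the metal coordination sphere are derived from the Cartesian Hessian by
    the Seminario sub-Hessian eigendecomposition method; every
    metal-coordinating atom receives a unique atom-type label so that no two
    chemically distinct metal terms share a parameter entry; the remaining
    organic scaffold is parametrized from a transferable database with a
    Seminario fallback; metal Lennard-Jones terms come from an embedded UFF
    table (vdW distance halved); restrained electrostatic-potential charge
    fitting supports per-atom charge constraints, total-charge conservation
    and chemical-equivalence classes. Writes frcmod, Tripos mol2 and PDB
    files, and reads XYZ geometries, Gaussian formatted-checkpoint and ORCA
    Hessians, and plain charge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
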