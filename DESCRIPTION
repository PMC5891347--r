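Package: DomainDynamics
Title: Essential Dynamics and Two-State Conformer Analysis of Multidomain
    C-Alpha Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of two-domain
    proteins at C-alpha resolution: Kabsch superposition, positional
    covariance and principal component analysis with Boltzmann-inversion
    free-energy surfaces, geometric descriptors (interdomain centroid
    distance, salt-bridge center-of-mass distances, helix axes and
    interhelix angles, RMSF/B-factors, coordination-shell radii),
    comparative residue-pair distance-change and
    anticorrelation-difference maps, and histogram/KDE-based
    extended-versus-compact state classification with population
    free-energy differences. Includes a seeded two-state Markov generator
    of synthetic two-domain trajectories with ground-truth basin labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, bio3d, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
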