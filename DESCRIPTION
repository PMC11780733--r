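Package: dnapucker
Title: Sugar Pucker Torsion Refitting and DNA Conformational Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational machinery for refining deoxyribose torsion potentials in
    AMBER-style nucleic-acid force fields and for validating the resulting
    conformational ensembles. Implements Altona-Sundaralingam pseudorotation algebra
    and constrained pucker-scan construction, AMBER frcmod dihedral parameter I/O,
    composite CBS/CCSD(T) reference-energy assembly, solvation-aware linear
    least-squares Fourier refitting, trajectory conformer statistics (percent north
    pucker, pseudorotation potentials of mean force with block-averaged confidence
    intervals, BI/BII and alpha/gamma backbone substate populations), CEHS base-pair
    step and helical parameter algebra with El Hassan-Calladine groove widths,
    flat-well restraint bookkeeping, and synthetic fixture generators (two-state
    pucker time series, Fourier-planted torsion scans, idealized A- and B-form
    fiber duplexes) with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
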