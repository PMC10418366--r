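Package: chisno
Title: Chi1 Rotamer Overlap Analysis of pH-Induced Active-Site Destabilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of per-residue chi1 side-chain dihedral time
    series from molecular-dynamics simulations to diagnose pH-induced
    rotameric destabilization of enzyme active sites.  Reads GROMACS
    chi-utility xvg files and delimited angle tables, normalizes circular
    angle data by doubling and stacking onto a contiguous 360-degree
    window, computes the integral-of-non-overlapping (S_NO) statistic
    between condition-paired replicate chi1 distributions, selects
    pH-responsive residues by a replicate-reproducibility rule, classifies
    frames into rotamer states and counts sustained violations of the
    native state, assigns discrete protonation-state charge schemes and
    net protein charges, and generates synthetic von Mises/Markov chi1
    trajectories so the whole pipeline is testable without trajectory
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
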