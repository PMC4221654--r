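Package: contactprop
Title: Residue-Residue Contact Propensities and Contact Prediction Re-Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes residue-residue contact sites in protein structures
    using a C-beta distance cutoff and sequence separation definition.
    Computes contact degrees and their power-law dependence on the contact
    parameters, per-class and per-topology amino-acid contact propensities
    (Wc, Wt), unordered pair contact frequencies (fp) and their normalized
    form (fpn), and a topology-versus-class divergence score (St). Assigns
    structural classes (alpha, beta, alpha+beta) from simplified secondary
    structure, re-ranks externally supplied per-pair contact scores (such as
    direct information from direct coupling analysis) against class pair
    frequencies to improve the top-ranked contact set, and evaluates
    predictions with mean true-positive-rate curves. Includes deterministic
    generators for idealized helix, hairpin, and coil structures with known
    contact ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: bio3d, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
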