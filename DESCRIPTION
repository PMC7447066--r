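Package: psitraj
Title: Disulfide and Structural Dynamics Analysis for Saposin-Fold Dimer
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    saposin-fold homodimers such as the potato plant-specific insert (PSI),
    studied as a function of pH and disulfide-bond reduction. Provides the
    condition-code registry for single, double and triple disulfide removal,
    rule-based pH-dependent protonation assignment, cysteine S-gamma
    pair-distance statistics with pooled histograms and disulfide
    reformability/interchange calls, loop-partitioned RMSD, RMSF (optionally
    filtered on the first covariance eigenvector), radius of gyration and
    centre-of-mass separations, a per-residue secondary-structure variation
    index derived from DSSP assignments, and hydrogen-bond, hydrophobic,
    salt-bridge and cation-pi contact censuses partitioned by monomer and by
    the disordered loop. A deterministic synthetic-trajectory generator with
    planted ground truth makes every stage testable without MD output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
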