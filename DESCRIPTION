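Package: hpfold
Title: Ground-State Search for the 2D Hydrophobic-Polar Lattice Protein Model
    by Full-State-Space Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ground-state conformation search in the two-dimensional
    square-lattice hydrophobic-polar (HP) protein model. Implements tabular
    Q-learning over the full tree-structured state space (one state per action
    prefix, indexed by exact geometric-series arithmetic) with rigid
    (overlap-masking) and flexible (overlap-penalty) reward criteria, the
    compressed partial-state variant, a myopic contact-greedy baseline, and an
    exact ground-state oracle based on pruned self-avoiding-walk enumeration.
    Includes a sixteen-sequence benchmark suite, a reproducible experiment
    harness with seeded learning curves and hit statistics, and decoding of the
    converged value table into the pool of distinct minimum-energy
    conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    seqinr,
    jsonlite,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
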