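Package: fibrationRepair
Title: Fibration-Symmetry-Driven Repair of Neuronal Connectomes from
    Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers cluster-synchrony partitions from multi-animal neuronal
    activity traces (Level-of-Synchronicity and correlation-family metrics,
    clique synchronization and Louvain community detection, consensus
    co-occurrence clustering) and minimally "repairs" a directed connectome
    by mixed-integer linear programming so that the observed synchrony
    clusters become fibers of a (minimally) balanced coloring. Includes
    directed-graph fibration machinery (balanced-coloring verification,
    coarsest equitable refinement, input trees, base graphs, bilateral
    collapsing), a synthetic-cohort generator with admissible-ODE dynamics
    on planted fibration-symmetric graphs, permutation significance testing
    of repair costs, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
SystemRequirements: Python (>= 3.8) with scipy >= 1.9 on the PATH
    (scipy.optimize.milp / HiGHS is the MILP solver backend)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
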