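Package: peakwalk
Title: Early Adaptation of Finite Populations on Rugged Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study early adaptation of finite populations evolving on
    rugged fitness landscapes in the weak-mutation (origin-fixation) regime.
    Generates tunably epistatic landscape ensembles (LK/NK, LKp, House of Cards,
    Rough Mount Fuji, Eggbox, Ising) over binary genotypes, simulates Moran and
    Wright-Fisher origin-fixation walks and their adaptive-walk limits, and
    computes by exact first-step analysis the fitness of the first peak a
    population encounters, together with walk lengths and times, stationary
    distributions, peak-accessibility measures (accessible mutational paths,
    greedy basins of attraction) and the classification of how the mean
    first-peak fitness depends on population size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
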