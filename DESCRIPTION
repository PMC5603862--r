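Package: qsarfs
Title: Wrapper Feature Selection for QSAR with Genetic Algorithms and
    Learning Automata
Version: 0.1.0
Authors@R:
    person("QSAR", "Tools", email = "qsarfs@example.org", role = c("aut", "cre"))
Description: Wrapper descriptor selection for quantitative
    structure-activity relationship (QSAR) tables. Provides a plain
    genetic algorithm (GA), an object-migration learning-automata (LA)
    selector, and two hybrids: a sequential GA-then-LA pipeline (SGALA)
    and a mixed variant that applies the automata reward/penalize update
    inside every GA generation (MGALA). Candidate subsets are scored by
    the root-mean-square error of a multiple linear regression refit.
    Includes descriptor preprocessing (constant-column removal, Pearson
    correlation filtering, activity-ranked train/test splitting),
    downstream least-squares support vector regression with an RBF
    kernel, Golbraikh-Tropsha/Roy external validation statistics,
    leverage-based applicability-domain assessment (Williams plot data),
    a synthetic table generator with planted ground truth, and a
    command-line runner for multi-seed experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
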