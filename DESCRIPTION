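Package: boardball
Title: Simulation and Analysis of Dyadic Board-Ball Collaboration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying haptic communication in a collaborative
    ball-and-beam (board-ball) task. Provides a deterministic physics
    simulator of the two-handed board-ball dynamics with selectable
    haptic-feedback sources (full, partner-sourced, environment-sourced,
    unrelated, or none), a synthetic-dyad generator with configurable
    leader-follower asymmetry and known ground truth, zero-phase
    Butterworth filtering and hidden-Markov-model segmentation of hand and
    board velocity profiles, per-trial coordination and leader-follower
    role metrics (movement ratio, onset delay, corrective and unilateral
    manipulation ratios, motion-triggered trajectory averaging), and a
    study pipeline with repeated-measures condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
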