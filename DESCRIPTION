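Package: wormnav
Title: Behavioral and Neural Analysis of C. elegans Olfactory Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying error-correcting reorientation behavior in
    C. elegans odor-gradient navigation and for relating it to neural activity.
    Includes a seeded generative simulator of biased-random-walk navigation
    with ground-truth reorientation events and coupled synthetic calcium
    traces; reversal/turn/pirouette detection from trajectory angular speed;
    shuffle-based null models for directed turning; head-swing phase warping
    and event-triggered averaging of neural activity; behavior-matched
    quintile subsampling; a receptor-expression permutation test; and a
    gated-recurrent-unit decoder of upcoming turn direction with hierarchical
    cross-validation and bootstrap model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
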