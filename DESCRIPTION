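Package: RecruitKinetics
Title: Recruitment Kinetics of DNA-Repair Proteins at Laser-Induced Damage Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the recruitment kinetics of fluorescently tagged
    DNA-repair proteins (such as FUS-eGFP) at UV-laser micro-irradiated DNA
    damage sites in live-cell time-lapse microscopy. Provides readers for
    multi-dimensional TIFF stacks with non-uniform frame schedules, maximum
    intensity projection, translation-only drift registration and
    photobleaching correction, automatic nucleus and damage-stripe
    segmentation with a two-pixel background ring, extraction of
    background-corrected intensity traces, segmentation of each trace into
    lag, association, plateau and dissociation phases, robust non-linear
    fitting of a first-order association/dissociation model, and cohort
    statistics (recruiting and plateaued fractions, one-way ANOVA with Tukey
    post hoc comparisons). A forward simulator with full ground truth makes
    every stage testable on synthetic movies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, Software, TimeCourse
RoxygenNote: 7.3.3
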