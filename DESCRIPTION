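Package: pubscore
Title: Pubertal Ovarian Maturation Scoring and Retrospective Dating of First
    Ovulation in Laboratory Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based staging of peripubertal ovarian maturation in rats and
    mice from coded histological observations. Assigns an integer maturation
    score (the Pub-score) from the most advanced healthy antral follicle class
    in non-ovulating animals, and from corpus luteum dating and regressing-
    generation counting in ovulating ones, then retrodates the age at first
    ovulation. Includes a synthetic-cohort simulator for round-trip validation,
    cohort summaries (means, SDs, Student-t confidence intervals, Pearson R
    squared between vaginal opening and first ovulation), CSV readers/writers
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
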