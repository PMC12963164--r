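Package: drapewatch
Title: Draping Detection and Pre-Incision Interval Analysis for Operating-Room Surveillance Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the start of surgical draping from operating-room
    surveillance footage by localizing the operating bed before patient
    entry, sampling the mean color of the bed region about once per second,
    deriving a cyan-like color score sensitive to blue sterile drapes,
    classifying each sample as before or after draping with a radial-basis
    support vector machine on entry-normalized color features, and
    confirming the event after an uninterrupted run of positive seconds.
    Includes a synthetic operating-room scene generator for end-to-end
    testing without hospital data, an evaluation harness for detection
    timing error, and paired nonparametric statistics (exact Wilcoxon
    signed-rank with Bonferroni adjustment) for the intervals between
    preparatory staff actions and skin incision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
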