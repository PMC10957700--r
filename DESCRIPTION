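Package: ctpcea
Title: Cost-Effectiveness of CT Perfusion Screening for Large Vessel Occlusion Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Markov microsimulation for the health-economic
    evaluation of adding CT perfusion (CTP) to a non-contrast CT plus CT
    angiography imaging protocol for the detection of endovascular-treatment
    eligible large vessel occlusions in acute ischemic stroke. Provides a
    synthetic cohort generator emulating a Dutch EVT-treated registry cohort,
    proportional-odds counterfactual construction of the non-CTP control arm,
    yearly modified Rankin Scale trajectory simulation with recurrence and
    mortality hazard ratios, discounted cost and QALY accounting with
    number-needed-to-image screening costs, net monetary benefit outcomes,
    and one-way, probabilistic, and scenario-grid sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
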