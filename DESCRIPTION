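Package: dyadvr
Title: Dyadic Virtual-Reality Fight Analysis for Paired Zebrafish Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for dyadic social-interaction trials in which two
    agents (head-fixed zebrafish driven through a closed-loop virtual-reality
    arena) leave frame-aligned trajectory logs. Implements per-frame view-field
    classification (left eye, binocular, right eye, blind), attack-posture and
    rising-edge bite detection, approach-episode extraction from the mutual
    distance series, trial-level interaction metrics (near rate, center
    occupancy, shuffle-null attraction, eye-use percentages and the left eye
    index, distance-binned binocular-view profiles), discrete transfer entropy
    on symbolized ethograms, a discrete-event simulator of the shock protocol,
    a rank-test group-comparison harness with a standardized-mean-difference
    effect size, and a synthetic two-agent trajectory generator with
    controllable attraction, directional coupling and lateral eye bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
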