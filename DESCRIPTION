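Package: deerCBA
Title: Cost-Benefit Analysis of Red Deer Management Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stationary sex- and age-structured life-table engine for red
    deer (Cervus elaphus) populations managed by hunting, together with an
    annual net-benefit valuation of alternative harvest strategies. Five
    built-in management strategies (free harvest, trophy hunting, maximum
    harvest and two natural demographic compositions) are resolved to
    per-sex, per-age mortality schedules, propagated to stationary cohort
    tables, collapsed to eight sex/age classes, and valued with meat,
    recreational, browsing-damage and traffic-damage terms. Includes
    grouped one-at-a-time sensitivity bounds, decision rules (including the
    extinction rule), a cull-based population estimator, a vehicle-collision
    probability calculator, and a synthetic-scenario generator for
    property-style testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
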