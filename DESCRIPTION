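Package: actinodiv
Title: Occurrence-Based Diversity Dynamics of Palaeozoic Ray-Finned Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fossil occurrence tables of Palaeozoic
    actinopterygians (and similar clade-level compilations): reading and
    cleaning literature-compiled occurrence data, binning occurrences into
    roughly equal-length composite time intervals built from ICS stages and
    regional substages, computing sampled-in-bin genus and species richness,
    sampling-effort proxies (unique localities, geological units, occupied
    equal-area grid cells), ordinary least-squares regressions of richness
    against sampling proxies, interval length and sea level, and collector's
    curves of cumulative species descriptions. Includes a seeded synthetic
    occurrence generator with controllable true diversity and sampling
    effort so that every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
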