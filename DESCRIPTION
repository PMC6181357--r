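Package: nestdyn
Title: Stock-and-Flow Dynamics of Nest-Site Availability for Forest Raptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic stock-and-flow model of nesting-platform availability
    and occupancy for a forest raptor community (booted eagle, common buzzard,
    northern goshawk) limited by mature-forest nest sites. Couples a two-stock
    occupancy model (total nests, occupied nests) to an age-structured forest
    submodel with clearcut rotations, and provides scenario builders, summary
    metrics (carrying capacity, capacity gaps, extinction), trajectory export,
    and a command-line interface for forest-management scenario experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
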