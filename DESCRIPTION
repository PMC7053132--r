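Package: demecycles
Title: Multilevel Selection Dynamics of Microbial Populations in
    Structured Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models microbial strains growing on a finite shared resource
    in many separated demes (tidal pools, droplets) that are repeatedly
    pooled, diluted and reseeded by Poisson sampling.  Within-deme growth
    is integrated as a consumer-resource system, optionally coupled to a
    public good: enzymatic degradation of an antibiotic (time-dependent
    growth rate via a Hill dose-response) or pyoverdine production
    (time-dependent yield).  The long-term dynamics are a deterministic
    map between cycles of the mean inoculum, for which the package
    computes expectation lattice sums, Price-equation decompositions of
    composition change, numerical isoclines, fixed points with stability
    classification, limit-cycle detection, closed-form isocline
    approximations, a finite-deme Monte Carlo oracle, and parameter-space
    scans of long-term outcomes (coexistence, fixation, extinction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
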