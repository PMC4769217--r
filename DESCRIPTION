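Package: burnflow
Title: Burn Injury Triage Toolkit: TBSA Estimation, Fluid Planning and
    Store-and-Forward Teleconsultation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support core for emergency burn care at the point of
    care. Estimates total body surface area (TBSA) burned from depth-layered
    paint masks over a two-view body avatar using an age-adjusted
    Lund-Browder allocation, plans Parkland-formula fluid resuscitation with
    the standard 8/16-hour phase split, produces rule-based immediate
    treatment advice offline, and maintains pseudonymized coded case records
    through a simulated store-and-forward tele-expert consultation relay with
    session timeout, access-control and unsynced-data retention rules. Ships
    a deterministic synthetic fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
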