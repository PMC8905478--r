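Package: glucotext
Title: Two-Way SMS Self-Monitoring Support Engine for Gestational Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A testable engine for an automated two-way text-messaging
    intervention supporting self-monitoring of blood glucose (SMBG) in
    gestational diabetes. Schedules four daily glucose-check reminders
    anchored to reported mealtimes plus weekly educational and motivational
    messages, parses glucose replies and returns tiered feedback (rotating
    in-range encouragement, single critical-value replies, care-team
    contact prompts), honors STOP opt-outs, computes capped SMBG adherence
    from glucometer exports with a rank-based pre/during comparison, and
    ships a seeded cohort simulator so the whole pipeline runs without an
    SMS gateway or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
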