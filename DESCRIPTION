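Package: cinegate
Title: Simulation of Prospective Cardio-Respiratory Gating for Steady-State CINE MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software emulation of a hardware gating control unit for small-animal
    MRI together with a simulator of the prospectively gated, steady-state-maintained
    CINE acquisition it drives. Generates seeded synthetic ECG and respiration
    voltage traces with ground-truth event times, models the analogue front end
    (amplifier delay and broadening, voltage scaling), implements the respiratory
    threshold gate with trailing-edge termination and the two-rate turning-point
    R-wave detector, combines the gates into scanner-facing TTL control signals,
    runs the constant-TR gate-evaluation/CINE-block state machine with
    count-threshold breath declaration and automatic re-acquisition, and evolves
    spoiled gradient-echo longitudinal magnetization through the resulting RF
    schedule so that gating schemes (conventional triggering, double gating,
    true steady-state maintenance) can be designed and compared without hardware
    or animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
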