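Package: growsim
Title: Mechanistic Simulation of Human Growth, Body Composition and Energy Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates individual human body weight, body composition (fat mass and
    fat-free mass) and height from birth to old age with a daily explicit-Euler
    energy-balance model. Growth is canalized toward age-, sex- and race-indexed
    reference curves for height, BMI, fat mass index and physical activity; energy
    intake is allocated to basal metabolism (computed from organ masses and
    age-dependent cellularity), activity, the thermic effect of feeding, tissue
    growth and adaptive thermogenesis through an explicit supply/demand priority
    ladder. Includes stunting and catch-up growth in height under chronic energy
    deficit, intake and height-factor calibration, BMI-percentile tracking, and
    energy-gap policy analyses for weight loss and weight maintenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
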