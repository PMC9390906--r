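Package: filmdose
Title: Radiochromic Film In Vivo Dosimetry for Cobalt-60 Teletherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in vivo dosimetry toolkit for GafChromic EBT2 film on a
    Cobalt-60 teletherapy beam. Converts densitometer optical densities to
    absorbed dose through a cubic net-optical-density calibration, propagates
    densitometer and fit uncertainties into a per-dose uncertainty budget,
    builds and combines correction factors for field size, source-to-skin
    distance, gantry angle and wedge angle, and estimates entrance dose (at
    the depth of maximum dose), depth dose via percentage-depth-dose tables,
    and skin dose at the 0.070 mm reference depth. A seeded synthetic-data
    generator emulates film readings, post-exposure optical-density growth,
    calibration datasets and correction-factor landscapes so the whole
    pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
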