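Package: cupversion
Title: Acetabular Cup Version from Anteroposterior Pelvis Radiograph Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the orientation of a total-hip-arthroplasty acetabular
    component from landmark annotations on anteroposterior pelvis radiographs.
    Implements direct least-squares ellipse fitting of the cup-opening rim,
    pelvic pose standardization from the inter-teardrop line and the pelvic
    radiographic axis (sacrococcygeal junction to upper pole of the pubic
    symphysis), the paired positive/negative standardized version angles, and
    the two-radiograph comparison rule that resolves whether the cup is
    anteverted or retroverted. Includes an orthographic radiograph simulator
    that forward-projects a parameterized pelvis and cup so every step can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
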