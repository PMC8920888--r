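Package: lurnoise
Title: Land-Use Regression Mapping of Road-Traffic Noise with Virtual
    Microphone Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scalable land-use-regression (LUR) modelling of
    road-traffic noise (Lden). Builds context-aware raster predictors
    (log-proximity to typed roads, lane-weighted focal road length,
    topographic position indices for terrain and buildings, land-cover
    fractions at systematically scaled radii), draws virtual-microphone
    samples from reference noise rasters under random, systematic and
    stratified designs, fits ordinary-least-squares LUR models, evaluates
    them with conventional and spatially blocked cross-validation, and
    deploys them to area-wide noise predictions with residual and
    threshold reporting. Fully synthetic study scenes, including an
    energetic-summation acoustic fixture, make the whole pipeline
    reproducible without external data.
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
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
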