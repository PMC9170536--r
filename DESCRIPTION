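Package: waggledance
Title: Inference of Honey Bee Foraging from Waggle Dance Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes honey bee (Apis mellifera) waggle dances into
    communicated foraging vectors (bearing and distance), propagates the
    dance's inherent imprecision by simulating each dance's advertised
    location as a probability cloud, intersects clouds with a crop-field
    map, and estimates percent recruitment to crop classes with resampling
    confidence intervals as well as distance-corrected monthly odds ratios
    of crop attractiveness from repeated multinomial logistic fits.
    Includes seasonal foraging-distance summaries with rank-based tests,
    an intra-dance variability screening workflow for data validation, and
    a forward synthetic-data generator (landscape, foraging truth, and
    run-level dance tables) so the whole pipeline can be exercised and
    calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
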