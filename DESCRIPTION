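Package: osnevents
Title: Early Event Detection from Online Social Network Message Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects emerging events from region-tagged social-media message
    streams by monitoring changes in user posting behavior. Provides a seeded
    synthetic stream generator with injectable events, social-triangulation
    geolocation of users from the community accounts they follow, a text
    preprocessing chain (noise filtering, hashtag segmentation, normalization,
    lemmatization), a softmax topic classifier, deep-belief-network subtopic
    discovery with a softmax head fine-tuned by L-BFGS, a relative-change
    detector on daily per-region per-topic counts, a hierarchical tree-grown
    affect classifier over six emotions, and confusion-matrix evaluation
    metrics including the G-mean and detection latency.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
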