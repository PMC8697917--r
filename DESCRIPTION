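Package: kapentagyrus
Title: Morphometric Species Delimitation Tools for Kapentagyrus Gill Monogeneans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphometric species delimitation and identification of
    gill-infecting monogenean flatworms of the genus Kapentagyrus
    (Dactylogyridae), parasites of Afrotropical freshwater clupeid fishes.
    Provides the published dichotomous identification key as an executable,
    traceable decision tree over haptoral sclerite measurements and diagnostic
    length ratios, embedded reference tables of per-species measurement
    summaries and host survey data, quantitative-parasitology summaries
    (prevalence, mean intensity, mean abundance), the multivariate
    morphometric protocol (missing-data filtering, standardization, PCA and
    non-metric multidimensional scaling), and a seeded truncated-normal
    generator of synthetic specimens parameterized from the reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
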