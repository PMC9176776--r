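Package: marriagemarkets
Title: Sex Ratios and Marriage Timing in Family-Reconstitution Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how marriage-market sex ratios relate to the
    timing and likelihood of first marriage in family-reconstitution register
    data. Provides a data model for linked parish registers (baptism, marriage,
    burial acts), retrospective and prospective residence localization,
    operational sex-ratio series at colonial, regional and parish scope with
    opposite-sex-sibling exclusion, annual episode splitting into
    counting-process tables, a stratified Cox proportional-hazards model
    battery, descriptive nuptiality surfaces, and a demographic
    microsimulation that generates register data with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.0),
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    knitr
Config/testthat/edition: 3
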