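Package: cardiomet
Title: Cardiometabolic Phenotyping of the Fructose-Fed Rat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for metabolic-syndrome studies in the
    fructose-overloaded rat: beat-to-beat extraction of systolic, diastolic
    and mean arterial pressure and heart rate from raw pressure waveforms;
    autoregressive (Levinson-Durbin) spectral quantification of systolic
    pressure variability in the low- and high-frequency bands; baroreflex
    sensitivity gains from vasoactive-drug bolus trials; the insulin
    tolerance test rate constant (Kitt); stereological point-counting
    morphometry of heart and aorta (volume and numerical densities, ANP
    granule metrics, intima-media geometry, elastic lamellae counts,
    circumferential wall tension); and the group-comparison statistics
    (one-way ANOVA with Student-Newman-Keuls post-test, repeated-measures
    ANOVA, Pearson correlation). Includes seeded synthetic-data generators
    for every input class so the full pipeline is testable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    nortest,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
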