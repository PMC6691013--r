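Package: stromaquant
Title: Quantification Pipeline for Stromal Remodeling and Biosensor Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable quantification stages for studies of cancer-associated
    fibroblast (CAF) driven matrix remodeling and therapy response: TCSPC
    single-exponential lifetime fitting and FLIM-FRET biosensor thresholding,
    gray-level co-occurrence matrix (GLCM) texture of collagen SHG images,
    gradient-tensor streaming anisotropy, birefringence coverage and gel
    contraction area, color-deconvolution DAB optical density, organotypic
    invasion scoring (invasive index, cluster and mode-of-invasion rules),
    Hertz-model AFM indentation fits, linear-viscoelastic storage modulus
    extraction, and the study-level statistics (Holm-Sidak familywise
    adjustment, two-sample t power and sample size). Seeded synthetic-data
    generators emulate every input with ground truth attached so all stages
    are testable without raw microscopy or instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    EBImage,
    minpack.lm,
    igraph,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
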