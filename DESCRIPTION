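Package: ctbodycomp
Title: CT Body Composition Analysis at the Third Lumbar Vertebra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for body-composition assessment from axial computed
    tomography (CT) at the third lumbar vertebra (L3). Segments skeletal
    muscle, subcutaneous, visceral and intramuscular adipose tissue by
    Hounsfield-unit thresholding within morphologically derived body
    compartments, computes the standard per-tissue areas, percentages,
    height-normalised indices and mean radiodensities, and estimates
    whole-body fat mass and fat-free mass in kilograms with three linear
    models, including a density-weighted model whose predictor combines
    patient weight, whole-slice mean radiodensity and the fat fraction.
    Includes a validation suite (Pearson correlation with Fisher-z
    confidence intervals, Bland-Altman limits of agreement, relative-error
    grids, quantile-quantile normality checks) against dual-energy X-ray
    absorptiometry (DXA) reference masses, and a synthetic phantom and
    cohort generator so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
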