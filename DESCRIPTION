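Package: glucast
Title: Physiological Model-Based Long-Term Glucose Forecasting from CGM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Long-term (30-120 min) blood glucose forecasting for type 1
    diabetes from continuous glucose monitoring (CGM) data. Implements a
    composite minimal model of glucose-insulin dynamics (Bergman minimal
    model coupled to Hovorka-type subcutaneous insulin and gut absorption
    compartments), real-time estimation of the gastrointestinal states by
    deconvolution of the CGM signal, weighted fusion of model and
    deconvolved states, and open-loop propagation over the prediction
    horizon. Includes subject-specific parameter identification by
    constrained minimisation of the mean absolute relative difference
    (MARD), a third-order ARX baseline forecaster, evaluation metrics
    (RMSE, error-grid analysis, hypoglycaemia prediction via the Matthews
    correlation coefficient), gap imputation by modified Akima cubic
    Hermite interpolation, and a virtual-patient scenario generator for
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
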