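Package: fldpsim
Title: Simulated Federated Learning with Differential Privacy for
    Ultrasound Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation bench for privacy-preserving federated
    learning on breast-ultrasound-like images. Generates class-structured
    synthetic speckle phantoms (normal tissue, benign and malignant lesions),
    partitions them across simulated clients under IID or Dirichlet label
    skew with log-normal quantity skew and client-specific feature skew,
    trains closed-form differentiable classifiers with FedAvg, FedProx and
    server-side adaptive (FedOpt) aggregation, applies client-side
    differentially private local updates (per-sample gradient clipping plus
    calibrated Gaussian noise), and accounts the (epsilon, delta) privacy
    budget in closed form under basic and sublinear composition. Includes a
    communication-cost model, macro-averaged evaluation metrics, and an
    experiment matrix/ablation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
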