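Package: adrenomics
Title: CT Radiomics and Unsupervised Classification of Adrenocortical Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based analysis of adrenal CT volumes of interest:
    washout densitometry, a 32-feature radiomic signature (first-order
    histogram, grey-level co-occurrence matrix and run-length matrix
    features), univariate feature selection with ROC/Youden cut-off
    analysis, and unsupervised PCA plus k-means classification of lesions
    into benign and malignant clusters. Includes a synthetic phantom and
    cohort generator so the whole pipeline can be exercised and validated
    without patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
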