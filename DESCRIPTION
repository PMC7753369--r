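Package: msvdfuse
Title: Hybrid EEG-fNIRS Fusion by Multi-Resolution Singular Value Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing concurrently recorded electroencephalography (EEG)
    and functional near-infrared spectroscopy (fNIRS) signals for hybrid
    brain-computer interfaces. Implements multi-resolution singular value
    decomposition (MSVD) of even-dimensioned signal matrices via 2x2
    blockification, the max-absolute-detail / averaged-approximation fusion
    rules at both the feature and the system level, the surrounding pipeline
    (Butterworth filtering, Modified Beer-Lambert conversion, baseline
    standardization, moving-average synchronization, Pearson-correlation
    channel selection, symlet discrete wavelet transform and statistical
    feature extraction), k-nearest-neighbour and decision-tree classification
    with stratified cross-validation, and a synthetic hybrid-signal generator
    with planted cross-modal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rpart,
    pROC
Config/testthat/edition: 3
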