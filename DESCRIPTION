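Package: sinusmatch
Title: Forensic Identification from CT Slices by Keypoint-Descriptor Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches a postmortem head-CT slice against a database of
    antemortem CT-slice feature sets to produce a ranked candidate-identity
    list. CT slices are preprocessed (8-bit normalisation, Sobel edge
    enhancement, box smoothing), keypoints and 64-dimensional real-valued
    descriptors are extracted with a KAZE-style nonlinear-diffusion
    detector, and pairs of feature sets are compared with a bidirectional
    similarity score built from squared-Euclidean nearest-neighbour
    matching, Lowe's ratio test, unique assignment and RANSAC homography
    verification. Includes an encrypted, pseudonymised feature database,
    per-identity rank consolidation with score-based and rank-based
    strategies, a minimal DICOM reader/writer, and a synthetic CT phantom
    generator for end-to-end evaluation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    jsonlite,
    openssl,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
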