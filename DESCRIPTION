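Package: reachgcn
Title: Sit-and-Reach Pose Correctness with a Ghost Spatio-Temporal Graph
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for judging the correctness of sit-and-reach
    (seated forward flexion) exercise form from 2D body-keypoint
    sequences.  Builds chain graphs over grouped unilateral keypoints,
    implements a lightweight spatio-temporal graph convolutional
    classifier in which each block couples a spatial graph convolution,
    a 9-tap temporal convolution and a ghost channel-expansion layer,
    and trains it end to end in R.  Includes a FLOPs/parameter ledger
    for the ghost lightweighting, a self-training loop for pseudo-label
    promotion of keypoint detections with OKS evaluation, a frame
    selection and interpolation pipeline from raw detections to model
    tensors, a synthetic sit-and-reach motion generator with scripted
    error modes, and the evaluation protocol (stratified splits,
    repeated stratified k-fold cross-validation, ablation grids).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
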