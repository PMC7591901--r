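Package: voxsite
Title: Voxel-Based Detection of Druggable Ligand-Binding Sites on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects druggable ligand-binding sites on protein structures by
    treating them as multi-channel three-dimensional images. Structures are
    voxelized into atomic-density grids, tiled into fixed-size cubes, and
    scanned with a cell-based 3D convolutional detection network trained with
    a YOLO-style composite loss; raw cell predictions are merged by greedy
    non-maximum suppression in Cartesian space. Includes rotation-replica
    averaging over icosahedron-facet axes, spatiotemporal clustering of
    predictions across conformational ensembles with two cluster scores,
    average-precision evaluation under center- and ligand-distance criteria,
    training-corpus curation filters with a structural-similarity-aware
    train/validation split, and a synthetic-structure generator that plants
    labeled pockets so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
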