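Package: striaparc
Title: Connectivity-Based Parcellation of Brain Regions from Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subdividing a seed brain region (e.g. the striatum) by
    clustering voxelwise resting-state functional-connectivity profiles.
    Implements temporal preprocessing (framewise-displacement exclusion,
    despiking, CompCor nuisance components, simultaneous band-pass filtering
    and nuisance regression), seed-voxel by target-voxel Fisher-z correlation
    profiles, K-means clustering with correlation distance and restarts,
    split-half variation-of-information stability analysis with an optimal-K
    selection rule, seed-to-voxel multiple-regression connectivity maps with
    permutation cluster-extent correction, and ROI-to-ROI connectivity with
    Benjamini-Hochberg false-discovery-rate control. A synthetic multi-subject
    data generator with planted cluster structure makes the whole pipeline
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
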