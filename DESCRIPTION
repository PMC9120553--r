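Package: movieroi
Title: Subject-Specific Functional ROIs from Short Movie-Viewing fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Defines subject-specific face, scene and object regions of
    interest (ssROIs) from a single short movie-viewing fMRI run, and runs
    the downstream timecourse analyses that validate them: artifact
    detection and scrubbing, component-based nuisance regression (CompCor),
    discrete-cosine high-pass filtering, localizer GLMs with contrast
    t-maps, group-constrained subject-specific (GSS) voxel selection,
    reverse-correlation event detection, split-half inter-regional
    correlation with Fisher z transformation, partial and lag-shifted
    correlations, and leave-one-out group means. Includes a synthetic
    multi-subject BOLD generator with planted ground truth (selective
    voxels, latent region timecourses, motion artifacts, developmental
    effects) so the full pipeline is testable end to end without any data
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
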