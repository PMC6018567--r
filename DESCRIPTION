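Package: iterlesion
Title: Iterative Voxel-Based Lesion-Deficit Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate voxel-based lesion-deficit mapping for stroke
    cohorts, with permutation-based family-wise error control (maxT and
    maximum cluster extent under Freedman-Lane residual permutation) and an
    iterative patient-exclusion procedure that re-runs the analysis after
    removing patients with substantial damage to previously identified
    regions, unmasking lesion sites whose association with the deficit is
    diluted when the same deficit can arise from damage to any of several
    regions. Includes lesion-image input/output and summaries (overlap maps,
    analysis masks, region damage fractions), behavioural score handling with
    task-specific impairment cut-offs, post-hoc incidence and severity
    analyses, statistical power maps, and a synthetic lesion-cohort simulator
    with vascular-territory-like lesion co-occurrence and OR-structured
    deficit causation for validating the method against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
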