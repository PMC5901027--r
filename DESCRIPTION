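Package: littplan
Title: Computer-Assisted Trajectory Planning for Laser Interstitial
    Thermal Therapy of the Mesial Temporal Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated stereotactic trajectory planning for laser
    interstitial thermal therapy (LiTT) of the amygdalohippocampal
    complex in mesial temporal lobe epilepsy. Provides a parametric
    synthetic head phantom with ground-truth geometry, label-volume
    anatomy tools (region masks, exact anisotropic Euclidean distance
    fields, skull surface geometry, tectal-plate truncation), trajectory
    safety metrics (intracerebral length, drilling angle, risk from
    cumulative proximity to critical structures, brainstem clearance),
    an entry-point planner with feasibility filtering and weighted
    ranking over prioritized entry gyri, cylindrical ablation-zone
    modeling with per-structure volumetrics and residual mesial
    hippocampal head depth, and manual-versus-automated comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
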