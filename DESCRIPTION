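Package: spotlab
Title: Spot-Size Effects in Pencil Beam Scanning Proton Lung Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of small versus large spot sizes in
    pencil beam scanning proton therapy for moving lung targets. Provides a
    seeded synthetic 4D thorax phantom with analytic, invertible displacement
    fields; an analytic pencil-beam dose engine with energy-dependent Gaussian
    lateral profiles and a parameterized Bragg depth-dose; SFUD spot placement
    and robust (worst-case) spot-weight optimization with D99 normalization,
    minimum-MU enforcement and alternating-order volumetric repainting; DVH
    metrics; 12-scenario setup/range robustness evaluation; Niemierko
    EUD/NTCP radiobiological modelling; and a time-resolved interplay
    simulation that distributes spot delivery over breathing phases and
    accumulates dose on a reference phase.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
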