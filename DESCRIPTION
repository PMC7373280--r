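Package: eogtandem
Title: Unsupervised Relabeling and CNN-LSTM Classification of Electrooculographic Saccades
Version: 0.1.0
Authors@R: person("EOG", "Tandem Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening spinocerebellar ataxia type 2 from
    electrooculography (EOG) saccade recordings. Patient registers of
    saccades carry a single diagnosis (control, presymptomatic, sick) even
    though presymptomatic registers contain many healthy-looking saccades;
    the package corrects this bag-level label noise by clustering training
    saccades on a self-organizing map and relabeling each map cell through
    a control/presymptomatic count-ratio threshold, then trains a 1D
    convolutional + LSTM classifier on the relabeled saccades and
    classifies registers by majority vote. Includes saccade segmentation
    from raw traces, a synthetic saccade-register generator with per-saccade
    ground truth, threshold-sweep experiment orchestration, and a command
    line interface.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
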