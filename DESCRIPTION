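Package: p300em
Title: Unsupervised EM-Trained Bayesian Classification for the P300 Matrix Speller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a Bayesian linear classifier for the row/column P300
    matrix speller that is trained entirely without labelled data. The
    spelling paradigm's constraint -- one target row and one target column per
    character, shared across stimulus repetitions -- is embedded as a discrete
    latent indicator per pseudo-symbol, and the classifier is fitted by
    expectation-maximization with closed-form updates for the weight vector,
    the projection noise variance and the prior precision. Includes the
    character-by-character EEG preprocessing chain (common average reference,
    band-pass filtering, channel normalization, decimated epoch extraction),
    offline and online/adaptive spelling protocols including a cold-start
    speller with couple reinitialisation, likelihood-based classifier
    selection, synthetic session generators at feature and raw-signal level,
    evaluation metrics (rank AUC, spelling accuracy, online traces), a
    CSV/JSON session bundle format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'paradigm.R'
    'preprocess.R'
    'model.R'
    'em.R'
    'runtime.R'
    'synthetic.R'
    'evaluation.R'
    'bundle.R'
    'cli.R'
    'p300em-package.R'
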