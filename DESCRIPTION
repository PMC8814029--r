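Package: nisqclass
Title: Quantum Machine-Learning Classifiers for Tabular Data on a Statevector Simulator
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dense statevector simulator with the minimal gate set needed for
    near-term quantum machine learning on two-class tabular data: log2(N)
    amplitude encoding via Ry/CNOT rotation trees, an N-qubit Hadamard/Rz
    feature map, Hadamard-test and Swap-test inner-product estimation (exact or
    from binomial shot counts), a quantum distance classifier, a simplified
    quantum-kernel support vector machine with imbalance-ratio weights, a
    reference kernel SVM, an analytic depolarizing-noise model with
    least-squares slope/RMSE/fidelity analysis, and a cross-validated AUC
    evaluation pipeline with a synthetic two-class Gaussian data generator and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
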