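# nisqclass

Quantum machine-learning classifiers for two-class tabular (clinical-style)
data, running entirely on a bundled dense statevector simulator. The package
targets the regime where near-term quantum hardware is plausible: few
features, small cohorts, shallow circuits.

## What it implements

**Encoding.** A feature vector x ∈ ℝᴺ is zero-padded to the next power of
two, l2-normalised, and stored as the amplitudes of an n = ⌈log₂N⌉-qubit
state |φ(x)⟩ prepared by a hierarchical tree of R_y rotations expanded into
R_y/CNOT sequences (so 8 features need 3 qubits). An alternative N-qubit map
(H on every qubit, features as R_z angles, nearest-neighbour CNOT chain) is
provided for comparison.

**Overlap estimation.** Two interference circuits read inner products off an
ancilla qubit:

- Hadamard test: Pr(ancilla = 0) = (1 + Re⟨u|v⟩)/2, so Re⟨u|v⟩ = 2·Pr(0) − 1;
- Swap test: Pr(ancilla = 0) = (1 + |⟨u|v⟩|²)/2, so |⟨u|v⟩|² = 2·Pr(0) − 1.

Both run exactly (probability read off the statevector) or with binomial
shot noise (default 8192 shots), optionally through a depolarizing channel.

**Classifiers.**

- *qDC* (quantum distance classifier): splits training samples by label into
  sets P and Q, computes d(u, v) = 1 − ⟨u|v⟩ to every training state via the
  Hadamard test, and assigns the label of the closer set (ties go to P).
- *sqKSVM* (simplified quantum-kernel SVM): decision value
  Σᵢ yᵢ αᵢ* K(xᵢ, x̃) with the quantum kernel K = |⟨u|v⟩|² and *fixed*
  weights from the class imbalance ratio IR (αᵢ* = 1 when IR = 0.5, else IR
  for the majority and 1 − IR for the minority class); threshold at 0. No
  optimisation, so the kernel is evaluated once.
- *qKSVM reference*: a conventional soft-margin SVM dual (hand-written
  deterministic SMO) on the same precomputed quantum kernel.

**Noise analysis.** The depolarizing channel ε_λ(ρ) = (1−λ)ρ + λ·I/2ⁿ
contracts expectation values by (1−λ). Fitting noisy-vs-ideal overlap
scatter by ordinary least squares estimates λ̂ = 1 − slope; RMSE between the
two value sets gives a fidelity 1 − RMSE.

**Pipeline.** CSV loading, correlation-redundancy reduction, univariate
feature ranking (training split only), repeated stratified 80/20
cross-validation with rank-based AUC, imbalance ratio, an experimental
geometric-difference score g_CQ comparing quantum and classical linear
kernels, a synthetic two-class Gaussian generator, and a CLI.

## Worked example

```r
library(nisqclass)

d <- generate_two_class(M = 60, N = 8, separation = 3, IR = 0.4, seed = 42)
imbalance_ratio(d$labels)
#> [1] 0.4

circ <- encode_log2n(d$features[1, ])
circ
#> <qcircuit> 3 qubit(s), 13 gate(s)
round(Re(statevector_of(circ)), 4)
#> [1] 0.3023 0.1424 0.2738 0.4288 0.2832 0.5414 0.3357 0.3787
round(normalize_and_pad(d$features[1, ]), 4)   # identical by construction
#> [1] 0.3023 0.1424 0.2738 0.4288 0.2832 0.5414 0.3357 0.3787

u <- d$features[1, ]; v <- d$features[2, ]
hadamard_test(encode_log2n(u), encode_log2n(v))$value  # = u.v exactly
#> [1] 0.9109665
swap_test(encode_log2n(u), encode_log2n(v), mode = "shots", seed = 7)$value
#> [1] 0.8146973   # |u.v|^2 = 0.8299 estimated from 8192 shots

cross_validate(d, classifier = "qdc", encoding = "log2n",
               cfg = cv_config(seed = 1))
#> <evaluation_report> qdc / log2n encoding
#>   folds: 10  features: all  IR: 0.4
#>   fold AUC: 1.000 1.000 0.971 1.000 0.943 0.943 1.000 0.886 0.971 0.914
#>   mean AUC: 0.9629

sc <- noise_scatter(200, 8, noise_model(0.1, shots = 8192), seed = 9)
sc$fit
#> <noise_fit> n = 200; slope = 0.9007, intercept = 0.0002881
#>   lambda_hat = 0.09926, RMSE = 0.04016, fidelity = 0.9598
```

The mean CV AUC of 0.96 says the quantum distance classifier nearly
separates a 3σ-separated synthetic cohort; the noise fit recovers the
injected depolarizing rate λ = 0.1 to three decimals from 8192-shot
sampling, with a 4% RMSE between noisy and ideal overlaps.

## Command line

```sh
Rscript -e 'nisqclass::run_cli()' generate --samples 100 --features 8 --separation 2 --out data.csv
Rscript -e 'nisqclass::run_cli()' evaluate data.csv --model sqksvm --encoding log2n --features 8 --out report.csv
Rscript -e 'nisqclass::run_cli()' noise-fit --lambda 0.1 --backend shots --out scatter.csv
```

Commands: `generate`, `encode`, `kernel`, `classify`, `evaluate`,
`noise-fit`; shared flags `--encoding {log2n,nqubit}`,
`--backend {exact,shots}`, `--shots`, `--lambda`, `--seed`, `--features`,
`--out`.

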