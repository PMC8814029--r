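# Depolarizing noise: with probability lambda the state is replaced by the
# maximally mixed state I/2^n, so any expectation value contracts linearly,
#   <O>_noisy = (1 - lambda) <O> + lambda tr(O) / 2^n.
# For the ancilla Pauli-Z readout (traceless) this turns the ancilla
# probability p into p' = (1 - lambda) p + lambda / 2.  The analysis side
# fits noisy-vs-ideal scatter by ordinary least squares: the slope estimates
# 1 - lambda, the RMSE measures the discrepancy, and fidelity = 1 - RMSE.

#' Construct a depolarizing noise model
#'
#' @param lambda probability of error rate in `[0, 1]`.
#' @param n_qubits qubit count of the noisy register (enters through the
#'   `tr(O)/2^n` term for non-traceless observables).
#' @param shots shot budget used when sampling under this model.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(lambda, n_qubits = 1L, shots = 8192L) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  structure(list(lambda = lambda, n_qubits = as.integer(n_qubits),
                 shots = if (is.null(shots)) NULL else as.integer(shots)),
            class = "noise_model")
}

#' Noisy expectation value under depolarizing noise
#'
#' `(1 - lambda) * ideal + lambda * o_trace / 2^n`.  For a traceless
#' observable (e.g. Pauli Z) this is a pure contraction towards 0.
#'
#' @param ideal noiseless expectation value(s).
#' @param model a [noise_model()].
#' @param o_trace trace of the observable (0 for Pauli Z).
#' @return Numeric noisy expectation value(s).
#' @export
noisy_expectation <- function(ideal, model, o_trace = 0) {
  (1 - model$lambda) * ideal + model$lambda * o_trace / 2^model$n_qubits
}

#' Overlap estimate under depolarizing noise and shot sampling
#'
#' Runs the chosen overlap test exactly, contracts the ancilla probability by
#' `p' = (1 - lambda) p + lambda / 2` (the depolarizing channel applied to
#' the final pre-measurement state, ancilla Z observable), samples
#' `Binomial(shots, p')`, and returns the usual `2 p-hat - 1` estimator.
#' With `shots = NULL` the infinite-shot limit is returned (no sampling).
#'
#' @param U,V state-preparation [circuit()]s.
#' @param test `"hadamard"` or `"swap"`.
#' @param model a [noise_model()].
#' @param seed integer seed for the binomial draw.
#' @return The (noisy) overlap estimate, a plain number: Re<u|v> for the
#'   Hadamard test, |<u|v>|^2 for the Swap test (not clipped, so the noise
#'   contraction is visible).
#' @export
noisy_overlap_run <- function(U, V, test = c("hadamard", "swap"), model,
                              seed = 1L) {
  test <- match.arg(test)
  circ <- if (test == "hadamard") hadamard_test_circuit(U, V) else
    swap_test_circuit(U, V)
  st <- run_circuit(circ)
  p0 <- marginal_probability(st, 0L, 0)
  p0 <- (1 - model$lambda) * p0 + model$lambda / 2
  if (!is.null(model$shots) && is.finite(model$shots)) {
    cnt <- sample_counts(st_with_p0(1L, p0), 0L, model$shots, seed)
    p0 <- cnt$count0 / cnt$shots
  }
  2 * p0 - 1
}

#' Least-squares fit of noisy vs ideal overlap values
#'
#' Ordinary least squares of `noisy` on `ideal` (unconstrained intercept).
#' Under pure depolarizing noise the slope is `1 - lambda`, so
#' `lambda_hat = 1 - slope`.  RMSE is the root mean squared difference
#' between the two value sets, and the fidelity is reported as `1 - RMSE`.
#'
#' @param ideal,noisy equal-length numeric vectors (>= 2 points; `ideal`
#'   must not be constant).
#' @return A list of class `noise_fit`: `slope`, `intercept`, `lambda_hat`,
#'   `rmse`, `fidelity`, `n_points`.
#' @export
fit_noise <- function(ideal, noisy) {
  if (length(ideal) != length(noisy)) stop("ideal and noisy lengths differ")
  if (length(ideal) < 2) stop("need at least 2 points")
  if (stats::var(ideal) == 0) stop("ideal values have zero variance")
  fit <- stats::lm.fit(cbind(1, ideal), noisy)
  rmse <- sqrt(mean((noisy - ideal)^2))
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 lambda_hat = 1 - unname(fit$coefficients[2]),
                 rmse = rmse,
                 fidelity = 1 - rmse,
                 n_points = length(ideal)),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat("<noise_fit> n = ", x$n_points,
      "; slope = ", format(x$slope, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4),
      "\n  lambda_hat = ", format(x$lambda_hat, digits = 4),
      ", RMSE = ", format(x$rmse, digits = 4),
      ", fidelity = ", format(x$fidelity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simulate a noisy-vs-ideal overlap scatter
#'
#' Draws random unit-vector pairs, computes the exact Hadamard-test overlap
#' and its shot-sampled depolarized counterpart, and returns the scatter plus
#' its [fit_noise()] report — the simulator-side analogue of comparing a
#' noiseless simulator with a noisy device.
#'
#' @param n_pairs number of random vector pairs.
#' @param n_features feature-vector length (encoded on `ceil(log2 N)` qubits).
#' @param model a [noise_model()]; `shots = NULL` for the exact-probability
#'   limit.
#' @param seed integer seed for both the vector draws and the shot sampling.
#' @return A list: `data` (data.frame with `ideal`, `noisy`) and `fit`
#'   (a `noise_fit`).
#' @export
noise_scatter <- function(n_pairs = 500L, n_features = 8L, model, seed = 1L) {
  pairs <- with_local_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      u <- stats::rnorm(n_features)
      v <- stats::rnorm(n_features)
      list(u = u / sqrt(sum(u^2)), v = v / sqrt(sum(v^2)))
    })
  })
  ideal <- numeric(n_pairs); noisy <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    Uc <- encode_log2n(pairs[[i]]$u)
    Vc <- encode_log2n(pairs[[i]]$v)
    ideal[i] <- hadamard_test(Uc, Vc)$value
    noisy[i] <- noisy_overlap_run(Uc, Vc, "hadamard", model,
                                  seed = as.integer((seed + 977L * i) %% .Machine$integer.max))
  }
  list(data = data.frame(ideal = ideal, noisy = noisy),
       fit = fit_noise(ideal, noisy))
}
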