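# Overlap estimation circuits.
#
# Both tests place the ancilla on qubit 0 and the data register(s) above it.
# Pr(0) on the ancilla carries the overlap:
#   Hadamard test: Pr(0) = (1 + Re<u|v>) / 2      -> value = 2 Pr(0) - 1
#   Swap test:     Pr(0) = (1 + |<u|v>|^2) / 2    -> value = 2 Pr(0) - 1
# In shots mode Pr(0) is replaced by the empirical frequency of a binomial
# draw; an optional depolarizing parameter lambda contracts Pr(0) towards 1/2
# before sampling (see module `noise`).

new_overlap_estimate <- function(value, mode, shots, seed) {
  structure(list(value = value, mode = mode,
                 shots = if (mode == "exact") 0L else as.integer(shots),
                 seed = if (mode == "exact") NA_integer_ else as.integer(seed)),
            class = "overlap_estimate")
}

#' @export
print.overlap_estimate <- function(x, ...) {
  cat("<overlap_estimate> ", format(x$value), " (", x$mode,
      if (x$mode == "shots") paste0(", shots=", x$shots), ")\n", sep = "")
  invisible(x)
}

# Gate list of controlled-(U shifted above the ancilla): the reusable heart
# of the Hadamard-test circuit for one encoded sample.
prep_ctrl_gates <- function(circ) {
  controlled_circuit(shift_circuit(circ, 1L), 0L)$gates
}

# Build the Hadamard-test circuit for state-preparation circuits U, V on n
# qubits each: ancilla q0; H; controlled-U; X; controlled-V; X; H.
hadamard_test_circuit <- function(U, V) {
  hadamard_circuit_from_gates(prep_ctrl_gates(U), prep_ctrl_gates(V),
                              U$n_qubits)
}

hadamard_circuit_from_gates <- function(cu_gates, cv_gates, n) {
  new_circuit(n + 1L, c(list(gate_h(0)), cu_gates, list(gate_x(0)),
                        cv_gates, list(gate_x(0), gate_h(0))))
}

# Build the Swap-test circuit: ancilla q0; U on qubits 1..n, V on n+1..2n;
# H(0); controlled-SWAP per qubit pair; H(0).
swap_test_circuit <- function(U, V) {
  n <- U$n_qubits
  swap_circuit_from_gates(shift_circuit(U, 1L)$gates,
                          shift_circuit(V, n + 1L)$gates, n)
}

swap_circuit_from_gates <- function(u_gates, v_gates, n) {
  cswaps <- lapply(1:n, function(i) gate_swap(i, i + n, controls = 0L))
  new_circuit(2L * n + 1L,
              c(list(gate_h(0)), u_gates, v_gates, cswaps, list(gate_h(0))))
}

# Shared estimator plumbing: exact ancilla Pr(0), optional depolarizing
# contraction, optional binomial sampling, then value = 2 Pr(0) - 1.
overlap_from_circuit <- function(circ, mode, shots, seed, lambda) {
  st <- run_circuit(circ)
  p0 <- marginal_probability(st, 0L, 0)
  if (lambda > 0) p0 <- (1 - lambda) * p0 + lambda / 2
  if (mode == "shots") {
    counts <- sample_counts(st_with_p0(circ$n_qubits, p0), 0L, shots, seed)
    p0 <- counts$count0 / counts$shots
  }
  2 * p0 - 1
}

# A 1-qubit stand-in state whose qubit-0 marginal is exactly p0; sampling the
# ancilla of the real circuit is statistically identical to sampling this.
st_with_p0 <- function(n_qubits, p0) {
  p0 <- min(max(p0, 0), 1)
  state_vector(c(sqrt(p0), sqrt(1 - p0)), 1L)
}

check_same_width <- function(U, V) {
  if (U$n_qubits != V$n_qubits) {
    stop("U acts on ", U$n_qubits, " qubits but V on ", V$n_qubits)
  }
}

#' Hadamard test: estimate Re<u|v>
#'
#' Assembles the interference circuit (H on the ancilla, controlled-U, X,
#' controlled-V, X, H, Z-basis measurement of the ancilla) for the states
#' `|u> = U|0...0>` and `|v> = V|0...0>`, and returns `2 Pr(0) - 1`, i.e. the
#' real part of the inner product.  Exact mode reads `Pr(0)` off the
#' statevector; shots mode replaces it with the empirical frequency of
#' `Binomial(shots, Pr(0))`.
#'
#' @param U,V state-preparation [circuit()]s on the same qubit count.
#' @param mode `"exact"` or `"shots"`.
#' @param shots number of measurement shots (shots mode; default 8192).
#' @param seed integer seed for the shot sampling.
#' @param lambda depolarizing error-rate parameter applied to the ancilla
#'   observable before sampling (0 = noiseless).
#' @return An `overlap_estimate`; `$value` lies in `[-1, 1]`.
#' @export
hadamard_test <- function(U, V, mode = c("exact", "shots"), shots = 8192L,
                          seed = 1L, lambda = 0) {
  mode <- match.arg(mode)
  check_same_width(U, V)
  stopifnot(lambda >= 0, lambda <= 1)
  val <- overlap_from_circuit(hadamard_test_circuit(U, V), mode, shots, seed,
                              lambda)
  new_overlap_estimate(min(max(val, -1), 1), mode, shots, seed)
}

#' Swap test: estimate |<u|v>|^2
#'
#' Assembles the controlled-SWAP circuit (H on the ancilla, U and V on
#' disjoint registers, one ancilla-controlled SWAP per qubit pair, H,
#' Z-basis measurement) and returns `2 Pr(0) - 1 = |<u|v>|^2`.  In shots
#' mode a negative estimate (possible through sampling noise since
#' `Pr(0) >= 1/2` only holds exactly) is clipped to 0.
#'
#' @inheritParams hadamard_test
#' @return An `overlap_estimate`; `$value` lies in `[0, 1]`.
#' @export
swap_test <- function(U, V, mode = c("exact", "shots"), shots = 8192L,
                      seed = 1L, lambda = 0) {
  mode <- match.arg(mode)
  check_same_width(U, V)
  stopifnot(lambda >= 0, lambda <= 1)
  val <- overlap_from_circuit(swap_test_circuit(U, V), mode, shots, seed,
                              lambda)
  new_overlap_estimate(min(max(val, 0), 1), mode, shots, seed)
}

#' Quantum kernel matrix between two sample sets
#'
#' Entry (i, j) is the squared overlap `K(x_i, x_j') = |<u_i|v_j>|^2` between
#' the encoded samples, estimated either with the Swap test or by squaring
#' the Hadamard-test real part (equivalent for real-valued data).  In exact
#' mode with `A` and `B` the same object, only the upper triangle is computed
#' and the diagonal is 1.
#'
#' @param A,B numeric matrices, rows = samples sharing a feature count.
#' @param encoder function mapping a feature vector to a [circuit()], e.g.
#'   from [make_encoder()].
#' @param method `"swap"` or `"hadamard2"`.
#' @param mode `"exact"` or `"shots"`.
#' @param shots,seed,lambda shot-sampling controls as in [hadamard_test()];
#'   entry (i, j) uses a distinct seed derived from `seed`.
#' @return Numeric `nrow(A) x nrow(B)` matrix with entries in `[0, 1]`,
#'   dimnames from the row names of `A` and `B`.
#' @export
kernel_matrix <- function(A, B = A, encoder = encode_log2n,
                          method = c("swap", "hadamard2"),
                          mode = c("exact", "shots"),
                          shots = 8192L, seed = 1L, lambda = 0) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share the feature count")
  symmetric <- identical(dim(A), dim(B)) && identical(unname(A), unname(B)) &&
    mode == "exact"

  encA <- lapply(seq_len(nrow(A)), function(i) encoder(A[i, ]))
  encB <- if (symmetric) encA else
    lapply(seq_len(nrow(B)), function(j) encoder(B[j, ]))
  n <- encA[[1]]$n_qubits

  # precompute the per-sample gate lists once; assembling a pairwise test
  # circuit is then a cheap concatenation
  if (method == "swap") {
    gA <- lapply(encA, function(ci) shift_circuit(ci, 1L)$gates)
    gB <- if (symmetric) lapply(encA, function(ci) shift_circuit(ci, n + 1L)$gates)
          else lapply(encB, function(ci) shift_circuit(ci, n + 1L)$gates)
  } else {
    gA <- lapply(encA, prep_ctrl_gates)
    gB <- if (symmetric) gA else lapply(encB, prep_ctrl_gates)
  }

  one_entry <- function(i, j, s) {
    if (method == "swap") {
      circ <- swap_circuit_from_gates(gA[[i]], gB[[j]], n)
      val <- overlap_from_circuit(circ, mode, shots, s, lambda)
      min(max(val, 0), 1)
    } else {
      circ <- hadamard_circuit_from_gates(gA[[i]], gB[[j]], n)
      val <- overlap_from_circuit(circ, mode, shots, s, lambda)
      min(max(val, -1), 1)^2
    }
  }

  K <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    jmin <- if (symmetric) i else 1L
    for (j in jmin:nrow(B)) {
      s <- as.integer((seed + 7919 * (i - 1) + j) %% .Machine$integer.max)
      K[i, j] <- if (symmetric && i == j) 1 else one_entry(i, j, s)
      if (symmetric) K[j, i] <- K[i, j]
    }
  }
  rownames(K) <- rownames(A); colnames(K) <- rownames(B)
  K
}

#' Write a kernel matrix as CSV
#'
#' @param K matrix from [kernel_matrix()].
#' @param path output file; row/column sample identifiers are kept.
#' @export
write_kernel_csv <- function(K, path) {
  utils::write.csv(K, path, row.names = TRUE)
}
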