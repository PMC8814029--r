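# Dense statevector simulator.
#
# Basis-state convention: amplitude index i (0-based) encodes the basis state
# |q_{n-1} ... q_1 q_0> with qubit 0 the LEAST significant bit of i.  The
# ancilla of the overlap-test circuits is qubit 0 throughout the package.

#' Construct a statevector
#'
#' A pure quantum state on `n_qubits` qubits, stored as the dense vector of
#' `2^n_qubits` complex amplitudes.  Qubit 0 is the least-significant bit of
#' the basis-state index.
#'
#' @param amplitudes complex (or numeric) vector of length `2^n_qubits`,
#'   normalised to unit l2 norm within `1e-10`.
#' @param n_qubits number of qubits; inferred from `length(amplitudes)` when
#'   missing.
#' @return An object of class `state_vector` with fields `n_qubits` and
#'   `amplitudes`.
#' @examples
#' state_vector(c(1, 0))            # |0>
#' zero_state(3)                    # |000>
#' @export
state_vector <- function(amplitudes, n_qubits = NULL) {
  amplitudes <- as.complex(amplitudes)
  if (is.null(n_qubits)) {
    n_qubits <- round(log2(length(amplitudes)))
  }
  if (n_qubits < 1 || length(amplitudes) != 2^n_qubits) {
    stop("amplitudes must have length 2^n_qubits with n_qubits >= 1")
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-10) {
    stop("state is not normalised: sum |amplitude|^2 = ", format(nrm))
  }
  structure(list(n_qubits = as.integer(n_qubits), amplitudes = amplitudes),
            class = "state_vector")
}

#' @rdname state_vector
#' @export
zero_state <- function(n_qubits) {
  amps <- complex(2^n_qubits)
  amps[1] <- 1 + 0i
  state_vector(amps, n_qubits)
}

#' @export
print.state_vector <- function(x, ...) {
  cat("<state_vector> ", x$n_qubits, " qubit(s), ",
      length(x$amplitudes), " amplitudes\n", sep = "")
  invisible(x)
}

# ---- gates ------------------------------------------------------------------

GATE_KINDS <- c("RY", "RZ", "H", "X", "Z", "CNOT", "SWAP")

#' Construct a gate
#'
#' Gates are the fixed vocabulary the overlap circuits need: `RY`, `RZ`, `H`,
#' `X`, `Z`, `CNOT` and `SWAP`, each optionally promoted by extra control
#' qubits.  `RY(phi)` uses the half-angle matrix
#' `[[cos(phi/2), -sin(phi/2)], [sin(phi/2), cos(phi/2)]]`, so `RY(2*theta)`
#' maps `|0>` to `cos(theta)|0> + sin(theta)|1>` (a negative `theta` carries
#' the sign of the `sin` branch).
#'
#' @param kind one of `"RY"`, `"RZ"`, `"H"`, `"X"`, `"Z"`, `"CNOT"`, `"SWAP"`.
#' @param targets target qubit index (two indices for `SWAP`).
#' @param controls zero or more control qubit indices, disjoint from `targets`.
#'   For `CNOT` the control goes here.
#' @param angle rotation angle in radians (`RY`/`RZ` only).
#' @return An object of class `qgate`.
#' @seealso [gate_ry()], [gate_h()], [gate_cnot()] and friends for shorthand
#'   constructors.
#' @export
gate <- function(kind, targets, controls = integer(0), angle = NULL) {
  kind <- match.arg(kind, GATE_KINDS)
  targets <- as.integer(targets)
  controls <- as.integer(controls)
  n_targets <- if (kind == "SWAP") 2L else 1L
  if (length(targets) != n_targets) {
    stop(kind, " takes exactly ", n_targets, " target(s)")
  }
  if (kind == "CNOT" && length(controls) < 1) {
    stop("CNOT needs at least one control")
  }
  if (anyDuplicated(c(targets, controls))) {
    stop("controls and targets must be disjoint qubit indices")
  }
  if (kind %in% c("RY", "RZ")) {
    if (is.null(angle)) stop(kind, " needs an angle")
  } else if (!is.null(angle)) {
    stop("angle given for non-rotation gate ", kind)
  }
  structure(list(kind = kind, targets = targets, controls = controls,
                 angle = angle),
            class = "qgate")
}

#' @rdname gate
#' @param target,control,q1,q2 qubit indices for the shorthand constructors.
#' @export
gate_ry <- function(target, angle, controls = integer(0))
  gate("RY", target, controls, angle)

#' @rdname gate
#' @export
gate_rz <- function(target, angle, controls = integer(0))
  gate("RZ", target, controls, angle)

#' @rdname gate
#' @export
gate_h <- function(target, controls = integer(0)) gate("H", target, controls)

#' @rdname gate
#' @export
gate_x <- function(target, controls = integer(0)) gate("X", target, controls)

#' @rdname gate
#' @export
gate_z <- function(target, controls = integer(0)) gate("Z", target, controls)

#' @rdname gate
#' @export
gate_cnot <- function(control, target) gate("CNOT", target, control)

#' @rdname gate
#' @export
gate_swap <- function(q1, q2, controls = integer(0))
  gate("SWAP", c(q1, q2), controls)

# 2x2 matrix of a single-qubit gate kind (CNOT shares the X matrix).
gate_matrix_2x2 <- function(g) {
  switch(g$kind,
    RY = {
      c <- cos(g$angle / 2); s <- sin(g$angle / 2)
      matrix(c(c, s, -s, c), 2, 2)
    },
    RZ = diag(c(exp(-1i * g$angle / 2), exp(1i * g$angle / 2))),
    H  = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X  = matrix(c(0, 1, 1, 0), 2, 2),
    CNOT = matrix(c(0, 1, 1, 0), 2, 2),
    Z  = diag(c(1, -1)),
    stop("no 2x2 matrix for ", g$kind)
  )
}

# ---- circuits ---------------------------------------------------------------

#' Construct a circuit
#'
#' An ordered gate sequence on a fixed qubit count.  Applying a circuit
#' preserves the state norm (all gates are unitary).
#'
#' @param n_qubits number of qubits the circuit acts on.
#' @param gates list of [gate()] objects, applied in order.
#' @return An object of class `qcircuit`.
#' @examples
#' bell <- circuit(2, list(gate_h(0), gate_cnot(0, 1)))
#' run_circuit(bell, zero_state(2))
#' @export
circuit <- function(n_qubits, gates = list()) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1) stop("n_qubits must be >= 1")
  for (g in gates) {
    if (!inherits(g, "qgate")) stop("gates must be a list of qgate objects")
    if (max(c(g$targets, g$controls)) >= n_qubits) {
      stop("gate touches qubit ", max(c(g$targets, g$controls)),
           " but circuit has ", n_qubits, " qubits")
    }
  }
  structure(list(n_qubits = n_qubits, gates = gates), class = "qcircuit")
}

# Validation-free constructor for hot paths that assemble circuits from
# already-checked gate lists.
new_circuit <- function(n_qubits, gates) {
  structure(list(n_qubits = n_qubits, gates = gates), class = "qcircuit")
}

#' @export
print.qcircuit <- function(x, ...) {
  cat("<qcircuit> ", x$n_qubits, " qubit(s), ", length(x$gates),
      " gate(s)\n", sep = "")
  if (length(x$gates)) {
    desc <- vapply(x$gates, function(g) {
      a <- if (is.null(g$angle)) "" else sprintf("(%.4g)", g$angle)
      ctl <- if (length(g$controls)) paste0(" c", paste(g$controls, collapse = ",")) else ""
      paste0(g$kind, a, " t", paste(g$targets, collapse = ","), ctl)
    }, character(1))
    cat(" ", paste(utils::head(desc, 12), collapse = "; "),
        if (length(desc) > 12) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Basis-index bookkeeping is identical for every gate with the same qubit
# count / targets / controls, so the (1-based) index pairs are memoised.
.idx_cache <- new.env(parent = emptyenv())

gate_index_pairs <- function(n, g) {
  key <- paste(n, g$kind == "SWAP", paste(g$targets, collapse = ","),
               paste(g$controls, collapse = ","), sep = "|")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- 0:(2^n - 1)
  sel <- rep(TRUE, 2^n)
  for (cq in g$controls) sel <- sel & bitwAnd(idx, bitwShiftL(1L, cq)) > 0L
  if (g$kind == "SWAP") {
    b1 <- bitwShiftL(1L, g$targets[1]); b2 <- bitwShiftL(1L, g$targets[2])
    ia <- idx[sel & bitwAnd(idx, b1) > 0L & bitwAnd(idx, b2) == 0L]
    res <- list(i0 = ia + 1L, i1 = ia - b1 + b2 + 1L)
  } else {
    bt <- bitwShiftL(1L, g$targets[1])
    i0 <- idx[sel & bitwAnd(idx, bt) == 0L]
    res <- list(i0 = i0 + 1L, i1 = i0 + bt + 1L)
  }
  .idx_cache[[key]] <- res
  res
}

# In-place-style core shared by apply_gate and run_circuit; the 2x2 action is
# inlined per gate kind to avoid allocating gate matrices in hot loops.
apply_gate_amps <- function(amps, n, g) {
  ix <- gate_index_pairs(n, g)
  i0 <- ix$i0; i1 <- ix$i1
  kind <- g$kind
  if (kind == "SWAP" || kind == "X" || kind == "CNOT") {
    tmp <- amps[i0]
    amps[i0] <- amps[i1]
    amps[i1] <- tmp
  } else if (kind == "RY") {
    c2 <- cos(g$angle / 2); s2 <- sin(g$angle / 2)
    a0 <- amps[i0]; a1 <- amps[i1]
    amps[i0] <- c2 * a0 - s2 * a1
    amps[i1] <- s2 * a0 + c2 * a1
  } else if (kind == "H") {
    a0 <- amps[i0]; a1 <- amps[i1]
    amps[i0] <- (a0 + a1) * 0.7071067811865475
    amps[i1] <- (a0 - a1) * 0.7071067811865475
  } else if (kind == "RZ") {
    amps[i0] <- amps[i0] * exp(complex(imaginary = -g$angle / 2))
    amps[i1] <- amps[i1] * exp(complex(imaginary = g$angle / 2))
  } else if (kind == "Z") {
    amps[i1] <- -amps[i1]
  } else {
    stop("unknown gate kind ", kind)
  }
  amps
}

#' Apply a single gate to a statevector
#'
#' Returns the state after the (possibly multi-controlled) unitary; the input
#' state is unchanged.  Controlled gates act only on basis states whose
#' control bits are all 1.
#'
#' @param state a [state_vector()].
#' @param g a [gate()].
#' @return The new `state_vector`.
#' @export
apply_gate <- function(state, g) {
  n <- state$n_qubits
  if (max(c(g$targets, g$controls)) >= n) {
    stop("gate qubit index out of range for a ", n, "-qubit state")
  }
  structure(list(n_qubits = n,
                 amplitudes = apply_gate_amps(state$amplitudes, n, g)),
            class = "state_vector")
}

#' Run a circuit on an initial state
#'
#' @param circ a [circuit()].
#' @param initial a [state_vector()] on the same qubit count; defaults to
#'   `zero_state(circ$n_qubits)`.
#' @return The final `state_vector`.
#' @export
run_circuit <- function(circ, initial = zero_state(circ$n_qubits)) {
  if (circ$n_qubits != initial$n_qubits) {
    stop("circuit acts on ", circ$n_qubits, " qubits but state has ",
         initial$n_qubits)
  }
  n <- circ$n_qubits
  amps <- initial$amplitudes
  for (g in circ$gates) amps <- apply_gate_amps(amps, n, g)
  structure(list(n_qubits = n, amplitudes = amps), class = "state_vector")
}

#' Statevector prepared by a circuit from |0...0>
#'
#' Convenience wrapper: the complex amplitude vector of
#' `run_circuit(circ, zero_state(n))`.
#'
#' @inheritParams run_circuit
#' @return Complex vector of length `2^n_qubits`.
#' @export
statevector_of <- function(circ) run_circuit(circ)$amplitudes

#' Promote a circuit to a controlled circuit
#'
#' Every gate gains `control` as an additional control qubit, so the returned
#' circuit applies the original circuit when the control qubit is `|1>` and
#' acts as the identity when it is `|0>`.  The control must be a fresh qubit
#' not touched by the circuit; the qubit count grows to include it if needed.
#'
#' @param circ a [circuit()].
#' @param control index of the (fresh) control qubit.
#' @return A `qcircuit` on `max(circ$n_qubits, control + 1)` qubits.
#' @export
controlled_circuit <- function(circ, control) {
  control <- as.integer(control)
  used <- unique(unlist(lapply(circ$gates, function(g) c(g$targets, g$controls))))
  if (control %in% used) {
    stop("control qubit ", control, " collides with a qubit used by the circuit")
  }
  gates <- lapply(circ$gates, function(g) {
    gate(g$kind, g$targets, c(g$controls, control), g$angle)
  })
  circuit(max(circ$n_qubits, control + 1L), gates)
}

#' Relabel circuit qubits by a constant offset
#'
#' Shifts every target and control index by `offset`, growing the qubit
#' count; used to place encoding registers next to the ancilla (qubit 0) in
#' the overlap-test circuits.
#'
#' @param circ a [circuit()].
#' @param offset non-negative integer added to every qubit index.
#' @return A `qcircuit` on `circ$n_qubits + offset` qubits.
#' @export
shift_circuit <- function(circ, offset) {
  offset <- as.integer(offset)
  if (offset < 0) stop("offset must be >= 0")
  gates <- lapply(circ$gates, function(g) {
    gate(g$kind, g$targets + offset, g$controls + offset, g$angle)
  })
  circuit(circ$n_qubits + offset, gates)
}

# ---- measurement ------------------------------------------------------------

#' Marginal probability of a single-qubit outcome
#'
#' Sum of squared amplitude moduli over the basis states whose bit at `qubit`
#' equals `outcome`; `Pr(0) + Pr(1) = 1`.
#'
#' @param state a [state_vector()].
#' @param qubit qubit index to measure.
#' @param outcome 0 or 1.
#' @return Probability in `[0, 1]`.
#' @export
marginal_probability <- function(state, qubit, outcome) {
  n <- state$n_qubits
  qubit <- as.integer(qubit)
  if (qubit < 0 || qubit >= n) stop("qubit index out of range")
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1")
  key <- paste0("m", n, "|", qubit)
  bit <- .idx_cache[[key]]
  if (is.null(bit)) {
    bit <- bitwAnd(0:(2^n - 1), bitwShiftL(1L, qubit)) > 0L
    .idx_cache[[key]] <- bit
  }
  keep <- if (outcome == 1) bit else !bit
  sum(Mod(state$amplitudes[keep])^2)
}

# Evaluate expr under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched (no global state).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample measurement counts on one qubit
#'
#' Draws `count0 ~ Binomial(shots, Pr(0))` for the marginal distribution of
#' `qubit`, reproducibly under `seed`.  Each call seeds a private RNG stream;
#' the caller's RNG state is untouched.
#'
#' @param state a [state_vector()].
#' @param qubit qubit index to measure.
#' @param shots number of repeated measurements (>= 1).
#' @param seed integer seed for this sampling call.
#' @return An object of class `measurement_counts` with fields `qubit`,
#'   `shots`, `count0`, `count1`.
#' @export
sample_counts <- function(state, qubit, shots, seed) {
  shots <- as.integer(shots)
  if (is.na(shots) || shots < 1) stop("shots must be >= 1")
  p0 <- marginal_probability(state, qubit, 0)
  count0 <- with_local_seed(seed, stats::rbinom(1, shots, p0))
  structure(list(qubit = as.integer(qubit), shots = shots,
                 count0 = as.integer(count0),
                 count1 = shots - as.integer(count0)),
            class = "measurement_counts")
}
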