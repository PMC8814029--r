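# Data-encoding circuits.
#
# Two feature maps are provided:
#  * log2(N) amplitude encoding: an l2-normalised (zero-padded) feature vector
#    becomes the amplitudes of a ceil(log2 N)-qubit state, prepared by a
#    hierarchical tree of Ry rotations expanded into Ry + CNOT sequences.
#  * N-qubit encoding: H on every qubit, feature values as Rz angles, then a
#    forward chain of nearest-neighbour CNOTs.

#' Normalise and zero-pad a feature vector
#'
#' Pads `x` with zeros at the tail to the next power of two, then divides by
#' the l2 norm, producing a unit amplitude vector ready for amplitude
#' encoding.
#'
#' @param x numeric feature vector with at least one nonzero entry.
#' @return Unit-norm numeric vector whose length is a power of two.
#' @examples
#' normalize_and_pad(c(3, 4))      # 0.6 0.8
#' normalize_and_pad(c(1, 2, 3))   # padded to length 4
#' @export
normalize_and_pad <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("empty feature vector")
  if (!all(is.finite(x))) stop("feature vector has non-finite entries")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("all-zero feature vector cannot be amplitude-encoded")
  n <- max(1L, ceiling(log2(length(x))))
  padded <- c(x, numeric(2^n - length(x)))
  padded / nrm
}

#' Hierarchical rotation angles for amplitude encoding
#'
#' Divide-and-conquer extraction of the Ry angle tree: level `k` holds `2^k`
#' angles, one per contiguous block of the amplitude vector at that depth.
#' For an internal split the angle satisfies `cos(theta) = |left block| /
#' |parent block|`; at the leaf level the signed amplitudes themselves are
#' used, so any pattern of signs is reproduced exactly (`atan2` covers the
#' full circle).  Zero-norm blocks get angle 0, which is unobservable.
#'
#' @param u unit-norm numeric vector whose length is a power of two.
#' @return An object of class `angle_tree`: list with `n_qubits` and
#'   `levels`, a list of numeric angle vectors (level k has `2^k` entries);
#'   `2^n - 1` angles in total.
#' @export
ry_tree_angles <- function(u) {
  u <- as.numeric(u)
  len <- length(u)
  n <- round(log2(len))
  if (len < 2 || 2^n != len) stop("length must be a power of two (>= 2)")
  if (abs(sum(u^2) - 1) > 1e-8) stop("input must have unit l2 norm")

  # blocks[[k + 1]]: 2^k block values at depth k; signed at the leaves,
  # nonnegative norms above.
  blocks <- vector("list", n + 1)
  blocks[[n + 1]] <- u
  for (k in n:1) {
    child <- blocks[[k + 1]]
    blocks[[k]] <- sqrt(child[c(TRUE, FALSE)]^2 + child[c(FALSE, TRUE)]^2)
  }

  levels <- vector("list", n)
  for (k in 1:n) {
    child <- blocks[[k + 1]]
    l <- child[c(TRUE, FALSE)]
    r <- child[c(FALSE, TRUE)]
    theta <- ifelse(l == 0 & r == 0, 0, atan2(r, l))
    levels[[k]] <- theta
  }
  structure(list(n_qubits = as.integer(n), levels = levels),
            class = "angle_tree")
}

#' @export
print.angle_tree <- function(x, ...) {
  cat("<angle_tree> depth ", x$n_qubits, " (",
      sum(lengths(x$levels)), " angles)\n", sep = "")
  invisible(x)
}

# Gray code of i (0-based).
gray_code <- function(i) bitwXor(i, bitwShiftR(i, 1L))

# Parity of popcount(bitwAnd(a, b)) as +1 / -1.
parity_sign <- function(a, b) {
  x <- bitwAnd(a, b)
  p <- 0L
  while (any(x > 0L)) {
    p <- bitwXor(p, bitwAnd(x, 1L))
    x <- bitwShiftR(x, 1L)
  }
  1 - 2 * p
}

# Uniformly-controlled RY: apply RY(theta[j + 1]) on `target` when the control
# qubits `ctrls` hold the bit pattern j (ctrls[m + 1] carries bit m of j).
# Emitted as the standard Gray-code ladder of plain RY gates interleaved with
# CNOTs, so the output circuit uses only the Ry/CNOT vocabulary.
ucry_gates <- function(target, ctrls, theta) {
  k <- length(ctrls)
  if (k == 0) return(list(gate_ry(target, theta[1])))
  m <- 2^k
  phi <- numeric(m)
  for (i in 0:(m - 1)) {
    g <- gray_code(i)
    s <- vapply(0:(m - 1), function(j) parity_sign(g, j), numeric(1))
    phi[i + 1] <- sum(s * theta) / m
  }
  gates <- vector("list", 2 * m)
  for (i in 0:(m - 1)) {
    g_cur <- gray_code(i)
    g_nxt <- gray_code((i + 1) %% m)
    changed <- round(log2(bitwXor(g_cur, g_nxt)))
    gates[[2 * i + 1]] <- gate_ry(target, phi[i + 1])
    gates[[2 * i + 2]] <- gate_cnot(ctrls[changed + 1], target)
  }
  gates
}

#' Build the log2(N) amplitude-encoding circuit
#'
#' Turns an [ry_tree_angles()] tree into a state-preparation circuit on
#' `n = depth` qubits, using only `RY` and `CNOT` gates (each level of the
#' tree becomes a uniformly-controlled rotation expanded by the Gray-code
#' ladder).  Running it on `|0...0>` reproduces the encoded amplitudes.
#'
#' Level k targets qubit `n - 1 - k` (qubit `n - 1` carries the most
#' significant bit of the amplitude index), controlled on the k more
#' significant qubits.  The doubled angle convention `RY(2*theta)` realises
#' `cos(theta)|0> + sin(theta)|1>` per split.
#'
#' @param tree an `angle_tree`.
#' @return A [circuit()] on `tree$n_qubits` qubits.
#' @export
build_log2n_circuit <- function(tree) {
  if (!inherits(tree, "angle_tree")) stop("malformed angle tree")
  n <- tree$n_qubits
  if (length(tree$levels) != n ||
      !all(lengths(tree$levels) == 2^(seq_len(n) - 1))) {
    stop("malformed angle tree: level k must hold 2^k angles")
  }
  gates <- list()
  for (k in 0:(n - 1)) {
    theta <- 2 * tree$levels[[k + 1]]
    target <- n - 1L - k
    if (k == 0) {
      gates <- c(gates, list(gate_ry(target, theta[1])))
    } else {
      # pattern bit m of the level index lives on qubit n - k + m
      ctrls <- (n - k):(n - 1L)
      gates <- c(gates, ucry_gates(target, ctrls, theta))
    }
  }
  circuit(n, gates)
}

#' Amplitude-encode a feature vector in one step
#'
#' Convenience composition of [normalize_and_pad()], [ry_tree_angles()] and
#' [build_log2n_circuit()]: N features end up on `ceil(log2 N)` qubits.
#'
#' @param x numeric feature vector.
#' @return A [circuit()] preparing the normalised, padded vector from
#'   `|0...0>`.
#' @export
encode_log2n <- function(x) {
  build_log2n_circuit(ry_tree_angles(normalize_and_pad(x)))
}

#' Build the N-qubit H/Rz/CNOT encoding circuit
#'
#' One qubit per feature: a Hadamard on every qubit, the feature values as
#' `Rz` rotation angles (qubit i gets feature i), then a single forward pass
#' of nearest-neighbour CNOTs (`i -> i+1`).
#'
#' Feature scaling: raw feature values make poor phase angles (unbounded, or
#' nearly constant), so by default each value is min-max scaled to `[0, pi]`.
#' Pass a `ranges` matrix (2 x N: per-feature min and max, computed on a
#' training set) so that train and test samples share one scaling; with
#' `ranges = NULL` the vector's own range is used.  `scale = FALSE` uses the
#' raw values.
#'
#' @param x numeric feature vector of length N >= 1.
#' @param scale logical; min-max scale the angles to `[0, pi]`?
#' @param ranges optional 2 x N matrix, rows = per-feature min and max.
#' @return A [circuit()] on N qubits.
#' @export
build_n_qubit_circuit <- function(x, scale = TRUE, ranges = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1) stop("empty feature vector")
  angles <- x
  if (scale) {
    if (is.null(ranges)) {
      lo <- rep(min(x), n); hi <- rep(max(x), n)
    } else {
      if (!is.matrix(ranges) || nrow(ranges) != 2 || ncol(ranges) != n) {
        stop("ranges must be a 2 x N matrix (min row, max row)")
      }
      lo <- ranges[1, ]; hi <- ranges[2, ]
    }
    span <- hi - lo
    angles <- ifelse(span > 0, (x - lo) / span, 0.5) * pi
    angles <- pmin(pmax(angles, 0), pi)  # clamp test values outside ranges
  }
  gates <- lapply(0:(n - 1), gate_h)
  gates <- c(gates, lapply(0:(n - 1), function(i) gate_rz(i, angles[i + 1])))
  if (n >= 2) {
    gates <- c(gates, lapply(0:(n - 2), function(i) gate_cnot(i, i + 1)))
  }
  circuit(n, gates)
}

#' Encoder factories
#'
#' Returns a function `x -> qcircuit` for the chosen encoding, with scaling
#' state baked in for the N-qubit map.
#'
#' @param encoding `"log2n"` or `"nqubit"`.
#' @param ranges optional 2 x N matrix of training-set feature ranges
#'   (N-qubit encoding only).
#' @param scale logical, N-qubit encoding only.
#' @return A single-argument function producing an encoding circuit.
#' @export
make_encoder <- function(encoding = c("log2n", "nqubit"), ranges = NULL,
                         scale = TRUE) {
  encoding <- match.arg(encoding)
  if (encoding == "log2n") {
    encode_log2n
  } else {
    function(x) build_n_qubit_circuit(x, scale = scale, ranges = ranges)
  }
}
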