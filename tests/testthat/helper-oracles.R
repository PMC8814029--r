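# Independent oracles used across the suite.  Everything here is built from
# first principles (kronecker algebra, explicit enumeration, generic
# optimisation) and never calls into the package's own simulation path.

# ---- dense-matrix circuit oracle -------------------------------------------
# Full 2^n x 2^n unitary of a gate via kronecker products.  Qubit q is the
# q-th bit of the basis index (LSB = qubit 0), so the kron chain runs from
# qubit n-1 (leftmost factor) down to qubit 0.

oracle_lift <- function(n, ops) {
  # ops: named list qubit -> 2x2 matrix; identity elsewhere
  M <- matrix(1, 1, 1)
  for (q in (n - 1):0) {
    op <- ops[[as.character(q)]]
    if (is.null(op)) op <- diag(2)
    M <- M %x% op
  }
  M
}

oracle_single_gate_matrix <- function(n, u2, target, controls = integer(0)) {
  if (!length(controls)) return(oracle_lift(n, stats::setNames(list(u2), target)))
  P1 <- matrix(c(0, 0, 0, 1), 2, 2)
  ops_p <- stats::setNames(rep(list(P1), length(controls)),
                           as.character(controls))
  P_ctrl <- oracle_lift(n, ops_p)
  ops_u <- c(ops_p, stats::setNames(list(u2), as.character(target)))
  diag(2^n) - P_ctrl + oracle_lift(n, ops_u)
}

oracle_gate_matrix <- function(n, g) {
  mats <- list(
    RY = function(a) matrix(c(cos(a / 2), sin(a / 2), -sin(a / 2), cos(a / 2)), 2, 2),
    RZ = function(a) diag(c(exp(-1i * a / 2), exp(1i * a / 2))),
    H  = function(a) matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X  = function(a) matrix(c(0, 1, 1, 0), 2, 2),
    Z  = function(a) diag(c(1, -1))
  )
  if (g$kind == "SWAP") {
    # (controlled-)SWAP(a,b) = product of three (controlled-)CNOTs
    a <- g$targets[1]; b <- g$targets[2]
    X2 <- mats$X(0)
    m1 <- oracle_single_gate_matrix(n, X2, b, c(a, g$controls))
    m2 <- oracle_single_gate_matrix(n, X2, a, c(b, g$controls))
    return(m1 %*% m2 %*% m1)
  }
  u2 <- if (g$kind == "CNOT") mats$X(0) else mats[[g$kind]](g$angle)
  oracle_single_gate_matrix(n, u2, g$targets[1], g$controls)
}

oracle_run_circuit <- function(circ, initial_amps) {
  v <- as.complex(initial_amps)
  for (g in circ$gates) v <- oracle_gate_matrix(circ$n_qubits, g) %*% v
  as.vector(v)
}

# ---- random objects ---------------------------------------------------------

random_unit <- function(len) {
  u <- stats::rnorm(len)
  u / sqrt(sum(u^2))
}

random_gate <- function(n) {
  kind <- sample(c("RY", "RZ", "H", "X", "Z", "CNOT", "SWAP"), 1)
  qs <- sample(0:(n - 1))
  switch(kind,
    RY = gate_ry(qs[1], stats::runif(1, -pi, pi)),
    RZ = gate_rz(qs[1], stats::runif(1, -pi, pi)),
    H  = gate_h(qs[1]),
    X  = gate_x(qs[1]),
    Z  = gate_z(qs[1]),
    CNOT = gate_cnot(qs[1], qs[2]),
    SWAP = if (n >= 3 && stats::runif(1) < 0.3) {
      gate_swap(qs[1], qs[2], controls = qs[3])   # exercise controlled swaps
    } else gate_swap(qs[1], qs[2])
  )
}

random_circuit <- function(n, n_gates) {
  circuit(n, lapply(seq_len(n_gates), function(i) random_gate(n)))
}

# ---- classical classifier oracles ------------------------------------------

# qDC by explicit dot products on normalised padded vectors.
oracle_qdc <- function(Xtr, labels, x_test, class_a) {
  enc <- function(x) normalize_and_pad(x)
  d <- apply(Xtr, 1, function(r) 1 - sum(enc(r) * enc(x_test)))
  minP <- min(d[labels == class_a])
  minQ <- min(d[labels != class_a])
  if (minP <= minQ) class_a else setdiff(unique(labels), class_a)
}

# sqKSVM by direct arithmetic.
oracle_sqksvm <- function(y, alpha, krow) {
  s <- sum(y * alpha * krow)
  if (s >= 0) 1L else -1L
}

# ---- ROC-integration AUC oracle --------------------------------------------

oracle_auc_trapezoid <- function(scores, y01) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y01 == 1] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y01 == 0] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# ---- SVM dual oracle (augmented Lagrangian + L-BFGS-B) ----------------------

oracle_svm_dual <- function(K, y, C = 1) {
  M <- length(y)
  Q <- (y %o% y) * K
  mu <- 10; nu <- 0
  alpha <- rep(C / 2, M)
  for (outer in 1:60) {
    obj <- function(a) {
      e <- sum(y * a)
      0.5 * sum(a * (Q %*% a)) - sum(a) + nu * e + 0.5 * mu * e^2
    }
    gr <- function(a) {
      e <- sum(y * a)
      as.vector(Q %*% a) - 1 + nu * y + mu * e * y
    }
    opt <- stats::optim(alpha, obj, gr, method = "L-BFGS-B",
                        lower = 0, upper = C,
                        control = list(maxit = 500, factr = 1e1))
    alpha <- opt$par
    e <- sum(y * alpha)
    nu <- nu + mu * e
    if (abs(e) < 1e-12) break
    mu <- min(mu * 2, 1e8)
  }
  grad <- as.vector(Q %*% alpha) - 1
  free <- alpha > 1e-6 & alpha < C - 1e-6
  b <- if (any(free)) mean(-y[free] * grad[free]) else {
    up <- (y == 1 & alpha < C - 1e-9) | (y == -1 & alpha > 1e-9)
    lo <- (y == -1 & alpha < C - 1e-9) | (y == 1 & alpha > 1e-9)
    (max(-(y * grad)[up]) + min(-(y * grad)[lo])) / 2
  }
  list(alpha = alpha, b = b)
}
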