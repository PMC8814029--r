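test_that("single gates act as expected on computational basis states", {
  # X flips |0> -> |1>
  s <- apply_gate(zero_state(1), gate_x(0))
  expect_equal(s$amplitudes, as.complex(c(0, 1)))

  # RY(2*theta)|0> = cos(theta)|0> + sin(theta)|1> at theta = pi/4
  s <- apply_gate(zero_state(1), gate_ry(0, 2 * (pi / 4)))
  expect_equal(Re(s$amplitudes), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)

  # CNOT(0 -> 1) completes the Bell state from (|00> + |10>)/sqrt(2)
  plus <- apply_gate(zero_state(2), gate_h(0))
  bell <- apply_gate(plus, gate_cnot(0, 1))
  expect_equal(bell$amplitudes,
               as.complex(c(1, 0, 0, 1) / sqrt(2)), tolerance = 1e-12)
})

test_that("run_circuit composes gates in order and handles the empty circuit", {
  st <- zero_state(2)
  expect_equal(run_circuit(circuit(2), st)$amplitudes, st$amplitudes)

  bell <- run_circuit(circuit(2, list(gate_h(0), gate_cnot(0, 1))))
  expect_equal(bell$amplitudes, as.complex(c(1, 0, 0, 1) / sqrt(2)),
               tolerance = 1e-12)

  expect_error(run_circuit(circuit(3), zero_state(2)), "qubits")
})

test_that("run_circuit agrees with the kronecker-product matrix oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    circ <- random_circuit(n, 20)
    init <- as.complex(random_unit(2^n))
    got <- run_circuit(circ, state_vector(init, n))$amplitudes
    want <- oracle_run_circuit(circ, init)
    expect_lt(max(Mod(got - want)), 1e-10)
  }
})

test_that("unitarity: random circuits preserve the norm", {
  set.seed(202)
  worst <- 0
  for (rep in 1:200) {
    n <- sample(2:4, 1)
    circ <- random_circuit(n, sample(1:30, 1))
    out <- run_circuit(circ, state_vector(as.complex(random_unit(2^n)), n))
    worst <- max(worst, abs(sum(Mod(out$amplitudes)^2) - 1))
  }
  expect_lt(worst, 1e-10)
})

test_that("controlled_circuit promotes every gate and respects the control", {
  # controlled empty circuit stays empty
  expect_length(controlled_circuit(circuit(2), 2)$gates, 0)

  # controlled(X on q1): fires iff control is |1>
  cx <- controlled_circuit(circuit(2, list(gate_x(1))), 2)
  on <- state_vector(as.complex(c(0, 0, 0, 0, 1, 0, 0, 0)), 3)  # |100>: q2=1
  res <- run_circuit(cx, on)
  expect_equal(which(Mod(res$amplitudes) > 0.5), 7L)  # |110>: q2=1, q1=1
  off <- run_circuit(cx, zero_state(3))
  expect_equal(which(Mod(off$amplitudes) > 0.5), 1L)

  # block-diagonal action diag(I, U) on a superposed control, against the
  # statevector oracle
  set.seed(303)
  u <- random_unit(4)
  enc <- encode_log2n(u)
  cU <- controlled_circuit(shift_circuit(enc, 1L), 0L)
  full <- circuit(3, c(list(gate_h(0)), cU$gates))
  got <- run_circuit(full)$amplitudes
  want <- numeric(8)
  want[1] <- 1 / sqrt(2)                      # |0>_c |00>
  want[seq(2, 8, by = 2)] <- u / sqrt(2)      # |1>_c |u>, ancilla is bit 0
  expect_lt(max(Mod(got - as.complex(want))), 1e-10)

  expect_error(controlled_circuit(circuit(2, list(gate_x(1))), 1), "collides")
})

test_that("marginal_probability sums the right amplitudes", {
  expect_equal(marginal_probability(zero_state(1), 0, 0), 1)

  bell <- run_circuit(circuit(2, list(gate_h(0), gate_cnot(0, 1))))
  expect_equal(marginal_probability(bell, 1, 0), 0.5, tolerance = 1e-12)

  set.seed(404)
  for (rep in 1:20) {
    amps <- as.complex(random_unit(8)) * exp(1i * stats::runif(8, 0, 2 * pi))
    amps <- amps / sqrt(sum(Mod(amps)^2))
    st <- state_vector(amps, 3)
    for (q in 0:2) {
      brute <- sum(Mod(amps[bitwAnd(0:7, 2^q) > 0])^2)
      expect_equal(marginal_probability(st, q, 1), brute, tolerance = 1e-12)
      expect_equal(marginal_probability(st, q, 0) + marginal_probability(st, q, 1),
                   1, tolerance = 1e-12)
    }
  }
  expect_error(marginal_probability(zero_state(2), 2, 0), "range")
})

test_that("sample_counts is binomial, deterministic under seed, and validates", {
  st <- zero_state(1)
  c1 <- sample_counts(st, 0, 100, seed = 5)
  expect_equal(c1$count0, 100L)
  expect_equal(c1$count0 + c1$count1, c1$shots)

  plus <- apply_gate(zero_state(1), gate_h(0))
  a <- sample_counts(plus, 0, 8192, seed = 7)
  b <- sample_counts(plus, 0, 8192, seed = 7)
  expect_identical(a$count0, b$count0)

  # 3-sigma binomial band around 4096 (99.7% per trial; a fixed seed is used)
  expect_lt(abs(a$count0 - 4096), 3 * sqrt(8192 * 0.25) + 1)

  expect_error(sample_counts(st, 0, 0, seed = 1), "shots")
})

test_that("sampling frequency converges at the binomial rate", {
  st <- apply_gate(zero_state(1), gate_ry(0, 2 * 0.6))
  p0 <- cos(0.6)^2
  for (shots in c(128, 8192, 1e6)) {
    cnt <- sample_counts(st, 0, shots, seed = 11)
    se <- sqrt(p0 * (1 - p0) / shots)
    expect_lt(abs(cnt$count0 / shots - p0), 4 * se)
  }
})

test_that("state and gate constructors validate their invariants", {
  expect_error(state_vector(c(1, 1)), "normalised")
  expect_error(state_vector(c(1, 0, 0)), "length")
  expect_error(gate("H", 0, angle = 1), "non-rotation")
  expect_error(gate("RY", 0), "angle")
  expect_error(gate("X", 0, controls = 0), "disjoint")
  expect_error(circuit(1, list(gate_x(1))), "qubit")
})
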