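test_that("Hadamard test recovers Re<u|v> exactly", {
  set.seed(601)
  u <- random_unit(8)
  Uc <- encode_log2n(u)
  expect_equal(hadamard_test(Uc, Uc)$value, 1, tolerance = 1e-10)

  # orthogonal states
  e1 <- encode_log2n(c(1, 0)); e2 <- encode_log2n(c(0, 1))
  expect_equal(hadamard_test(e1, e2)$value, 0, tolerance = 1e-10)

  for (rep in 1:60) {
    u <- random_unit(8); v <- random_unit(8)
    got <- hadamard_test(encode_log2n(u), encode_log2n(v))$value
    expect_equal(got, sum(u * v), tolerance = 1e-10)
  }

  expect_error(hadamard_test(encode_log2n(1:4), encode_log2n(1:8)), "qubits")
})

test_that("Swap test recovers |<u|v>|^2 exactly and Pr(0) >= 1/2", {
  set.seed(602)
  u <- random_unit(4)
  Uc <- encode_log2n(u)
  expect_equal(swap_test(Uc, Uc)$value, 1, tolerance = 1e-10)
  expect_equal(swap_test(encode_log2n(c(1, 0)), encode_log2n(c(0, 1)))$value,
               0, tolerance = 1e-10)

  for (rep in 1:40) {
    u <- random_unit(8); v <- random_unit(8)
    Uc <- encode_log2n(u); Vc <- encode_log2n(v)
    expect_equal(swap_test(Uc, Vc)$value, sum(u * v)^2, tolerance = 1e-10)
    # the assembled circuit's ancilla never dips below Pr(0) = 1/2
    p0 <- marginal_probability(
      run_circuit(nisqclass:::swap_test_circuit(Uc, Vc)), 0, 0)
    expect_gte(p0, 0.5 - 1e-12)
  }
})

test_that("ancilla probabilities carry the overlap in the documented form", {
  set.seed(603)
  for (rep in 1:20) {
    u <- random_unit(8); v <- random_unit(8)
    Uc <- encode_log2n(u); Vc <- encode_log2n(v)
    ph <- marginal_probability(
      run_circuit(nisqclass:::hadamard_test_circuit(Uc, Vc)), 0, 0)
    expect_equal(ph, (1 + sum(u * v)) / 2, tolerance = 1e-10)
    ps <- marginal_probability(
      run_circuit(nisqclass:::swap_test_circuit(Uc, Vc)), 0, 0)
    expect_equal(ps, (1 + sum(u * v)^2) / 2, tolerance = 1e-10)
  }
})

test_that("shot-mode estimates concentrate around the exact value", {
  set.seed(604)
  u <- random_unit(8); v <- random_unit(8)
  Uc <- encode_log2n(u); Vc <- encode_log2n(v)
  exact <- hadamard_test(Uc, Vc)$value
  p <- (1 + exact) / 2
  hits <- 0
  for (s in 1:200) {
    est <- hadamard_test(Uc, Vc, mode = "shots", shots = 8192, seed = s)$value
    if (abs(est - exact) <= 3 * 2 * sqrt(p * (1 - p) / 8192)) hits <- hits + 1
  }
  expect_gte(hits, 194)  # ~99.7% expected within 3 sigma

  # determinism under a fixed seed
  a <- swap_test(Uc, Vc, mode = "shots", shots = 1024, seed = 9)$value
  b <- swap_test(Uc, Vc, mode = "shots", shots = 1024, seed = 9)$value
  expect_identical(a, b)

  # standard error scales roughly as 1/sqrt(shots)
  sds <- vapply(c(2^7, 2^13, 2^20), function(sh) {
    stats::sd(vapply(1:60, function(s) {
      hadamard_test(Uc, Vc, mode = "shots", shots = sh, seed = s)$value
    }, numeric(1)))
  }, numeric(1))
  expect_gt(sds[1] / sds[2], 4)   # sqrt(8192/128) = 8, generous band
  expect_gt(sds[2] / sds[3], 4)   # sqrt(2^20/2^13) ~ 11.3
})

test_that("swap-mode clipping keeps shot estimates inside [0, 1]", {
  set.seed(605)
  u <- random_unit(4); v <- c(u[-1], -u[1])          # near-orthogonal pair
  v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))   # exactly orthogonal
  Uc <- encode_log2n(u); Vc <- encode_log2n(v)
  vals <- vapply(1:100, function(s) {
    swap_test(Uc, Vc, mode = "shots", shots = 64, seed = s)$value
  }, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("kernel_matrix matches the squared Gram matrix and both paths agree", {
  set.seed(606)
  X <- matrix(rnorm(5 * 4) + 3, 5, 4)
  rownames(X) <- paste0("s", 1:5)

  K <- kernel_matrix(X, X)
  U <- t(apply(X, 1, normalize_and_pad))
  G2 <- (U %*% t(U))^2
  expect_equal(unname(K), unname(G2), tolerance = 1e-10)
  expect_equal(K, t(K))
  expect_true(all(diag(K) == 1))
  expect_equal(rownames(K), rownames(X))

  # single sample
  K1 <- kernel_matrix(X[1, , drop = FALSE], X[1, , drop = FALSE])
  expect_equal(unname(K1), matrix(1), tolerance = 1e-12)

  # swap and squared-hadamard routes coincide for real data
  Y <- matrix(rnorm(3 * 4) + 3, 3, 4)
  Ks <- kernel_matrix(X, Y, method = "swap")
  Kh <- kernel_matrix(X, Y, method = "hadamard2")
  expect_equal(Ks, Kh, tolerance = 1e-10)

  expect_error(kernel_matrix(X, matrix(0, 2, 3)), "feature count")
})

test_that("exact kernels are PSD (squared Gram structure)", {
  set.seed(607)
  for (rep in 1:5) {
    X <- matrix(rnorm(6 * 4) + 2, 6, 4)
    K <- kernel_matrix(X, X)
    ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("kernel CSV export round-trips", {
  X <- matrix(c(1, 2, 3, 4), 2, 2) + 2
  rownames(X) <- c("a", "b")
  K <- kernel_matrix(X, X)
  f <- tempfile(fileext = ".csv")
  write_kernel_csv(K, f)
  back <- as.matrix(utils::read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(K), tolerance = 1e-12)
  unlink(f)
})
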