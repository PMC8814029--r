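test_that("quantum_distance follows the 1 - <u|v> rule", {
  u <- random_unit(4)
  Uc <- encode_log2n(u)
  expect_equal(quantum_distance(Uc, Uc), 0, tolerance = 1e-10)

  e1 <- encode_log2n(c(1, 0)); e2 <- encode_log2n(c(0, 1))
  expect_equal(quantum_distance(e1, e2), 1, tolerance = 1e-10)

  # antipodal states: distance 2
  Um <- build_log2n_circuit(ry_tree_angles(-u))
  expect_equal(quantum_distance(Uc, Um), 2, tolerance = 1e-10)
})

test_that("qdc assigns the nearest-set label, ties to set P", {
  train <- labeled_dataset(rbind(c(1, 0), c(0, 1)), c("a", "b"))
  # test point equal to a training point of class a
  pred <- qdc_classify(train, c(1, 0))
  expect_equal(pred$label, "a")
  expect_gt(pred$score, 0)

  # exact tie: equidistant point resolves to the P-set (class_a) label
  tie <- qdc_classify(train, c(1, 1))
  expect_equal(tie$label, "a")
  expect_equal(tie$score, 0, tolerance = 1e-10)

  # class_a override flips the tie
  tie_b <- qdc_classify(train, c(1, 1), class_a = "b")
  expect_equal(tie_b$label, "b")

  expect_error(qdc_classify(labeled_dataset(diag(2), c("a", "a")), c(1, 0)),
               "two classes")
})

test_that("qdc matches the classical brute-force oracle on random problems", {
  set.seed(701)
  for (rep in 1:25) {
    M <- sample(6:10, 1)
    Xtr <- matrix(rnorm(M * 4) + 3, M, 4)
    labels <- c("a", "b", sample(c("a", "b"), M - 2, replace = TRUE))
    xte <- rnorm(4) + 3
    train <- labeled_dataset(Xtr, labels)
    got <- qdc_classify(train, xte, class_a = "a")$label
    expect_equal(got, oracle_qdc(Xtr, labels, xte, "a"))
  }
})

test_that("qdc is invariant to duplicating a training sample", {
  set.seed(702)
  Xtr <- matrix(rnorm(8 * 4) + 3, 8, 4)
  labels <- rep(c("a", "b"), 4)
  xte <- matrix(rnorm(3 * 4) + 3, 3, 4)
  base <- qdc_classify(labeled_dataset(Xtr, labels), xte, class_a = "a")
  dup <- qdc_classify(labeled_dataset(rbind(Xtr, Xtr[1, ]), c(labels, "a")),
                      xte, class_a = "a")
  expect_equal(base$score, dup$score, tolerance = 1e-10)
  expect_equal(base$label, dup$label)
})

test_that("sqksvm_alpha implements the imbalance-ratio weighting", {
  expect_equal(sqksvm_alpha(rep(c("x", "y"), 5)), rep(1, 10))
  expect_equal(sqksvm_alpha(c("p", "p", "p", "n")), c(0.25, 0.25, 0.25, 0.75))

  # IR = 0.37 puts 0.37 on the majority and 0.63 on the minority
  labs <- c(rep("maj", 63), rep("min", 37))
  a <- sqksvm_alpha(labs, IR = 0.37)
  expect_equal(unique(a[labs == "maj"]), 0.37)
  expect_equal(unique(a[labs == "min"]), 0.63)

  expect_error(sqksvm_alpha(rep("p", 4)), "two classes")
  expect_error(sqksvm_alpha(c("p", "n"), IR = 0.7), "IR")
})

test_that("sqksvm_classify thresholds the weighted kernel vote at zero", {
  # all labels +1 and a nonzero kernel row: positive
  expect_equal(sqksvm_classify(rep(1, 3), rep(1, 3), c(0.2, 0.1, 0.4))$label, 1L)

  # score exactly 0 maps to +1
  z <- sqksvm_classify(c(1, -1), c(1, 1), c(0.3, 0.3))
  expect_equal(z$score, 0)
  expect_equal(z$label, 1L)

  # brute-force agreement and label antisymmetry
  set.seed(703)
  for (rep in 1:50) {
    M <- sample(4:12, 1)
    y <- c(1, -1, sample(c(-1, 1), M - 2, replace = TRUE))
    labs <- ifelse(y == 1, "p", "n")
    alpha <- sqksvm_alpha(labs)
    krow <- runif(M)
    got <- sqksvm_classify(y, alpha, krow)
    expect_equal(got$label, oracle_sqksvm(y, alpha, krow))
    flipped <- sqksvm_classify(-y, alpha, krow)
    expect_equal(flipped$score, -got$score, tolerance = 1e-12)
  }
  expect_error(sqksvm_classify(c(1, -1), c(1, 1), c(1, 2, 3)), "training size")
})

test_that("reference SVM separates a trivial problem and is deterministic", {
  X <- matrix(c(-2, -1.5, 1.5, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  K <- X %*% t(X) + 1
  fit <- qksvm_reference_fit(K, y)
  pred <- qksvm_decision(fit, K)
  expect_equal(pred$label, y)

  fit2 <- qksvm_reference_fit(K, y)
  expect_identical(fit$alpha, fit2$alpha)
  expect_identical(fit$b, fit2$b)
})

test_that("reference SVM agrees with an independent QP solve of the dual", {
  set.seed(704)
  d <- generate_two_class(40, 6, separation = 2, seed = 41)
  y <- as.numeric(label_signs(d$labels))
  U <- t(apply(d$features, 1, normalize_and_pad))
  K <- (U %*% t(U))^2
  fit <- qksvm_reference_fit(K, y, C = 1, tol = 1e-10)
  ora <- oracle_svm_dual(K, y, C = 1)
  dec_fit <- as.vector(K %*% (fit$alpha * y)) + fit$b
  dec_ora <- as.vector(K %*% (ora$alpha * y)) + ora$b
  expect_lt(max(abs(dec_fit - dec_ora)), 1e-6)
})

test_that("reference SVM repairs non-PSD kernels with a warning", {
  K <- diag(3); K[1, 3] <- K[3, 1] <- 2  # indefinite
  expect_warning(qksvm_reference_fit(K, c(1, -1, 1)), "PSD")
})

test_that("balanced sqksvm is invariant to which class is called majority", {
  set.seed(705)
  d <- generate_two_class(20, 4, separation = 2, IR = 0.5, seed = 11)
  K <- kernel_matrix(d$features, d$features)
  y <- as.numeric(label_signs(d$labels, positive = "pos"))
  a <- sqksvm_alpha(d$labels)
  s1 <- sqksvm_classify(y, a, K)$score
  # relabel: swap which class maps to +1; scores must only change sign
  s2 <- sqksvm_classify(-y, a, K)$score
  expect_equal(s2, -s1, tolerance = 1e-12)
})
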