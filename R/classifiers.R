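# Classifiers: quantum distance classifier (qDC), simplified quantum-kernel
# SVM (sqKSVM) with fixed imbalance-ratio weights, and a reference kernel SVM
# trained by SMO on a precomputed quantum kernel.

#' Construct a labelled two-class dataset
#'
#' @param features numeric M x N matrix, rows = samples.
#' @param labels length-M vector with exactly two distinct values (any type;
#'   coerced to character).
#' @param feature_names optional column names.
#' @return An object of class `labeled_dataset` with fields `features`,
#'   `labels`, `feature_names`.
#' @export
labeled_dataset <- function(features, labels, feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree on the sample count")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("<labeled_dataset> ", nrow(x$features), " samples x ",
      ncol(x$features), " features; classes: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_two_classes <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2) {
    stop("need exactly two classes, got: ", paste(u, collapse = ", "))
  }
  u
}

#' Map two-class labels to -1/+1
#'
#' By default the minority class maps to +1 (ties: the first label seen is
#' +1); override with `positive`.
#'
#' @param labels two-class label vector.
#' @param positive optional label to map to +1.
#' @return Integer vector of -1/+1 with attribute `positive`.
#' @export
label_signs <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  u <- check_two_classes(labels)
  if (is.null(positive)) {
    counts <- table(factor(labels, levels = unique(labels)))
    positive <- names(counts)[which.min(counts)]
  }
  if (!positive %in% u) stop("positive label not present")
  y <- ifelse(labels == positive, 1L, -1L)
  attr(y, "positive") <- positive
  y
}

# Overlap backends: exact statevector readout or binomial shot sampling with
# optional depolarizing lambda.

#' Describe an overlap-estimation backend
#'
#' @param mode `"exact"` or `"shots"`.
#' @param shots shots per overlap estimate (shots mode).
#' @param lambda depolarizing error-rate parameter in `[0, 1]`.
#' @param seed base seed; individual estimates derive their own sub-seeds.
#' @return A list of class `overlap_backend`.
#' @export
overlap_backend <- function(mode = c("exact", "shots"), shots = 8192L,
                            lambda = 0, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, shots = as.integer(shots), lambda = lambda,
                 seed = as.integer(seed)),
            class = "overlap_backend")
}

backend_hadamard <- function(backend, U, V, sub_seed) {
  hadamard_test(U, V, mode = backend$mode, shots = backend$shots,
                seed = as.integer((backend$seed + sub_seed) %% .Machine$integer.max),
                lambda = backend$lambda)$value
}

#' Quantum distance between two encoded states
#'
#' The distance `1 - Re<u|v>` for unit states (norms times 1 minus the inner
#' product), with the inner product taken from the Hadamard test.  Zero for
#' identical states, 1 for orthogonal states, 2 for antipodal states.
#'
#' @param U,V state-preparation [circuit()]s.
#' @param backend an [overlap_backend()].
#' @param sub_seed integer mixed into the backend seed for shots mode.
#' @return Non-negative real distance.
#' @export
quantum_distance <- function(U, V, backend = overlap_backend(), sub_seed = 0L) {
  1 - backend_hadamard(backend, U, V, sub_seed)
}

#' Quantum distance classifier (qDC)
#'
#' Splits the training set by label into sets P (label `class_a`) and Q,
#' encodes every sample, and labels each test sample by the closer set:
#' `a` when `min_P(dist) <= min_Q(dist)` (ties go to P), else `b`.  Distances
#' are [quantum_distance()] values from the Hadamard test.  The continuous
#' score `min_Q - min_P` (positive favours `a`) supports AUC computation.
#'
#' @param train a [labeled_dataset()] containing both classes.
#' @param test_x numeric matrix of test samples (or a single vector).
#' @param encoder feature-vector-to-circuit function, see [make_encoder()].
#' @param backend an [overlap_backend()].
#' @param class_a label playing the role of set P; default: first label in
#'   training order.
#' @return A data.frame with columns `score` (min_Q - min_P) and `label`.
#' @export
qdc_classify <- function(train, test_x, encoder = encode_log2n,
                         backend = overlap_backend(), class_a = NULL) {
  u <- check_two_classes(train$labels)
  if (is.null(class_a)) class_a <- train$labels[1]
  if (!class_a %in% u) stop("class_a is not a training label")
  class_b <- setdiff(u, class_a)
  if (is.vector(test_x)) test_x <- matrix(test_x, nrow = 1)
  test_x <- as.matrix(test_x)

  idxP <- which(train$labels == class_a)
  idxQ <- which(train$labels == class_b)
  if (!length(idxP) || !length(idxQ)) stop("a class subset is empty")

  enc_train <- lapply(seq_len(nrow(train$features)),
                      function(i) encoder(train$features[i, ]))
  n <- enc_train[[1]]$n_qubits
  cu_train <- lapply(enc_train, prep_ctrl_gates)
  out <- data.frame(score = numeric(nrow(test_x)),
                    label = character(nrow(test_x)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(test_x))) {
    cv_gates <- prep_ctrl_gates(encoder(test_x[k, ]))
    d <- vapply(seq_along(cu_train), function(i) {
      circ <- hadamard_circuit_from_gates(cu_train[[i]], cv_gates, n)
      s <- as.integer((backend$seed + 131071L * k + i) %% .Machine$integer.max)
      val <- overlap_from_circuit(circ, backend$mode, backend$shots, s,
                                  backend$lambda)
      1 - min(max(val, -1), 1)
    }, numeric(1))
    minP <- min(d[idxP]); minQ <- min(d[idxQ])
    out$score[k] <- minQ - minP
    out$label[k] <- if (minP <= minQ) class_a else class_b
  }
  out
}

#' Fixed sqKSVM weight vector from the imbalance ratio
#'
#' Uniform weights `alpha* = 1` for a balanced dataset (`IR = 0.5`);
#' otherwise `alpha* = IR` for every majority-class sample and
#' `alpha* = 1 - IR` for every minority-class sample.
#'
#' @param labels two-class training labels.
#' @param IR imbalance ratio in `(0, 0.5]`; default computed from `labels`
#'   via [imbalance_ratio()].
#' @return Numeric weight vector, one entry per training sample, in `(0, 1]`.
#' @export
sqksvm_alpha <- function(labels, IR = NULL) {
  labels <- as.character(labels)
  check_two_classes(labels)
  if (is.null(IR)) IR <- imbalance_ratio(labels)
  if (IR <= 0 || IR > 0.5) stop("IR must lie in (0, 0.5]")
  if (IR == 0.5) return(rep(1, length(labels)))
  counts <- table(labels)
  minority <- names(counts)[which.min(counts)]
  ifelse(labels == minority, 1 - IR, IR)
}

#' sqKSVM decision rule
#'
#' The simplified quantum-kernel SVM skips dual optimisation: the decision
#' value for a test sample is `sum_i y_i alpha*_i K(x_i, x~)` with the fixed
#' [sqksvm_alpha()] weights, thresholded at 0 (a score of exactly 0 maps to
#' +1).
#'
#' @param y training labels as -1/+1 (see [label_signs()]).
#' @param alpha weight vector from [sqksvm_alpha()].
#' @param k_row kernel values `K(x_i, x~)` for one test sample (length M), or
#'   an M x T matrix for T test samples.
#' @return A data.frame with columns `score` and `label` (+1/-1).
#' @export
sqksvm_classify <- function(y, alpha, k_row) {
  k_row <- as.matrix(k_row)
  if (nrow(k_row) != length(y) || length(alpha) != length(y)) {
    stop("kernel rows, labels and weights must share the training size")
  }
  score <- as.numeric(crossprod(k_row, y * alpha))
  data.frame(score = score, label = ifelse(score >= 0, 1L, -1L))
}

#' Reference kernel SVM on a precomputed quantum kernel
#'
#' Soft-margin SVM dual solved by sequential minimal optimisation (maximal
#' violating pair selection) on the precomputed kernel, as the optimised
#' counterpart to the fixed-weight sqKSVM.  A kernel whose smallest
#' eigenvalue is below `-psd_tol` is repaired by shifting the eigenvalue
#' floor to zero (with a warning).  The solver is deterministic.
#'
#' @param K square symmetric kernel matrix over the training samples.
#' @param y training labels as -1/+1.
#' @param C soft-margin cost (default 1).
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter iteration cap.
#' @param psd_tol negative-eigenvalue tolerance before repair.
#' @return List of class `qksvm_fit`: `alpha` (dual variables), `b`
#'   (intercept), `y`, `C`, `iterations`.
#' @export
qksvm_reference_fit <- function(K, y, C = 1, tol = 1e-8, max_iter = 100000L,
                                psd_tol = 1e-8) {
  K <- as.matrix(K)
  M <- nrow(K)
  if (ncol(K) != M) stop("K must be square")
  if (length(y) != M) stop("labels must match the kernel size")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol) {
    warning("kernel is not PSD (min eigenvalue ", format(min(ev)),
            "); repairing by eigenvalue shift")
    es <- eigen(K, symmetric = TRUE)
    K <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    K <- (K + t(K)) / 2
  }

  alpha <- numeric(M)
  G <- rep(-1, M)             # gradient of 1/2 a'Qa - e'a at alpha = 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ygrad <- -y * G
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(ygrad[up])]
    j <- which(lo)[which.min(ygrad[lo])]
    if (ygrad[i] - ygrad[j] < tol || iter > max_iter) break

    a2 <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (a2 <= 1e-12) a2 <- 1e-12
    t_star <- (ygrad[i] - ygrad[j]) / a2
    # keep both alphas inside [0, C]: alpha_i + y_i t, alpha_j - y_j t
    t_hi <- min(if (y[i] == 1) C - alpha[i] else alpha[i],
                if (y[j] == 1) alpha[j] else C - alpha[j])
    t_step <- min(t_star, t_hi)
    alpha[i] <- min(max(alpha[i] + y[i] * t_step, 0), C)
    alpha[j] <- min(max(alpha[j] - y[j] * t_step, 0), C)
    G <- G + t_step * y * (K[, i] - K[, j])
  }
  if (iter > max_iter) warning("SMO hit the iteration cap before tolerance")

  free <- alpha > 1e-8 & alpha < C - 1e-8
  ygrad <- -y * G
  b <- if (any(free)) mean(ygrad[free]) else {
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    (max(ygrad[up]) + min(ygrad[lo])) / 2
  }
  structure(list(alpha = alpha, b = b, y = y, C = C, iterations = iter),
            class = "qksvm_fit")
}

#' Decision values of a fitted reference kernel SVM
#'
#' @param fit a `qksvm_fit`.
#' @param k_rows M x T matrix of kernel values between the M training samples
#'   and T test samples.
#' @return A data.frame with columns `score` and `label` (+1/-1).
#' @export
qksvm_decision <- function(fit, k_rows) {
  k_rows <- as.matrix(k_rows)
  if (nrow(k_rows) != length(fit$alpha)) {
    stop("kernel rows must match the training size")
  }
  score <- as.numeric(crossprod(k_rows, fit$alpha * fit$y)) + fit$b
  data.frame(score = score, label = ifelse(score >= 0, 1L, -1L))
}

#' Export predictions as CSV
#'
#' @param predictions data.frame with `score` and `label` columns.
#' @param truth optional vector of true labels.
#' @param path output file.
#' @param ids optional sample identifiers.
#' @export
write_predictions_csv <- function(predictions, path, truth = NULL, ids = NULL) {
  df <- data.frame(id = if (is.null(ids)) seq_len(nrow(predictions)) else ids,
                   score = predictions$score,
                   predicted = predictions$label)
  if (!is.null(truth)) df$truth <- truth
  utils::write.csv(df, path, row.names = FALSE)
}
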