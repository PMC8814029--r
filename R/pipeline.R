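# Dataset handling, preprocessing, cross-validated evaluation and the
# synthetic two-class generator.
#
# The evaluation protocol mirrors small-cohort clinical ML practice: per
# fold, correlation-redundancy reduction and univariate feature ranking are
# fitted on the training split only, then the chosen quantum classifier
# scores the held-out validation samples and performance is summarised as
# the mean validation AUC over folds.

#' Load a two-class CSV dataset
#'
#' Rows = samples; all columns except `label_column` must be numeric
#' features; the label column must contain exactly two distinct values.
#'
#' @param path CSV file with a header row.
#' @param label_column name of the label column.
#' @return A [labeled_dataset()].
#' @export
load_csv <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not present")
  }
  labels <- as.character(df[[label_column]])
  u <- unique(labels)
  if (length(u) != 2) {
    stop("label column must have exactly two distinct values, got: ",
         paste(u, collapse = ", "))
  }
  feats <- df[setdiff(names(df), label_column)]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  labeled_dataset(as.matrix(feats), labels, feature_names = names(feats))
}

#' Write a labelled dataset as CSV
#'
#' @param data a [labeled_dataset()].
#' @param path output file.
#' @param label_column name for the label column.
#' @export
write_dataset_csv <- function(data, path, label_column = "label") {
  df <- as.data.frame(data$features)
  df[[label_column]] <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
}

#' Drop correlation-redundant features
#'
#' Greedy scan in column order: a feature is dropped when its absolute
#' Pearson correlation with any earlier kept feature exceeds `threshold`.
#' Constant columns (undefined correlation) are dropped first with a
#' warning.  Deterministic.
#'
#' @param data a [labeled_dataset()].
#' @param threshold correlation threshold in `(0, 1]` (default 0.9).
#' @return A `labeled_dataset` of the surviving features, with attribute
#'   `kept` holding the surviving column indices of the input.
#' @export
reduce_redundancy <- function(data, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  X <- data$features
  sds <- apply(X, 2, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const)) {
    warning("dropping constant feature(s): ",
            paste(data$feature_names[const], collapse = ", "))
  }
  candidates <- setdiff(seq_len(ncol(X)), const)
  kept <- integer(0)
  for (j in candidates) {
    redundant <- length(kept) &&
      any(abs(stats::cor(X[, kept, drop = FALSE], X[, j])) > threshold)
    if (!redundant) kept <- c(kept, j)
  }
  if (!length(kept)) stop("no features survive redundancy reduction")
  out <- labeled_dataset(X[, kept, drop = FALSE], data$labels,
                         feature_names = data$feature_names[kept])
  attr(out, "kept") <- kept
  out
}

#' Rank features by univariate class separation and select the top k
#'
#' Default score: absolute point-biserial correlation between each feature
#' and the -1/+1 label, computed on the supplied (training) data only.  A
#' custom `score_fun(feature_values, y_signs)` may be plugged in.  Ties break
#' to the earlier column (deterministic).
#'
#' @param data a [labeled_dataset()] (training split).
#' @param k number of features to keep; must not exceed the feature count.
#' @param score_fun optional scoring function; larger = more informative.
#' @return Integer vector of the top-k feature column indices, in rank order.
#' @export
rank_and_select <- function(data, k, score_fun = NULL) {
  p <- ncol(data$features)
  if (k > p) {
    stop("requested k = ", k, " features but only ", p, " are available")
  }
  y <- as.numeric(label_signs(data$labels))
  if (is.null(score_fun)) {
    score_fun <- function(x, y) {
      if (stats::sd(x) == 0) return(0)
      abs(stats::cor(x, y))
    }
  }
  scores <- apply(data$features, 2, score_fun, y = y)
  order(scores, decreasing = TRUE)[seq_len(k)]
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels two-class labels; `positive` selects the positive class
#'   (default: minority, see [label_signs()]).
#' @param positive optional positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  y <- label_signs(labels, positive)
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Class imbalance ratio
#'
#' Minority-class count divided by the total sample count, in `(0, 0.5]`.
#'
#' @param labels two-class label vector.
#' @return The imbalance ratio.
#' @export
imbalance_ratio <- function(labels) {
  labels <- as.character(labels)
  check_two_classes(labels)
  min(table(labels)) / length(labels)
}

#' Geometric-difference score between a quantum and a classical kernel
#'
#' Compares the geometry a quantum kernel induces with that of the classical
#' linear kernel on the same samples:
#' `g_CQ = sqrt( || sqrt(K_Q) K_C^{-1} sqrt(K_Q) ||_inf )` with the spectral
#' norm, after trace-normalising both kernels to `tr(K) = M`.  `K_C`
#' eigenvalues are floored at `reg` before inversion.  Values above 1 signal
#' that the quantum feature geometry separates points the classical kernel
#' cannot.  The exact normalisation used in the source literature varies;
#' treat absolute values as experimental.
#'
#' @param K_classical,K_quantum square kernel matrices of equal size.
#' @param reg eigenvalue floor for the classical-kernel inverse.
#' @return Positive scalar score.
#' @export
gcq_score <- function(K_classical, K_quantum, reg = 1e-8) {
  K_classical <- as.matrix(K_classical); K_quantum <- as.matrix(K_quantum)
  M <- nrow(K_classical)
  if (!all(dim(K_classical) == c(M, M)) || !all(dim(K_quantum) == c(M, M))) {
    stop("kernels must be square and of equal size")
  }
  tnorm <- function(K) K * (M / sum(diag(K)))
  Kc <- tnorm((K_classical + t(K_classical)) / 2)
  Kq <- tnorm((K_quantum + t(K_quantum)) / 2)
  ec <- eigen(Kc, symmetric = TRUE)
  Kc_inv <- ec$vectors %*% ((1 / pmax(ec$values, reg)) * t(ec$vectors))
  eq <- eigen(Kq, symmetric = TRUE)
  Kq_sqrt <- eq$vectors %*% (sqrt(pmax(eq$values, 0)) * t(eq$vectors))
  Mid <- Kq_sqrt %*% Kc_inv %*% Kq_sqrt
  Mid <- (Mid + t(Mid)) / 2
  sqrt(max(eigen(Mid, symmetric = TRUE, only.values = TRUE)$values))
}

#' Generate a synthetic two-class Gaussian dataset
#'
#' Two multivariate Gaussian clusters with unit marginal variance whose means
#' are `separation` standard deviations apart along a random unit direction;
#' the minority class holds a fraction `IR` of the samples.  Optional
#' exchangeable pairwise feature correlation `rho`.  Reproducible under
#' `seed`.  Labels are `"neg"` (majority) and `"pos"` (minority).
#'
#' All features share a positive `baseline` mean, emulating clinical
#' measurements (ages, counts, concentrations), which are positive with a
#' nonzero typical value.  This matters for amplitude encoding: l2
#' normalisation of zero-centred clusters maps the two classes onto
#' antipodal directions, which the sign-blind squared overlap
#' `|<u|v>|^2` cannot distinguish.
#'
#' @param M total sample count (>= 4).
#' @param N feature count (>= 2).
#' @param separation class-mean separation in units of the feature sd.
#' @param IR imbalance ratio in `(0, 0.5]`.
#' @param rho exchangeable feature correlation in `[0, 1)`.
#' @param baseline common feature mean in sd units (default 4).
#' @param seed integer seed.
#' @return A [labeled_dataset()].
#' @export
generate_two_class <- function(M, N, separation = 2, IR = 0.5, rho = 0,
                               baseline = 4, seed = 1L) {
  if (M < 4) stop("M must be >= 4")
  if (N < 2) stop("N must be >= 2")
  if (IR <= 0 || IR > 0.5) stop("IR must lie in (0, 0.5]")
  if (separation < 0) stop("separation must be >= 0")
  n_pos <- round(IR * M)
  if (n_pos < 1 || n_pos > M - n_pos) stop("IR infeasible for M = ", M)
  n_neg <- M - n_pos
  with_local_seed(seed, {
    dir <- stats::rnorm(N); dir <- dir / sqrt(sum(dir^2))
    Sigma <- matrix(rho, N, N); diag(Sigma) <- 1
    L <- chol(Sigma)
    draw <- function(m, mu) {
      Z <- matrix(stats::rnorm(m * N), m, N) %*% L
      sweep(Z, 2, mu, "+")
    }
    X <- rbind(draw(n_neg, baseline - separation / 2 * dir),
               draw(n_pos, baseline + separation / 2 * dir))
    labels <- c(rep("neg", n_neg), rep("pos", n_pos))
    ord <- sample.int(M)
    labeled_dataset(X[ord, , drop = FALSE], labels[ord])
  })
}

# ---- cross-validation -------------------------------------------------------

#' Cross-validation configuration
#'
#' Repeated stratified Monte-Carlo splitting: `n_folds` independent random
#' splits at `train_fraction` (so ten 80/20 splits by default, honouring
#' both a tenfold repetition count and an 80-20 train-validation ratio).
#'
#' @param n_folds number of repeated splits (default 10).
#' @param train_fraction fraction of each class used for training (default
#'   0.8).
#' @param n_features number of top-ranked features to keep per fold (`NULL` =
#'   all surviving features).
#' @param redundancy_threshold correlation threshold for
#'   [reduce_redundancy()].
#' @param seed integer seed controlling the splits (and shot sampling).
#' @param backend an [overlap_backend()].
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, train_fraction = 0.8, n_features = NULL,
                      redundancy_threshold = 0.9, seed = 1L,
                      backend = overlap_backend()) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  structure(list(n_folds = as.integer(n_folds),
                 train_fraction = train_fraction,
                 n_features = n_features,
                 redundancy_threshold = redundancy_threshold,
                 seed = as.integer(seed), backend = backend),
            class = "cv_config")
}

# One stratified train index set per fold, deterministic under cfg$seed.
stratified_splits <- function(labels, cfg) {
  classes <- unique(labels)
  lapply(seq_len(cfg$n_folds), function(f) {
    with_local_seed(cfg$seed * 1009L + f, {
      unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        n_tr <- max(1L, round(cfg$train_fraction * length(idx)))
        if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
        if (n_tr < 1) stop("class '", cl, "' too small to split")
        sort(sample(idx, n_tr))
      }))
    })
  })
}

#' Cross-validated evaluation of a quantum classifier
#'
#' For each of `cfg$n_folds` stratified Monte-Carlo splits: redundancy-reduce
#' and rank features on the training split only, encode with the chosen
#' feature map, score the validation samples with the chosen classifier, and
#' compute the validation AUC from the continuous decision scores.  The mean
#' AUC over folds is reported together with the imbalance ratio.
#'
#' @param data a [labeled_dataset()].
#' @param classifier `"qdc"`, `"sqksvm"` or `"qksvm"` (reference SMO fit).
#' @param encoding `"log2n"` or `"nqubit"`.
#' @param cfg a [cv_config()].
#' @param kernel_method kernel path for the SVM classifiers (`"swap"` or
#'   `"hadamard2"`).
#' @param C soft-margin cost for the reference SVM.
#' @return A list of class `evaluation_report`: `fold_auc`, `mean_auc`,
#'   `classifier`, `encoding`, `n_features`, `IR`, `n_folds`, `seed`.
#' @export
cross_validate <- function(data, classifier = c("qdc", "sqksvm", "qksvm"),
                           encoding = c("log2n", "nqubit"),
                           cfg = cv_config(), kernel_method = "swap", C = 1) {
  classifier <- match.arg(classifier)
  encoding <- match.arg(encoding)
  labels <- data$labels
  check_two_classes(labels)
  splits <- stratified_splits(labels, cfg)

  fold_auc <- vapply(seq_along(splits), function(f) {
    tr_idx <- splits[[f]]
    va_idx <- setdiff(seq_along(labels), tr_idx)
    train_all <- labeled_dataset(data$features[tr_idx, , drop = FALSE],
                                 labels[tr_idx],
                                 feature_names = data$feature_names)
    red <- reduce_redundancy(train_all, cfg$redundancy_threshold)
    kept <- attr(red, "kept")
    k <- if (is.null(cfg$n_features)) ncol(red$features) else cfg$n_features
    sel <- rank_and_select(red, k)
    cols <- kept[sel]

    Xtr <- data$features[tr_idx, cols, drop = FALSE]
    Xva <- data$features[va_idx, cols, drop = FALSE]
    train <- labeled_dataset(Xtr, labels[tr_idx])
    ranges <- rbind(apply(Xtr, 2, min), apply(Xtr, 2, max))
    encoder <- make_encoder(encoding, ranges = ranges)

    backend <- cfg$backend
    backend$seed <- as.integer((backend$seed + 7907L * f) %% .Machine$integer.max)

    scores <- switch(classifier,
      qdc = {
        pred <- qdc_classify(train, Xva, encoder, backend)
        # score favours class_a (= first training label); orient towards the
        # positive (minority) class for AUC
        y1 <- label_signs(train$labels)
        if (y1[1] == 1) pred$score else -pred$score
      },
      sqksvm = {
        y <- label_signs(train$labels)
        alpha <- sqksvm_alpha(train$labels)
        Krows <- kernel_matrix(Xtr, Xva, encoder, method = kernel_method,
                               mode = backend$mode, shots = backend$shots,
                               seed = backend$seed, lambda = backend$lambda)
        sqksvm_classify(y, alpha, Krows)$score
      },
      qksvm = {
        y <- label_signs(train$labels)
        Ktr <- kernel_matrix(Xtr, Xtr, encoder, method = kernel_method,
                             mode = backend$mode, shots = backend$shots,
                             seed = backend$seed, lambda = backend$lambda)
        Ktr <- (Ktr + t(Ktr)) / 2
        fit <- qksvm_reference_fit(Ktr, y, C = C)
        Krows <- kernel_matrix(Xtr, Xva, encoder, method = kernel_method,
                               mode = backend$mode, shots = backend$shots,
                               seed = backend$seed + 1L, lambda = backend$lambda)
        qksvm_decision(fit, Krows)$score
      })
    pos <- attr(label_signs(labels[tr_idx]), "positive")
    auc(scores, labels[va_idx], positive = pos)
  }, numeric(1))

  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc),
                 classifier = classifier,
                 encoding = encoding,
                 n_features = cfg$n_features,
                 IR = imbalance_ratio(labels),
                 n_folds = cfg$n_folds,
                 seed = cfg$seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$classifier, " / ", x$encoding, " encoding\n",
      "  folds: ", x$n_folds, "  features: ",
      if (is.null(x$n_features)) "all" else x$n_features,
      "  IR: ", format(x$IR, digits = 3), "\n",
      "  fold AUC: ", paste(format(x$fold_auc, digits = 3), collapse = " "),
      "\n  mean AUC: ", format(x$mean_auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per fold plus a `mean` row.
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report_csv <- function(report, path) {
  df <- data.frame(fold = c(seq_along(report$fold_auc), "mean"),
                   auc = c(report$fold_auc, report$mean_auc),
                   classifier = report$classifier,
                   encoding = report$encoding,
                   IR = report$IR)
  utils::write.csv(df, path, row.names = FALSE)
}
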