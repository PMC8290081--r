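# MVPA core: per-subject linear SVM with Platt probability calibration and
# stratified, leakage-safe cross-validation.  The SVM is solved by dual
# coordinate descent on the L1-hinge dual (deterministic given the seed),
# with the bias absorbed as an augmented constant feature.

svm_dcd <- function(X, y, C = 1, max_epochs = 200, tol = 1e-6, seed = 1) {
  n <- nrow(X); d <- ncol(X)
  Xa <- cbind(X, 1)
  Qii <- rowSums(Xa ^ 2)
  alpha <- numeric(n)
  w <- numeric(d + 1)
  order_seq <- withr::with_seed(seed, replicate(max_epochs, sample.int(n),
                                                simplify = FALSE))
  for (ep in seq_len(max_epochs)) {
    max_viol <- 0
    for (i in order_seq[[ep]]) {
      G <- y[i] * sum(w * Xa[i, ]) - 1
      PG <- G
      if (alpha[i] <= 0) PG <- min(G, 0)
      else if (alpha[i] >= C) PG <- max(G, 0)
      if (abs(PG) > 1e-12) {
        a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
        w <- w + (a_new - alpha[i]) * y[i] * Xa[i, ]
        alpha[i] <- a_new
      }
      max_viol <- max(max_viol, abs(PG))
    }
    if (max_viol < tol) break
  }
  list(w = w[seq_len(d)], b = w[d + 1], alpha = alpha)
}

# Platt's sigmoid fit: p(y=1|f) = 1 / (1 + exp(A f + B)), Newton iterations
# with the regularized targets from Platt (1999) / Lin et al. (2007).
platt_fit <- function(f, y, max_iter = 100, tol = 1e-10) {
  n1 <- sum(y == 1); n0 <- sum(y != 1)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                      # dF/dz
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h12 <- sum(f * d2)
    det <- h11 * h22 - h12 * h12
    if (abs(g1) < tol && abs(g2) < tol) break
    dA <- -(h22 * g1 - h12 * g2) / det
    dB <- -(-h12 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      newval <- obj(A + step * dA, B + step * dB)
      if (newval < val + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10)
        break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    val <- obj(A, B)
  }
  c(A = A, B = B)
}

#' Train a calibrated linear decoder
#'
#' Standardizes features, fits a linear SVM (hinge loss, cost `C`), and
#' calibrates a Platt sigmoid on cross-validated decision values from
#' held-out folds of the training data (so the calibration is not fit on
#' in-sample margins).  Label convention: the score approaches 1 for the
#' `positive` ("smoking-like") class.
#'
#' @param features trials x d numeric matrix.
#' @param labels condition per trial (two classes).
#' @param positive the label treated as the positive/smoking-like class.
#' @param C SVM cost parameter.
#' @param seed RNG seed (fold assignment and coordinate order).
#' @param calibration_folds folds for the calibration decision values.
#' @param featset optional `cluster_feature_set` recipe stored with the
#'   decoder (used by the closed-loop engine to assemble features online).
#' @param bands band definitions belonging to `featset`.
#' @return object of class `trained_decoder` with `w`, `b`, `mu`, `sd`,
#'   `platt`, `classes`, `positive`, `cv_accuracy` (NA until
#'   [crossvalidate()] fills it), `featset`, `bands`.
#' @export
train_decoder <- function(features, labels, positive = "smoking", C = 1,
                          seed = 1, calibration_folds = 3,
                          featset = NULL, bands = band_set()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("need exactly two classes, got: ", paste(classes, collapse = ", "))
  if (!positive %in% classes) positive <- classes[2]
  y <- ifelse(labels == positive, 1, -1)
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  fit <- svm_dcd(Z, y, C = C, seed = seed)

  folds <- stratified_folds(labels, calibration_folds, seed + 1)
  fcv <- numeric(length(y))
  for (k in seq_len(calibration_folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) { fcv[!tr] <- 0; next }
    fk <- svm_dcd(Z[tr, , drop = FALSE], y[tr], C = C, seed = seed)
    fcv[!tr] <- Z[!tr, , drop = FALSE] %*% fk$w + fk$b
  }
  platt <- platt_fit(fcv, y)
  if (platt["A"] >= 0) platt <- c(A = -1, B = 0)  # degenerate calibration

  structure(list(w = fit$w, b = fit$b, mu = mu, sd = sdv, platt = platt,
                 classes = classes, positive = positive, C = C,
                 cv_accuracy = NA_real_, featset = featset, bands = bands),
            class = "trained_decoder")
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf("<trained_decoder> %d features, positive class '%s'%s\n",
              length(x$w), x$positive,
              if (is.na(x$cv_accuracy)) "" else
                sprintf(", CV accuracy %.3f", x$cv_accuracy)))
  invisible(x)
}

decision_value <- function(decoder, features) {
  features <- matrix(features, ncol = length(decoder$w))
  Z <- sweep(sweep(features, 2, decoder$mu), 2, decoder$sd, "/")
  drop(Z %*% decoder$w + decoder$b)
}

#' Probabilistic score of feature vectors
#'
#' Platt-calibrated probability in (0, 1) that the pattern is
#' smoking-like; strictly increasing in the SVM decision value.
#'
#' @param decoder a [train_decoder()] result.
#' @param features numeric vector of length d, or a trials x d matrix.
#' @return numeric score(s) in (0, 1).
#' @export
score_decoder <- function(decoder, features) {
  stopifnot(inherits(decoder, "trained_decoder"))
  if (is.matrix(features)) {
    if (ncol(features) != length(decoder$w))
      stop("feature vector length mismatch: expected ", length(decoder$w))
  } else if (length(features) != length(decoder$w))
    stop("feature vector length mismatch: expected ", length(decoder$w))
  f <- decision_value(decoder, features)
  1 / (1 + exp(decoder$platt["A"] * f + decoder$platt["B"]))
}

#' Predicted class labels
#' @param decoder a `trained_decoder`.
#' @param features trials x d matrix.
#' @return character vector of labels.
#' @export
predict_class <- function(decoder, features) {
  f <- decision_value(decoder, features)
  neg <- setdiff(decoder$classes, decoder$positive)
  ifelse(f >= 0, decoder$positive, neg)
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validated accuracy
#'
#' Standardization and SVM fit are redone inside each training fold; each
#' test fold holds out 1/k (20% for the default k = 5) of the trials,
#' stratified by class.  Fold assignment depends only on `seed`.
#'
#' @param features trials x d matrix.
#' @param labels condition per trial.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param positive positive class label.
#' @param C SVM cost.
#' @return list with `fold_accuracy` (length k), `mean_accuracy`, `folds`.
#' @export
crossvalidate <- function(features, labels, k = 5, seed = 1,
                          positive = "smoking", C = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("need exactly two classes")
  if (min(tab) < k) stop("need at least k trials per class")
  folds <- stratified_folds(labels, k, seed)
  acc <- numeric(k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    dec <- train_decoder(features[tr, , drop = FALSE], labels[tr],
                         positive = positive, C = C, seed = seed)
    pred <- predict_class(dec, features[!tr, , drop = FALSE])
    acc[fold] <- mean(pred == labels[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = folds)
}

#' Cross-validate the full offline pipeline
#'
#' Leakage-safe evaluation of feature selection + decoding: inside each
#' training fold, cluster-mass feature selection is re-run from scratch
#' and a decoder trained on the fold's own clusters, then applied to the
#' held-out trials.  A fold whose training data yield no significant
#' cluster predicts the training-fold majority class.  Setting
#' `whole_data_selection = TRUE` reproduces the optimistic (leaky) variant
#' in which clusters are selected once on all trials; it exists for
#' comparison studies only.
#'
#' @param epochs an `epoch_set` with smoking/neutral labels.
#' @param k folds.
#' @param seed RNG seed.
#' @param bands,adjacency,n_perm,alpha,decim,n_cycles selection
#'   parameters, as in [select_features()].
#' @param domains feature domains to search.
#' @param whole_data_selection if `TRUE`, select features on all trials
#'   (information leakage; off by default).
#' @param C SVM cost.
#' @return list with `fold_accuracy`, `mean_accuracy`,
#'   `n_features_per_fold`, `folds`.
#' @export
crossvalidate_pipeline <- function(epochs, k = 5, seed = 1,
                                   bands = band_set(), adjacency = NULL,
                                   n_perm = 1000, alpha = 0.05,
                                   decim = 5, n_cycles = 7,
                                   domains = c("amplitude", "bands"),
                                   whole_data_selection = FALSE, C = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$kept & epochs$labels %in% c("smoking", "neutral")
  ep <- subset_epochs(epochs, keep)
  labels <- ep$labels
  if (min(table(labels)) < k) stop("need at least k trials per class")
  if (is.null(adjacency)) adjacency <- montage_adjacency(ep$channel_labels)
  folds <- stratified_folds(labels, k, seed)
  bp <- if ("bands" %in% domains)
    band_power(ep, bands, n_cycles = n_cycles, decim = decim) else NULL
  global_featset <- NULL
  if (whole_data_selection)
    global_featset <- select_features(ep, bands, adjacency, n_perm, alpha,
                                      seed, decim, n_cycles, domains,
                                      band_power_set = bp)
  acc <- numeric(k); nfeat <- integer(k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    ep_tr <- subset_epochs(ep, tr)
    bp_fold <- if (!is.null(bp)) {
      b <- bp; b$power <- bp$power[tr, , , , drop = FALSE]; b
    } else NULL
    featset <- if (whole_data_selection) global_featset else
      select_features(ep_tr, bands, adjacency, n_perm, alpha,
                      seed + fold, decim, n_cycles, domains,
                      band_power_set = bp_fold)
    nfeat[fold] <- length(featset$clusters)
    if (!length(featset$clusters)) {
      maj <- names(which.max(table(labels[tr])))
      acc[fold] <- mean(labels[!tr] == maj)
      next
    }
    bp_tr <- if (!is.null(bp)) {
      b <- bp; b$power <- bp$power[tr, , , , drop = FALSE]; b
    } else NULL
    bp_te <- if (!is.null(bp)) {
      b <- bp; b$power <- bp$power[!tr, , , , drop = FALSE]; b
    } else NULL
    Xtr <- assemble_features(ep_tr, featset, bands, band_power_set = bp_tr,
                             n_cycles = n_cycles, decim = decim)
    Xte <- assemble_features(subset_epochs(ep, !tr), featset, bands,
                             band_power_set = bp_te,
                             n_cycles = n_cycles, decim = decim)
    dec <- train_decoder(Xtr, labels[tr], C = C, seed = seed)
    acc[fold] <- mean(predict_class(dec, Xte) == labels[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       n_features_per_fold = nfeat, folds = folds)
}
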