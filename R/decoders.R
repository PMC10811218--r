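# The compared decoding pipelines. Every fit_* function returns an object
# with a predict() method mapping trials to labels in {1, 2}; prediction is
# deterministic given the fitted model.

assert_two_classes <- function(labels) {
  if (!all(c(1L, 2L) %in% labels))
    stop("training data must contain both classes (labels 1 and 2)",
         call. = FALSE)
}

# CSP spatial filters from the class-mean covariances (per-trial covariances
# normalized by trace before averaging). Rows of the returned matrix are
# filters ordered by decreasing class-1 variance ratio; the full filter set
# W satisfies W (C1 + C2) Wt = I.
csp_filters <- function(trials, n_pairs = 3, shrinkage = 1e-3) {
  covs <- trial_covariances(trials, shrinkage)
  covs <- lapply(covs, function(C) C / sum(diag(C)))
  C1 <- Reduce(`+`, covs[trials$labels == 1L]) / sum(trials$labels == 1L)
  C2 <- Reduce(`+`, covs[trials$labels == 2L]) / sum(trials$labels == 2L)
  Cc <- C1 + C2
  e <- eigen(Cc, symmetric = TRUE)
  P <- diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  S1 <- P %*% C1 %*% t(P)
  b <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W <- t(b$vectors) %*% P
  sel <- c(seq_len(n_pairs), nrow(W) - seq_len(n_pairs) + 1L)
  list(W = W[sel, , drop = FALSE], W_full = W)
}

# Normalized log-variance features (Ramoser et al. convention): the share
# of each projection's variance, which cancels per-trial global gain.
csp_features <- function(W, trials) {
  n <- n_trials(trials)
  out <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) {
    proj <- W %*% trials$data[i, , ]
    v <- apply(proj, 1, var)
    out[i, ] <- log(v / sum(v))
  }
  colnames(out) <- paste0("csp", seq_len(ncol(out)))
  out
}

#' Fit the CSP + LDA decoder
#'
#' Common spatial patterns from the generalized eigendecomposition of the
#' class-mean covariances; features are log-variances of the `2 * n_pairs`
#' most discriminative projections; classification by linear discriminant
#' analysis.
#'
#' @param train An [mi_trials()] (band-filtered, windowed) with both classes
#'   present.
#' @param n_pairs Number of CSP filter pairs.
#' @param shrinkage Covariance shrinkage.
#' @return A `csp_lda` model with a [predict()] method.
#' @export
fit_csp_lda <- function(train, n_pairs = 3, shrinkage = 1e-3) {
  assert_two_classes(train$labels)
  cf <- csp_filters(train, n_pairs, shrinkage)
  feat <- csp_features(cf$W, train)
  lda <- MASS::lda(feat, grouping = factor(train$labels, levels = c(1, 2)))
  structure(list(W = cf$W, W_full = cf$W_full, lda = lda,
                 n_pairs = n_pairs),
            class = c("csp_lda", "mi_decoder"))
}

#' @export
predict.csp_lda <- function(object, newdata, ...) {
  feat <- csp_features(object$W, newdata)
  as.integer(as.character(predict(object$lda, feat)$class))
}

# Plug-in mutual information between a continuous feature and binary labels
# via equal-frequency binning.
binned_mutual_information <- function(x, labels, n_bins = 4) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(0)
  bx <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(bx, labels) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  mi
}

#' Construct a filter-bank specification
#'
#' The default bank is the 19 four-Hz-wide bands stepped by 1 Hz from
#' 8-12 Hz to 26-30 Hz (the published table's "25-25 Hz" entry is read as
#' 25-29 Hz, the only value continuing the pattern).
#'
#' @param bands Two-column matrix or list of `(low, high)` pairs in Hz.
#' @return A `filter_bank` object (two-column matrix).
#' @export
filter_bank <- function(bands = cbind(8:26, 12:30)) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- matrix(as.numeric(bands), ncol = 2)
  if (any(bands[, 1] >= bands[, 2]) || any(bands <= 0) || any(bands >= 250))
    stop("each band must satisfy 0 < low < high < 250 Hz", call. = FALSE)
  colnames(bands) <- c("low", "high")
  structure(bands, class = c("filter_bank", class(bands)))
}

#' Fit the filter-bank CSP + SVM decoder
#'
#' Per-band CSP log-variance features, mutual-information ranking to keep
#' the `k_features` most label-informative features, and a linear-kernel
#' support vector machine.
#'
#' @param train An [mi_trials()] holding broadband trials (each band is
#'   filtered internally).
#' @param bank A [filter_bank()].
#' @param k_features Number of features kept after ranking (clipped with a
#'   warning if it exceeds the number available).
#' @param n_pairs CSP pairs per band.
#' @param shrinkage Covariance shrinkage.
#' @return An `fbcsp_svm` model with a [predict()] method.
#' @export
fbcsp_feature_matrix <- function(x, bank, filters) {
  feats <- lapply(seq_len(nrow(bank)), function(b) {
    # order-4 band filters: 4-Hz cells must be spectrally selective
    tb <- bandpass_trials(x, bank[b, 1], bank[b, 2], order = 4)
    csp_features(filters[[b]], tb)
  })
  feat <- do.call(cbind, feats)
  colnames(feat) <- paste0("b", rep(seq_len(nrow(bank)),
                                    each = ncol(feat) / nrow(bank)),
                           "_", colnames(feat))
  feat
}

fit_fbcsp_svm <- function(train, bank = filter_bank(), k_features = 4,
                          n_pairs = 1, shrinkage = 1e-3) {
  assert_two_classes(train$labels)
  n_bands <- nrow(bank)
  filters <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    tb <- bandpass_trials(train, bank[b, 1], bank[b, 2], order = 4)
    filters[[b]] <- csp_filters(tb, n_pairs, shrinkage)$W
  }
  feat <- fbcsp_feature_matrix(train, bank, filters)
  if (k_features > ncol(feat)) {
    warning(sprintf("k_features clipped from %d to the %d available features",
                    k_features, ncol(feat)), call. = FALSE)
    k_features <- ncol(feat)
  }
  mi <- apply(feat, 2, binned_mutual_information, labels = train$labels)
  keep <- order(mi, decreasing = TRUE)[seq_len(k_features)]
  # a CSP feature and its variance-ratio partner are kept together
  partner <- function(j) {
    j <- as.integer(j)
    m2 <- 2L * as.integer(n_pairs)
    b <- (j - 1L) %/% m2
    within <- (j - 1L) %% m2
    b * m2 + (m2 - 1L - within) + 1L
  }
  keep <- sort(unique(c(keep, vapply(keep, partner, integer(1)))))
  y <- factor(train$labels, levels = c(1, 2))
  svm <- e1071::svm(feat[, keep, drop = FALSE], y, kernel = "linear",
                    scale = TRUE)
  structure(list(bank = bank, filters = filters, keep = keep,
                 mi = mi, svm = svm, n_pairs = n_pairs),
            class = c("fbcsp_svm", "mi_decoder"))
}

#' @export
predict.fbcsp_svm <- function(object, newdata, ...) {
  feat <- fbcsp_feature_matrix(newdata, object$bank,
                               object$filters)[, object$keep, drop = FALSE]
  as.integer(as.character(predict(object$svm, feat)))
}

#' Fit the minimum-distance-to-Riemannian-mean decoder
#'
#' One Riemannian mean covariance per class; a trial is assigned the class
#' whose mean is nearest under the affine-invariant metric. Exact ties go to
#' the lower label.
#'
#' @param train An [mi_trials()] or a list with elements `covs` (list of SPD
#'   matrices) and `labels`.
#' @param shrinkage Covariance shrinkage.
#' @return An `mdrm_model` with a [predict()] method.
#' @export
fit_mdrm <- function(train, shrinkage = 1e-3) {
  cs <- as_covariance_set(train, shrinkage)
  assert_two_classes(cs$labels)
  means <- lapply(c(1L, 2L), function(cl)
    riemannian_mean(cs$covs[cs$labels == cl]))
  structure(list(means = means, shrinkage = shrinkage),
            class = c("mdrm_model", "mi_decoder"))
}

as_covariance_set <- function(x, shrinkage = 1e-3) {
  if (inherits(x, "mi_trials"))
    list(covs = trial_covariances(x, shrinkage), labels = x$labels)
  else if (is.list(x) && !is.null(x$covs)) x
  else stop("expected an mi_trials or a covariance set", call. = FALSE)
}

mdrm_distances <- function(object, x) {
  cs <- as_covariance_set(x, object$shrinkage)
  t(vapply(cs$covs, function(C)
    c(airm_distance(C, object$means[[1]]),
      airm_distance(C, object$means[[2]])), numeric(2)))
}

# label 2 only when clearly nearer; numerically exact ties go to label 1
nearest_label <- function(d) {
  tol <- 1e-9 * (d[, 1] + d[, 2])
  ifelse(d[, 2] < d[, 1] - tol, 2L, 1L)
}

#' @export
predict.mdrm_model <- function(object, newdata, ...) {
  nearest_label(mdrm_distances(object, newdata))
}

#' Fit the tangent-space LDA decoder
#'
#' Trials' covariances are mapped to the tangent space at the grand
#' Riemannian mean and classified by a (regularized) Fisher linear
#' discriminant; the signed distance to the decision plane is the score.
#'
#' @param train An [mi_trials()] or covariance set; at least 2 trials per
#'   class.
#' @param shrinkage Covariance shrinkage.
#' @param reg Discriminant ridge regularization.
#' @return A `tslda_model` with [predict()] and score support.
#' @export
fit_tslda <- function(train, shrinkage = 1e-3, reg = 1e-3) {
  cs <- as_covariance_set(train, shrinkage)
  assert_two_classes(cs$labels)
  if (any(table(cs$labels) < 2L))
    stop("each class needs at least 2 trials", call. = FALSE)
  ref <- riemannian_mean(cs$covs)
  V <- tangent_coordinates(cs$covs, ref)
  fd <- fisher_direction(V, cs$labels, reg)
  thr <- sum(fd$w * (fd$m1 + fd$m2)) / 2
  structure(list(ref = ref, w = fd$w, threshold = thr,
                 shrinkage = shrinkage),
            class = c("tslda_model", "mi_decoder"))
}

# Signed distance to the LDA plane; positive favours class 2.
tslda_score <- function(object, x) {
  cs <- as_covariance_set(x, object$shrinkage)
  V <- tangent_coordinates(cs$covs, object$ref)
  as.vector(V %*% object$w) - object$threshold
}

#' @export
predict.tslda_model <- function(object, newdata, ...) {
  ifelse(tslda_score(object, newdata) > 0, 2L, 1L)
}

#' Fit the discriminant geodesic filtering + MDRM decoder
#'
#' Training covariances are passed through a Fisher geodesic discriminant
#' filter ([fgda_fit()]) that keeps only class-discriminative tangent
#' variation, then classified by minimum distance to the filtered class
#' Riemannian means. Test covariances are filtered with the same projector
#' before the nearest-mean rule.
#'
#' @param train An [mi_trials()] or covariance set.
#' @param shrinkage Covariance shrinkage.
#' @param reg Discriminant ridge regularization.
#' @return A `dgfmdrm_model` with a [predict()] method.
#' @export
fit_dgfmdrm <- function(train, shrinkage = 1e-3, reg = 1e-3) {
  cs <- as_covariance_set(train, shrinkage)
  assert_two_classes(cs$labels)
  filt <- fgda_fit(cs$covs, cs$labels, reg = reg)
  filtered <- lapply(cs$covs, fgda_apply, filter = filt)
  means <- lapply(c(1L, 2L), function(cl)
    riemannian_mean(filtered[cs$labels == cl]))
  structure(list(filter = filt, means = means, shrinkage = shrinkage),
            class = c("dgfmdrm_model", "mi_decoder"))
}

dgfmdrm_distances <- function(object, x) {
  cs <- as_covariance_set(x, object$shrinkage)
  t(vapply(cs$covs, function(C) {
    Cf <- fgda_apply(object$filter, C)
    c(airm_distance(Cf, object$means[[1]]),
      airm_distance(Cf, object$means[[2]]))
  }, numeric(2)))
}

#' @export
predict.dgfmdrm_model <- function(object, newdata, ...) {
  nearest_label(dgfmdrm_distances(object, newdata))
}

#' Decision fusion of the TSLDA and DGFMDRM decoders
#'
#' Both models score each trial for class 2 on a common `[0, 1]` scale — a
#' logistic of the LDA signed distance, and a softmax of the negative
#' Riemannian distances — and the fused score is their mean; label 2 is
#' assigned when it exceeds 0.5, with exact ties broken toward the class
#' with the smaller Riemannian distance.
#'
#' @param m1 A `tslda_model`.
#' @param m2 A `dgfmdrm_model`.
#' @param trials An [mi_trials()] or covariance set.
#' @return Integer labels in `{1, 2}`.
#' @export
predict_fusion <- function(m1, m2, trials) {
  stopifnot(inherits(m1, "tslda_model"), inherits(m2, "dgfmdrm_model"))
  p1 <- 1 / (1 + exp(-tslda_score(m1, trials)))
  d <- dgfmdrm_distances(m2, trials)
  p2 <- exp(-d[, 2]) / (exp(-d[, 1]) + exp(-d[, 2]))
  fused <- (p1 + p2) / 2
  out <- ifelse(fused > 0.5, 2L, 1L)
  tie <- fused == 0.5
  out[tie] <- ifelse(d[tie, 2] < d[tie, 1], 2L, 1L)
  out
}
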