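test_that("CSP filters whiten the composite covariance and separate planted sources", {
  tr <- separable_trials()
  cf <- strokemi:::csp_filters(tr, n_pairs = 1)
  covs <- strokemi:::trial_covariances(tr)
  covs <- lapply(covs, function(C) C / sum(diag(C)))
  C1 <- Reduce(`+`, covs[tr$labels == 1]) / sum(tr$labels == 1)
  C2 <- Reduce(`+`, covs[tr$labels == 2]) / sum(tr$labels == 2)
  expect_equal(cf$W_full %*% (C1 + C2) %*% t(cf$W_full), diag(4),
               tolerance = 1e-8)

  model <- fit_csp_lda(tr, n_pairs = 1)
  expect_equal(predict(model, tr), tr$labels)   # training accuracy 1.0

  only1 <- subset_trials(tr, which(tr$labels == 1L))
  expect_error(fit_csp_lda(only1), "both classes")
})

test_that("CSP+LDA sits at chance on label-permuted data", {
  tr <- separable_trials(n_per_class = 20)
  set.seed(99)
  tr$labels <- sample(tr$labels)
  res <- cross_validate(function(x) fit_csp_lda(x, n_pairs = 1), tr,
                        folds = 10, seed = 99)
  band <- chance_band(n_trials(tr))
  expect_gte(res$accuracy, band[1] - 0.1)
  expect_lte(res$accuracy, band[2] + 0.1)
})

test_that("FBCSP ranks features from the discriminative band first", {
  # rhythm confined to 10-14 Hz separates the classes
  set.seed(12)
  fs <- 250; n <- 500; n_per <- 12
  labels <- rep(1:2, each = n_per)
  t <- (0:(n - 1)) / fs
  data <- array(rnorm(2 * n_per * 4 * n, sd = 1), dim = c(2 * n_per, 4, n))
  for (i in which(labels == 2))
    data[i, 1, ] <- data[i, 1, ] + 4 * sin(2 * pi * 12 * t + runif(1, 0, 6))
  tr <- mi_trials(data, labels, sample_rate = fs,
                  channel_names = paste0("ch", 1:4))
  bank <- filter_bank(cbind(c(4, 8, 10, 16, 20), c(8, 12, 14, 20, 24)))
  model <- fit_fbcsp_svm(tr, bank, k_features = 4, n_pairs = 1)
  feat_band <- ceiling(model$keep / 2)        # 2 features per band
  overlaps <- bank[feat_band, 1] <= 14 & bank[feat_band, 2] >= 10
  expect_true(all(overlaps))
  expect_equal(predict(model, tr), tr$labels)

  # selecting every feature is the identity selection
  expect_warning(
    m_all <- fit_fbcsp_svm(tr, bank, k_features = 99, n_pairs = 1),
    "clipped")
  expect_equal(m_all$keep, seq_len(2 * nrow(bank)))
})

test_that("MDRM classifies by nearest Riemannian mean with a documented tie-break", {
  cs <- separable_cov_set()
  model <- fit_mdrm(cs)
  expect_equal(predict(model, cs), cs$labels)

  # a trial covariance equal to a class mean is assigned that class
  expect_equal(predict(model, list(covs = model$means[1], labels = 1L)), 1L)
  expect_equal(predict(model, list(covs = model$means[2], labels = 2L)), 2L)

  # equidistant point -> lower label
  m1 <- diag(2); m2 <- diag(c(4, 4))
  pm <- structure(list(means = list(m1, m2), shrinkage = 0),
                  class = c("mdrm_model", "mi_decoder"))
  mid <- diag(c(2, 2))                        # geodesic midpoint
  expect_equal(airm_distance(mid, m1), airm_distance(mid, m2))
  expect_equal(predict(pm, list(covs = list(mid), labels = 1L)), 1L)
})

test_that("TSLDA separates tangent-space clusters and rejects degenerate input", {
  cs <- separable_cov_set()
  model <- fit_tslda(cs)
  expect_equal(predict(model, cs), cs$labels)
  one_each <- list(covs = cs$covs[c(1, 9)], labels = c(1L, 2L))
  expect_error(fit_tslda(one_each), "at least 2")
})

test_that("DGFMDRM filters nuisance variance before the nearest-mean rule", {
  cs <- separable_cov_set(noise = 0.2)
  model <- fit_dgfmdrm(cs)
  expect_equal(predict(model, cs), cs$labels)

  # high-nuisance task: filtering should not hurt relative to plain MDRM
  set.seed(13)
  accs <- replicate(5, {
    tr_set <- separable_cov_set(n_per_class = 10, sep = 1.6, noise = 0.35,
                                seed = sample.int(1e6, 1))
    te_set <- separable_cov_set(n_per_class = 10, sep = 1.6, noise = 0.35,
                                seed = sample.int(1e6, 1))
    c(mean(predict(fit_dgfmdrm(tr_set), te_set) == te_set$labels),
      mean(predict(fit_mdrm(tr_set), te_set) == te_set$labels))
  })
  expect_gte(mean(accs[1, ] - accs[2, ]), 0)
})

test_that("decision fusion agrees with agreeing models and never undercuts both", {
  cs <- separable_cov_set()
  m1 <- fit_tslda(cs)
  m2 <- fit_dgfmdrm(cs)
  p1 <- predict(m1, cs); p2 <- predict(m2, cs)
  fused <- predict_fusion(m1, m2, cs)
  agree <- p1 == p2
  expect_equal(fused[agree], p1[agree])

  set.seed(14)
  for (i in 1:5) {
    tr_set <- separable_cov_set(n_per_class = 8, sep = 1.5, noise = 0.3,
                                seed = sample.int(1e6, 1))
    te_set <- separable_cov_set(n_per_class = 8, sep = 1.5, noise = 0.3,
                                seed = sample.int(1e6, 1))
    m1 <- fit_tslda(tr_set); m2 <- fit_dgfmdrm(tr_set)
    accs <- c(mean(predict(m1, te_set) == te_set$labels),
              mean(predict(m2, te_set) == te_set$labels))
    fused_acc <- mean(predict_fusion(m1, m2, te_set) == te_set$labels)
    expect_gte(fused_acc, min(accs) - 0.13)  # one-trial slack at n = 32
  }
})

test_that("backtracking search recovers planted masks and respects monotone fitness", {
  target_w <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  target_b <- rep(FALSE, 19); target_b[c(3, 11)] <- TRUE
  jaccard_fit <- function(wm, bm) {
    sel <- outer(wm, bm); tgt <- outer(target_w, target_b)
    sum(sel & tgt) / sum(sel | tgt)
  }
  hits <- vapply(1:20, function(s) {
    m <- bsa_select(7, 19, jaccard_fit, seed = s)
    identical(m$window_mask, target_w) && identical(m$band_mask, target_b)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # monotone fitness: more selected is always better -> all-true mask
  mono <- bsa_select(7, 19, function(wm, bm) sum(wm) + sum(bm), seed = 1)
  expect_true(all(mono$window_mask) && all(mono$band_mask))

  # pop = 1, iters = 0: the (repaired) initial mask, reproducibly
  m1 <- bsa_select(7, 19, jaccard_fit, pop = 1, iters = 0, seed = 5,
                   polish = FALSE)
  m2 <- bsa_select(7, 19, jaccard_fit, pop = 1, iters = 0, seed = 5,
                   polish = FALSE)
  expect_identical(m1$window_mask, m2$window_mask)
  expect_identical(m1$band_mask, m2$band_mask)
  expect_true(any(m1$window_mask) && any(m1$band_mask))
})

test_that("LTSA recovers planted planar structure and maps new points", {
  set.seed(15)
  n <- 60
  plane <- matrix(rnorm(n * 2), n)
  basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10)))
  X <- plane %*% t(basis) + matrix(rnorm(n * 10, sd = 1e-3), n)
  red <- ltsa_reduce(X, k_neighbors = 12, d_out = 2)
  # neighborhood ranks preserved vs the oracle plane coordinates
  d_true <- as.vector(dist(plane))
  d_emb <- as.vector(dist(red$embedding))
  expect_gte(cor(d_true, d_emb, method = "spearman"), 0.9)

  # out-of-sample mapping lands near the corresponding training points
  Y2 <- red$map(X[1:5, , drop = FALSE])
  expect_lt(max(sqrt(rowSums((Y2 - red$embedding[1:5, ])^2))), 0.35)

  expect_error(ltsa_reduce(X, d_out = 10), "reduction required")
  expect_error(ltsa_reduce(X, k_neighbors = 2, d_out = 2), "exceed")

  # duplicated points do not break the neighbor search
  Xd <- rbind(X, X[1:3, ])
  expect_silent(ltsa_reduce(Xd, k_neighbors = 12, d_out = 2))

  expect_warning(ltsa_reduce(X[1:8, ], k_neighbors = 12, d_out = 2), "PCA")
})

test_that("the TWFB decoder is deterministic given its seed", {
  rec <- default_subject()$recording
  sp <- split_train_test(rec, 0.6, seed = 4)
  m1 <- fit_twfb_dgfmdm(sp$train, seed = 9, iters = 10)
  m2 <- fit_twfb_dgfmdm(sp$train, seed = 9, iters = 10)
  expect_identical(m1$mask$window_mask, m2$mask$window_mask)
  expect_identical(m1$mask$band_mask, m2$mask$band_mask)
  p1 <- predict(m1, sp$test)
  expect_identical(p1, predict(m2, sp$test))
  expect_true(all(p1 %in% c(1L, 2L)))
  expect_true(any(m1$mask$window_mask) && any(m1$mask$band_mask))
})
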