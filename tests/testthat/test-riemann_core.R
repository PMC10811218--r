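test_that("spatial covariance estimates converge and shrink correctly", {
  set.seed(10)
  T <- 20000
  X <- matrix(rnorm(2 * T), 2)
  C <- spatial_covariance(X, shrinkage = 0)
  expect_lt(abs(C[1, 2]), 3 / sqrt(T))
  expect_equal(diag(C), c(1, 1), tolerance = 3 / sqrt(T))

  # duplicated channel: singular without shrinkage, SPD with it
  Xd <- rbind(X[1, 1:500], X[1, 1:500], X[2, 1:500])
  expect_error(spatial_covariance(Xd, shrinkage = 0), "degenerate")
  Cs <- spatial_covariance(Xd, shrinkage = 1e-3)
  expect_gt(min(eigen(Cs, symmetric = TRUE)$values), 0)

  # full shrinkage is exactly the scaled identity
  C1 <- spatial_covariance(X[, 1:100], shrinkage = 1)
  expect_equal(C1, diag(2) * sum(diag(C1)) / 2, tolerance = 1e-12)
})

test_that("the AIRM distance satisfies its closed forms and axioms", {
  expect_equal(airm_distance(diag(3), exp(2) * diag(3)), 2 * sqrt(3),
               tolerance = 1e-10)
  A <- random_spd(4, seed = 1)
  expect_equal(airm_distance(A, A), 0, tolerance = 1e-7)
  expect_error(airm_distance(A, diag(3)), "dimension")

  set.seed(2)
  for (i in 1:10) {
    A <- random_spd(4); B <- random_spd(4); C <- random_spd(4)
    dab <- airm_distance(A, B)
    # symmetry, triangle inequality
    expect_equal(dab, airm_distance(B, A), tolerance = 1e-8)
    expect_lte(dab, airm_distance(A, C) + airm_distance(C, B) + 1e-9)
    # congruence invariance under a random invertible map
    W <- matrix(rnorm(16), 4) + diag(4)
    expect_equal(airm_distance(W %*% A %*% t(W), W %*% B %*% t(W)), dab,
                 tolerance = 1e-8)
  }
})

test_that("the Frechet mean matches closed forms and minimises the objective", {
  A <- random_spd(3, seed = 3)
  expect_equal(riemannian_mean(list(A)), A)
  expect_equal(riemannian_mean(list(A, A)), A, tolerance = 1e-8)
  expect_equal(riemannian_mean(list(diag(c(1, 1)), diag(c(4, 4)))),
               diag(c(2, 2)), tolerance = 1e-8)

  # commuting (co-diagonalizable) set: mean == exp(mean of logs)
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  logs <- replicate(5, rnorm(4), simplify = FALSE)
  mats <- lapply(logs, function(v) Q %*% diag(exp(v)) %*% t(Q))
  oracle <- Q %*% diag(exp(Reduce(`+`, logs) / 5)) %*% t(Q)
  expect_equal(riemannian_mean(mats), oracle, tolerance = 1e-6)

  # perturbing the mean along random tangent directions raises sum(d^2)
  set.seed(5)
  mats <- replicate(6, random_spd(3), simplify = FALSE)
  G <- riemannian_mean(mats)
  obj <- function(M) sum(vapply(mats, airm_distance, numeric(1), A = M)^2)
  f0 <- obj(G)
  for (i in 1:5) {
    v <- rnorm(6) * 0.05
    expect_gt(obj(inverse_tangent_map(v, G)), f0 - 1e-10)
  }
})

test_that("tangent maps are isometric and invertible", {
  ref <- random_spd(5, seed = 6)
  expect_equal(tangent_map(ref, ref), rep(0, 15), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:5) {
    C <- random_spd(5)
    v <- tangent_map(C, ref)
    expect_length(v, 15L)
    expect_equal(inverse_tangent_map(v, ref), C, tolerance = 1e-9)
    expect_equal(sqrt(sum(v^2)), airm_distance(C, ref), tolerance = 1e-9)
  }
})

test_that("geodesic filtering projects onto the discriminant direction", {
  ref <- diag(3)
  # two classes separated along tangent direction e1, noise along e4
  d <- 6L
  set.seed(8)
  mk <- function(mu) {
    v <- rep(0, d)
    v[1] <- mu + rnorm(1, 0, 0.05)
    v[4] <- rnorm(1, 0, 0.3)
    inverse_tangent_map(v, ref)
  }
  mats <- c(lapply(rep(-1, 6), mk), lapply(rep(1, 6), mk))
  labels <- rep(1:2, each = 6)
  filt <- fgda_fit(mats, labels, ref = ref)

  # projection never moves a matrix farther from the reference
  for (C in mats[1:4]) {
    Cf <- fgda_apply(filt, C)
    expect_lte(airm_distance(Cf, ref), airm_distance(C, ref) + 1e-9)
    # idempotence
    expect_equal(fgda_apply(filt, Cf), Cf, tolerance = 1e-9)
  }

  # within-class scatter along the discarded (noise) direction vanishes
  Vf <- t(vapply(mats, function(C)
    tangent_map(fgda_apply(filt, C), ref), numeric(d)))
  expect_lt(max(abs(Vf[, 4])), 0.1)       # noise axis suppressed
  expect_gt(mean(Vf[labels == 2, 1]) - mean(Vf[labels == 1, 1]), 1)

  expect_error(fgda_fit(mats[1:7], c(1, rep(2, 6))), "at least 2")
})
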