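# Shared fixtures, built once per test run. Sizes are kept small: most unit
# tests need only a handful of trials.

fixture_env <- new.env(parent = emptyenv())

# Memoise expensive fixtures across test files.
fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# Default-difficulty subject (full study-scale epoch structure).
default_subject <- function(seed = 11) {
  fixture(paste0("subj", seed), function()
    generate_subject_recording(NULL, synthetic_config(), seed = seed))
}

# Small recording for I/O tests: canonical channel/sample counts, 8 trials.
small_recording <- function() {
  fixture("small_rec", function()
    generate_subject_recording(
      NULL, synthetic_config(n_trials = 8), seed = 5)$recording)
}

# Hand-built two-class SPD covariance set with separable structure:
# class 2 inflates the variance of the first channel.
separable_cov_set <- function(n_per_class = 8, dim = 4, sep = 3,
                              noise = 0.05, seed = 1) {
  set.seed(seed)
  covs <- list(); labels <- integer(0)
  for (cl in 1:2) for (i in seq_len(n_per_class)) {
    base <- diag(dim)
    if (cl == 2L) base[1, 1] <- sep
    W <- diag(dim) + noise * matrix(rnorm(dim * dim), dim)
    covs[[length(covs) + 1L]] <- W %*% base %*% t(W)
    labels <- c(labels, cl)
  }
  list(covs = covs, labels = labels)
}

# Small separable mi_trials: class 2 has 3x the amplitude on channel 1.
separable_trials <- function(n_per_class = 10, n_ch = 4, n_samp = 250,
                             seed = 2) {
  set.seed(seed)
  labels <- rep(1:2, each = n_per_class)
  data <- array(rnorm(2 * n_per_class * n_ch * n_samp),
                dim = c(2 * n_per_class, n_ch, n_samp))
  data[labels == 2L, 1, ] <- 3 * data[labels == 2L, 1, ]
  mi_trials(data, labels, sample_rate = 250,
            channel_names = paste0("ch", seq_len(n_ch)))
}

random_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

# binomial 95% band around 0.5 for n Bernoulli trials
chance_band <- function(n) 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n)
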