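# The proposed decoder: optimal time-window and filter-bank selection by
# backtracking search, per-(window, band) spatial covariances forming the
# matrix set M, tangent-space features reduced by local tangent space
# alignment, and a discriminant filter with nearest-class-centroid
# classification in the reduced space.

#' Construct a time-window specification
#'
#' The default seven 1-s windows slide in 0.5-s steps over the 0-4 s
#' motor-imagery period (times relative to MI onset).
#'
#' @param windows Two-column matrix or list of `(start, end)` pairs in
#'   seconds relative to MI onset; all inside `[0, 4]`.
#' @return A `time_windows` object (two-column matrix).
#' @export
time_windows <- function(windows = cbind(seq(0, 3, 0.5), seq(1, 4, 0.5))) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (any(windows[, 1] >= windows[, 2]) || any(windows < 0) ||
      any(windows > 4))
    stop("windows must satisfy start < end and lie inside [0, 4] s",
         call. = FALSE)
  colnames(windows) <- c("start", "end")
  structure(windows, class = c("time_windows", class(windows)))
}

mask_key <- function(wm, bm) paste(c(as.integer(wm), as.integer(bm)),
                                   collapse = "")

# Repair an all-empty window or band mask by switching on the single
# candidate with the best univariate fitness (other part all-on if empty).
repair_mask <- function(wm, bm, fitness) {
  if (!any(wm)) {
    probe_b <- if (any(bm)) bm else rep(TRUE, length(bm))
    scores <- vapply(seq_along(wm), function(i) {
      w <- rep(FALSE, length(wm)); w[i] <- TRUE
      fitness(w, probe_b)
    }, numeric(1))
    wm[which.max(scores)] <- TRUE
  }
  if (!any(bm)) {
    scores <- vapply(seq_along(bm), function(i) {
      b <- rep(FALSE, length(bm)); b[i] <- TRUE
      fitness(wm, b)
    }, numeric(1))
    bm[which.max(scores)] <- TRUE
  }
  list(wm = wm, bm = bm)
}

#' Select time windows and filter bands by backtracking search
#'
#' Binary selection over the window/band grid using the backtracking search
#' optimization algorithm (BSA): a population of real-coded genomes in
#' `[0, 1]` evolves via the historical-population mutation
#' `mutant = P + F (oldP - P)` and map-based crossover, thresholded at 0.5
#' into masks. All-empty window or band masks are repaired to the single
#' best univariate candidate. After the evolutionary loop the best mask is
#' polished by greedy single-bit flips until locally optimal. Deterministic
#' given `seed`; fitness evaluations are memoized.
#'
#' @param candidate_windows A [time_windows()] (or its row count).
#' @param candidate_bands A [filter_bank()] (or its row count).
#' @param fitness_fn Function `(window_mask, band_mask) -> scalar` to
#'   maximise, e.g. cross-validated training accuracy.
#' @param pop Population size.
#' @param iters Number of BSA generations.
#' @param seed Integer seed.
#' @param mix_rate Crossover mix rate (fraction of dimensions taken from the
#'   mutant).
#' @param polish Run the greedy bit-flip refinement of the final mask.
#' @return A `selection_mask`: list with logical `window_mask`, `band_mask`
#'   and the achieved `fitness`.
#' @export
bsa_select <- function(candidate_windows, candidate_bands, fitness_fn,
                       pop = 20, iters = 50, seed = 1, mix_rate = 1,
                       polish = TRUE) {
  n_w <- if (is.matrix(candidate_windows)) nrow(candidate_windows) else
    as.integer(candidate_windows)
  n_b <- if (is.matrix(candidate_bands)) nrow(candidate_bands) else
    as.integer(candidate_bands)
  D <- n_w + n_b
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fit_raw <- function(wm, bm) {
    key <- mask_key(wm, bm)
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals <<- evals + 1L
    val <- fitness_fn(wm, bm)
    cache[[key]] <- val
    val
  }
  # fitness of a genome: threshold, repair, evaluate
  fit_genome <- function(x) {
    wm <- x[seq_len(n_w)] > 0.5
    bm <- x[n_w + seq_len(n_b)] > 0.5
    if (!any(wm) || !any(bm)) {
      r <- repair_mask(wm, bm, fit_raw)
      wm <- r$wm; bm <- r$bm
    }
    list(fit = fit_raw(wm, bm), wm = wm, bm = bm)
  }
  with_seed(seed, {
    P <- matrix(runif(pop * D), pop, D)
    # bias half of the initial population toward sparse masks: with a
    # parsimony-penalised fitness the optima are sparse, and uniform
    # genomes start at ~D/2 selected bits
    sparse <- seq_len(pop %/% 2)
    P[sparse, ] <- P[sparse, , drop = FALSE]^2
    oldP <- matrix(runif(pop * D), pop, D)
    evalP <- lapply(seq_len(pop), function(i) fit_genome(P[i, ]))
    fitP <- vapply(evalP, `[[`, numeric(1), "fit")
    best <- evalP[[which.max(fitP)]]
    iter <- 0L
    while (iter < iters) {
      iter <- iter + 1L
      if (runif(1) < 0.5) oldP <- P
      oldP <- oldP[sample.int(pop), , drop = FALSE]
      F <- 3 * rnorm(1)
      M <- P + F * (oldP - P)
      # map-based crossover
      Tn <- P
      for (i in seq_len(pop)) {
        if (runif(1) < 0.5) {
          k <- max(1L, ceiling(mix_rate * runif(1) * D))
          dims <- sample.int(D, k)
        } else {
          dims <- sample.int(D, 1L)
        }
        Tn[i, dims] <- M[i, dims]
      }
      # boundary control: regenerate out-of-range genes
      bad <- Tn < 0 | Tn > 1
      Tn[bad] <- runif(sum(bad))
      for (i in seq_len(pop)) {
        cand <- fit_genome(Tn[i, ])
        if (cand$fit > fitP[i]) {
          P[i, ] <- Tn[i, ]
          fitP[i] <- cand$fit
          if (cand$fit > best$fit) best <- cand
        }
      }
    }
    if (polish) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (d in seq_len(D)) {
          wm <- best$wm; bm <- best$bm
          if (d <= n_w) wm[d] <- !wm[d] else bm[d - n_w] <- !bm[d - n_w]
          if (!any(wm) || !any(bm)) next
          f <- fit_raw(wm, bm)
          if (f > best$fit) {
            best <- list(fit = f, wm = wm, bm = bm)
            improved <- TRUE
          }
        }
      }
    }
  })
  structure(list(window_mask = best$wm, band_mask = best$bm,
                 fitness = best$fit, evaluations = evals),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask: %d/%d windows, %d/%d bands; fitness %.3f>\n",
              sum(x$window_mask), length(x$window_mask),
              sum(x$band_mask), length(x$band_mask), x$fitness))
  invisible(x)
}

#' Local tangent space alignment dimensionality reduction
#'
#' Nonlinear embedding that aligns local PCA frames of each point's
#' neighborhood (point included). Out-of-sample points are mapped through
#' locally-linear barycentric weights of their `k_neighbors` nearest
#' training points.
#'
#' @param vectors Numeric `n x D` matrix of feature vectors.
#' @param k_neighbors Neighborhood size (point itself included); must be at
#'   least `d_out + 1`.
#' @param d_out Output dimension; must be smaller than `D`. When `n` is too
#'   small for meaningful neighborhoods the function falls back to PCA with
#'   a warning.
#' @return List with `embedding` (`n x d_out`) and `map`, a function taking
#'   a `m x D` matrix to `m x d_out` embedded coordinates.
#' @export
ltsa_reduce <- function(vectors, k_neighbors = 12, d_out = 10) {
  X <- as.matrix(vectors)
  n <- nrow(X); D <- ncol(X)
  if (d_out >= D)
    stop("d_out must be smaller than the input dimension (reduction required)",
         call. = FALSE)
  if (k_neighbors <= d_out)
    stop("k_neighbors must exceed d_out", call. = FALSE)
  dmat <- as.matrix(stats::dist(X))
  knn_of <- function(drow, k) order(drow)[seq_len(k)]  # ties broken by index

  if (n < k_neighbors + 1L) {
    warning("too few points for LTSA neighborhoods; falling back to PCA",
            call. = FALSE)
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr), nu = 0, nv = d_out)
    V <- sv$v
    Y <- sweep(X, 2, ctr) %*% V
    return(list(embedding = Y,
                map = function(newX)
                  sweep(as.matrix(newX), 2, ctr) %*% V,
                method = "pca"))
  }

  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Ni <- knn_of(dmat[i, ], k_neighbors)
    Xi <- X[Ni, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    sv <- svd(Xi, nu = min(d_out, k_neighbors), nv = 0)
    Gi <- cbind(1 / sqrt(k_neighbors), sv$u[, seq_len(d_out), drop = FALSE])
    B[Ni, Ni] <- B[Ni, Ni] + diag(k_neighbors) - tcrossprod(Gi)
  }
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  idx <- order(e$values)[2:(d_out + 1L)]           # skip the constant vector
  Y <- e$vectors[, idx, drop = FALSE] * sqrt(n)

  oos_map <- function(newX) {
    newX <- as.matrix(newX)
    out <- matrix(0, nrow(newX), d_out)
    for (j in seq_len(nrow(newX))) {
      dists <- colSums((t(X) - newX[j, ])^2)
      Ni <- knn_of(dists, k_neighbors)
      Z <- sweep(X[Ni, , drop = FALSE], 2, newX[j, ])
      G <- tcrossprod(Z)
      G <- G + diag(k_neighbors) * (sum(diag(G)) * 1e-3 + 1e-12)
      w <- solve(G, rep(1, k_neighbors))
      w <- w / sum(w)
      out[j, ] <- colSums(w * Y[Ni, , drop = FALSE])
    }
    out
  }
  list(embedding = Y, map = oos_map, method = "ltsa")
}

# ---- TWFB + DGFMDM ---------------------------------------------------------

# Per-(window, band) covariance sets and tangent features for a recording.
# Returns nested lists indexed [[band]][[window]].
twfb_features <- function(rec, windows, bank, mi_onset = 2.0,
                          shrinkage = 1e-3, mean_tol = 1e-5,
                          mean_iter = 5, refs = NULL,
                          bands_used = seq_len(nrow(bank)),
                          windows_used = seq_len(nrow(windows))) {
  eeg <- eeg_trials(rec)
  d <- dim(eeg$data)
  fs <- eeg$sample_rate
  # samples x (channels * trials), trial-major column blocks
  big <- matrix(aperm(eeg$data, c(3, 2, 1)), nrow = d[3])
  n_w <- nrow(windows); n_b <- nrow(bank)
  covs <- refs_out <- tang <- vector("list", n_b)
  for (b in bands_used) {
    # order-4 skirts keep neighbouring 4-Hz cells spectrally distinct
    bt <- signal::butter(4, bank[b, ] / (fs / 2), type = "pass")
    Xf <- .zerophase_filter_cpp(bt$b, bt$a, big,
                                3L * (length(bt$a) - 1L))
    covs[[b]] <- refs_out[[b]] <- tang[[b]] <- vector("list", n_w)
    for (w in windows_used) {
      i0 <- round((mi_onset + windows[w, 1]) * fs)       # 0-based
      i1 <- round((mi_onset + windows[w, 2]) * fs) - 1L
      if (i0 < 0L || i1 >= d[3])
        stop("window falls outside the epoch", call. = FALSE)
      cw <- .window_covs_cpp(Xf, d[2], i0, i1, shrinkage)
      # trace normalization: 500-sample narrow-band SCMs are dominated by
      # burst/amplitude variability, which carries no class information
      cw <- lapply(cw, function(C) C * (d[2] / sum(diag(C))))
      ref <- if (is.null(refs)) {
        .riemannian_mean_cpp(cw, mean_tol, mean_iter)$mean
      } else refs[[b]][[w]]
      covs[[b]][[w]] <- cw
      refs_out[[b]][[w]] <- ref
      tang[[b]][[w]] <- tangent_coordinates(cw, ref)
    }
  }
  list(covs = covs, refs = refs_out, tangent = tang)
}

# Principal-component scores via the Gram matrix (fast for wide matrices).
pca_scores <- function(X, r) {
  Xc <- sweep(X, 2, colMeans(X))
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  r <- min(r, sum(e$values > max(e$values) * 1e-12))
  e$vectors[, seq_len(r), drop = FALSE] *
    rep(sqrt(pmax(e$values[seq_len(r)], 0)), each = nrow(X))
}

selected_pairs <- function(window_mask, band_mask) {
  expand.grid(w = which(window_mask), b = which(band_mask))
}

# Concatenate per-(window, band) tangent blocks; each block is scaled so
# its total variance (computed on the fitting data and reused at predict
# time) is 1 — otherwise high-variance nuisance cells dominate the
# geometry of the concatenated feature space.
concat_tangent <- function(tang, pairs, scales = NULL) {
  blocks <- lapply(seq_len(nrow(pairs)), function(k) {
    V <- tang[[pairs$b[k]]][[pairs$w[k]]]
    if (!is.null(scales)) V * scales[k] else V
  })
  do.call(cbind, blocks)
}

block_scales <- function(tang, pairs) {
  vapply(seq_len(nrow(pairs)), function(k) {
    V <- tang[[pairs$b[k]]][[pairs$w[k]]]
    tv <- sum(apply(V, 2, var))
    if (tv > 0) 1 / sqrt(tv) else 1
  }, numeric(1))
}

stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Fit the time-window/filter-bank discriminant-geometry Riemannian decoder
#'
#' The proposed pipeline: (1) build the grid of candidate time windows and
#' filter bands; (2) select windows and bands with [bsa_select()], the
#' fitness being 5-fold cross-validated training accuracy of a fast
#' tangent-space discriminant surrogate; (3) form the covariance matrix set
#' M from the selected (window, band) pairs — kept as per-pair blocks, whose
#' tangent coordinates concatenate exactly as a block-diagonal matrix's
#' would; (4) reduce the concatenated tangent features with [ltsa_reduce()];
#' (5) apply a Fisher discriminant filter in the reduced space and classify
#' by minimum distance to the class centroids.
#'
#' @param train An [mi_recording()] with raw (broadband) epochs.
#' @param windows A [time_windows()].
#' @param bank A [filter_bank()].
#' @param seed Integer seed driving the selection search and fold
#'   assignment.
#' @param pop,iters BSA population size and generations.
#' @param fitness_folds Folds for the selection fitness.
#' @param d_out,k_neighbors LTSA output dimension and neighborhood size.
#' @param shrinkage Covariance shrinkage.
#' @param pca_rank Per-pair PCA rank for the selection surrogate.
#' @param cell_penalty Fitness penalty per selected window or band;
#'   standard parsimony pressure against accumulating cells the noisy
#'   cross-validated fitness cannot reject.
#' @param fitness_reps Number of independently-seeded cross-validation
#'   repetitions averaged into the selection fitness.
#' @param mi_onset MI onset within the epoch, seconds.
#' @param pool `"block"` keeps per-pair covariance blocks (default);
#'   `"average"` pools the selected pairs' covariances into a single matrix
#'   per trial.
#' @return A `twfb_dgfmdm` model with a [predict()] method.
#' @export
fit_twfb_dgfmdm <- function(train, windows = time_windows(),
                            bank = filter_bank(), seed = 1,
                            pop = 20, iters = 50, fitness_folds = 5,
                            d_out = 10, k_neighbors = 12,
                            shrinkage = 1e-3, pca_rank = 6,
                            cell_penalty = 0.01, fitness_reps = 10,
                            mi_onset = 2.0,
                            pool = c("block", "average")) {
  pool <- match.arg(pool)
  assert_two_classes(train$labels)
  n <- n_trials(train)
  feats <- twfb_features(train, windows, bank, mi_onset, shrinkage)

  # per-pair PCA compression for the selection fitness, laid out as one
  # big score matrix so a mask selects contiguous column blocks
  r <- as.integer(min(pca_rank, n - 2L))
  n_w <- nrow(windows); n_b <- nrow(bank)
  scores <- matrix(0, n, n_w * n_b * r)
  for (b in seq_len(n_b)) for (w in seq_len(n_w)) {
    sc <- pca_scores(feats$tangent[[b]][[w]], r)
    tv <- sum(apply(sc, 2, var))
    if (tv > 0) sc <- sc / sqrt(tv)          # unit total variance per cell
    k0 <- ((b - 1L) * n_w + (w - 1L)) * r
    scores[, k0 + seq_len(ncol(sc))] <- sc
  }
  # several independent fold assignments are averaged to shrink the
  # fitness variance (the search compares ~10^3 masks, so the argmax of a
  # noisy estimate is strongly optimistic); a parsimony penalty on the
  # number of selected windows and bands keeps masks small
  folds_rep <- vapply(seq_len(fitness_reps), function(k)
    stratified_folds(train$labels, fitness_folds, child_seed(seed, k)),
    integer(n))
  fitness <- function(wm, bm) {
    pairs <- selected_pairs(wm, bm)
    cols <- as.vector(vapply(seq_len(nrow(pairs)), function(k)
      ((pairs$b[k] - 1L) * n_w + (pairs$w[k] - 1L)) * r + seq_len(r),
      integer(r)))
    acc <- .surrogate_cv_cpp(scores[, cols, drop = FALSE],
                             train$labels, folds_rep, 8L, 1e-3)
    acc - cell_penalty * (sum(wm) + sum(bm))
  }
  mask <- bsa_select(windows, bank, fitness, pop = pop, iters = iters,
                     seed = child_seed(seed, 2L))

  pairs <- selected_pairs(mask$window_mask, mask$band_mask)
  if (pool == "average") {
    pooled <- lapply(seq_len(n), function(i)
      Reduce(`+`, lapply(seq_len(nrow(pairs)), function(k)
        feats$covs[[pairs$b[k]]][[pairs$w[k]]][[i]])) / nrow(pairs))
    ref <- riemannian_mean(pooled, tol = 1e-6, max_iter = 20)
    Vfull <- tangent_coordinates(pooled, ref)
    refs <- ref
  } else {
    scales <- block_scales(feats$tangent, pairs)
    Vfull <- concat_tangent(feats$tangent, pairs, scales)
    refs <- feats$refs
  }
  # lossless PCA pre-projection onto the training span: neighborhoods and
  # distances are preserved exactly while the alignment and out-of-sample
  # steps work in at most n - 1 stable dimensions
  ctr <- colMeans(Vfull)
  Vc <- sweep(Vfull, 2, ctr)
  sv <- svd(Vc, nu = 0)
  p <- max(min(n - 1L, sum(sv$d > sv$d[1] * 1e-10)), 2L)
  proj <- sv$v[, seq_len(p), drop = FALSE]
  Z <- Vc %*% proj

  d_use <- min(d_out, ncol(Z) - 1L, n - 2L)
  k_use <- max(min(k_neighbors, n - 1L), d_use + 1L)
  red <- ltsa_reduce(Z, k_neighbors = k_use, d_out = d_use)
  fd <- fisher_direction(red$embedding, train$labels)
  z <- as.vector(red$embedding %*% fd$w)
  centroids <- c(mean(z[train$labels == 1L]), mean(z[train$labels == 2L]))

  structure(list(windows = windows, bank = bank, mask = mask,
                 pairs = pairs, refs = refs,
                 scales = if (pool == "block") scales else NULL,
                 center = ctr, proj = proj,
                 reduce = red, w = fd$w,
                 centroids = centroids, pool = pool, shrinkage = shrinkage,
                 mi_onset = mi_onset, seed = seed),
            class = c("twfb_dgfmdm", "mi_decoder"))
}

#' @export
predict.twfb_dgfmdm <- function(object, newdata, ...) {
  n <- n_trials(newdata)
  pairs <- object$pairs
  feats <- twfb_features(newdata, object$windows, object$bank,
                         object$mi_onset, object$shrinkage,
                         refs = if (object$pool == "block") object$refs else
                           NULL,
                         bands_used = sort(unique(pairs$b)),
                         windows_used = sort(unique(pairs$w)))
  V <- if (object$pool == "average") {
    pooled <- lapply(seq_len(n), function(i)
      Reduce(`+`, lapply(seq_len(nrow(pairs)), function(k)
        feats$covs[[pairs$b[k]]][[pairs$w[k]]][[i]])) / nrow(pairs))
    tangent_coordinates(pooled, object$refs)
  } else {
    concat_tangent(feats$tangent, pairs, object$scales)
  }
  Z <- sweep(V, 2, object$center) %*% object$proj
  z <- as.vector(object$reduce$map(Z) %*% object$w)
  ifelse(abs(z - object$centroids[2]) < abs(z - object$centroids[1]), 2L, 1L)
}
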