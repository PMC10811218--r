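# Geometry of symmetric positive-definite (SPD) spatial covariance matrices
# under the affine-invariant Riemannian metric (AIRM): covariance
# estimation, distances, Frechet means, tangent-space coordinates and Fisher
# geodesic discriminant filtering. Heavy matrix functions run in compiled
# code via a symmetric eigendecomposition with a 1e-12 eigenvalue floor.

assert_spd_dim <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("SPD matrices have mismatched dimensions", call. = FALSE)
}

#' Spatial covariance matrix of one trial
#'
#' Sample covariance `X Xᵀ / (T - 1)` of the mean-removed multichannel
#' signal, shrunk toward `(trace/n) I` by factor `lambda` to keep filtered
#' narrow-band covariances positive-definite.
#'
#' @param trial Numeric `channels x samples` matrix.
#' @param shrinkage Shrinkage weight `lambda` in `[0, 1]`.
#' @param check Verify positive-definiteness of the result (skipped on
#'   internal hot paths where `shrinkage > 0` already guarantees it).
#' @return SPD matrix (`channels x channels`).
#' @export
spatial_covariance <- function(trial, shrinkage = 1e-3, check = TRUE) {
  stopifnot(is.matrix(trial), ncol(trial) > 1, shrinkage >= 0, shrinkage <= 1)
  C <- .cov_shrink_cpp(trial, shrinkage)
  if (check) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * .Machine$double.eps * nrow(C))
      stop("degenerate trial covariance (rank-deficient data); ",
           "use shrinkage > 0", call. = FALSE)
  }
  C
}

# Covariance per trial of an mi_trials object -> list of SPD matrices.
trial_covariances <- function(trials, shrinkage = 1e-3) {
  lapply(seq_len(n_trials(trials)), function(i)
    spatial_covariance(trials$data[i, , ], shrinkage,
                       check = shrinkage == 0))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(A, B) = || log(A^{-1/2} B A^{-1/2}) ||_F`; symmetric, zero iff
#' `A == B`, and invariant under congruence `A -> W A Wᵀ`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Non-negative scalar distance.
#' @export
airm_distance <- function(A, B) {
  assert_spd_dim(A, B)
  .airm_dist_cpp(A, B)
}

#' Riemannian (Frechet) mean of a set of SPD matrices
#'
#' The fixed point of the gradient iteration
#' `G <- G^{1/2} exp(mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}`, i.e. the
#' matrix minimising the sum of squared AIRM distances to the set.
#'
#' @param mats List of SPD matrices.
#' @param tol Convergence tolerance on the Frobenius norm of the update.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with a warning.
#' @return SPD mean matrix.
#' @export
riemannian_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  if (!length(mats)) stop("empty matrix set", call. = FALSE)
  if (length(mats) == 1L) return(mats[[1]])
  res <- .riemannian_mean_cpp(mats, tol, max_iter)
  if (!res$converged)
    warning(sprintf("Riemannian mean did not converge in %d iterations (residual %.2e)",
                    max_iter, res$crit), call. = FALSE)
  res$mean
}

#' Map an SPD matrix to tangent-space coordinates
#'
#' Half-vectorization (column-major upper triangle, off-diagonal entries
#' scaled by sqrt(2)) of `log(ref^{-1/2} C ref^{-1/2})`, so the Euclidean
#' norm of the coordinates equals `airm_distance(C, ref)`.
#'
#' @param C SPD matrix to map.
#' @param ref SPD reference (tangent) point.
#' @return Numeric vector of length `n (n + 1) / 2`.
#' @export
tangent_map <- function(C, ref) {
  assert_spd_dim(C, ref)
  as.vector(.tangent_vecs_cpp(list(C), ref))
}

#' Map tangent-space coordinates back to the SPD manifold
#'
#' Inverse of [tangent_map()].
#'
#' @param v Tangent coordinates (length `n (n + 1) / 2`).
#' @param ref SPD reference point used for the forward map.
#' @return SPD matrix.
#' @export
inverse_tangent_map <- function(v, ref) {
  n <- nrow(ref)
  if (length(v) != n * (n + 1) / 2)
    stop("tangent vector length does not match the reference dimension",
         call. = FALSE)
  S <- matrix(0, n, n)
  S[upper.tri(S, diag = TRUE)] <- v
  off <- upper.tri(S)
  S[off] <- S[off] / sqrt(2)
  S <- S + t(S) - diag(diag(S))
  E <- .spd_fun_cpp(S, "exp")
  R <- .spd_fun_cpp(ref, "sqrt")
  R %*% E %*% R
}

# Tangent coordinates for a list of SPD matrices (rows = matrices).
tangent_coordinates <- function(mats, ref) .tangent_vecs_cpp(mats, ref)

# Regularized Fisher discriminant direction for a 2-class problem in
# Euclidean coordinates; returns the within-class-whitened direction and the
# class means. reg scales the ridge added to the within-class scatter.
# When the dimension exceeds the sample count the discriminant is computed
# in the (lossless) PCA subspace spanned by the data and mapped back — the
# standard small-sample LDA construction.
fisher_direction <- function(X, labels, reg = 1e-3, pmax = 20) {
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2L)
  n <- nrow(X)
  if (ncol(X) > n - 2L) {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    p <- max(min(n - 2L, pmax, sum(e$values > max(e$values) * 1e-10)), 1L)
    lam <- e$values[seq_len(p)]
    U <- e$vectors[, seq_len(p), drop = FALSE]
    B <- crossprod(Xc, U) %*% diag(1 / sqrt(lam), p)
    fd <- fisher_direction(Xc %*% B, labels, reg)
    w <- B %*% fd$w
    w <- w / sqrt(sum(w^2))
    return(list(w = as.vector(w),
                m1 = colMeans(X[labels == cls[1], , drop = FALSE]),
                m2 = colMeans(X[labels == cls[2], , drop = FALSE]),
                classes = cls))
  }
  m1 <- colMeans(X[labels == cls[1], , drop = FALSE])
  m2 <- colMeans(X[labels == cls[2], , drop = FALSE])
  Sw <- matrix(0, ncol(X), ncol(X))
  for (cl in cls) {
    Xi <- X[labels == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / (nrow(X) - 2L)
  gamma <- reg * mean(diag(Sw)) + 1e-12
  w <- solve(Sw + diag(gamma, ncol(X)), m2 - m1)
  w <- w / sqrt(sum(w^2))
  list(w = w, m1 = m1, m2 = m2, classes = cls)
}

#' Fit a Fisher geodesic discriminant filter
#'
#' Maps the training covariances to the tangent space at `ref`, fits a
#' (regularized) Fisher discriminant, and builds the rank-`k` orthogonal
#' projector onto the discriminant direction(s) in tangent coordinates.
#' Applying the filter projects a matrix's tangent coordinates and maps them
#' back to the manifold, discarding non-discriminative variation.
#'
#' @param mats List of SPD training matrices.
#' @param labels Integer class labels in `{1, 2}`, one per matrix.
#' @param ref SPD reference point; defaults to the Riemannian mean of
#'   `mats`.
#' @param reg Ridge regularization for the within-class scatter.
#' @return An object of class `geodesic_filter`.
#' @export
fgda_fit <- function(mats, labels, ref = NULL, reg = 1e-3) {
  labels <- as.integer(labels)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 matrices", call. = FALSE)
  if (is.null(ref)) ref <- riemannian_mean(mats)
  V <- tangent_coordinates(mats, ref)
  fd <- fisher_direction(V, labels, reg)
  structure(list(ref = ref, w = fd$w, rank = 1L, reg = reg),
            class = "geodesic_filter")
}

#' Apply a Fisher geodesic discriminant filter to an SPD matrix
#'
#' @param filter A `geodesic_filter` from [fgda_fit()].
#' @param C SPD matrix to filter.
#' @return Filtered SPD matrix.
#' @export
fgda_apply <- function(filter, C) {
  v <- tangent_map(C, filter$ref)
  proj <- filter$w * sum(filter$w * v)
  inverse_tangent_map(proj, filter$ref)
}
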