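# Per-sample influence on the FID: derivative of a softmax-weighted FID
# with respect to per-sample logits, evaluated at uniform weights. A sample
# with a positive gradient worsens the distance when upweighted (negative
# influence); a negative gradient marks a helpful sample.

#' Softmax-weighted sample moments
#'
#' Weights are `w = softmax(logits)`; the weighted mean is `sum_i w_i x_i`
#' and the weighted covariance `sum_i w_i (x_i - mu(w))(x_i - mu(w))^T`.
#' With equal logits this reduces exactly to the 1/N moments of
#' [fit_gaussian()].
#'
#' @param E Embedding matrix (N >= 2 rows).
#' @param logits N real logits.
#' @return Object of class `weighted_moments` with fields `logits`,
#'   `weights`, `mean`, `covariance`.
#' @export
weighted_moments <- function(E, logits) {
  E <- .as_embedding(E)
  N <- nrow(E)
  if (N < 2L) stop("weighted moments need at least 2 samples")
  if (length(logits) != N) stop("one logit per row required")
  u <- logits - max(logits)
  w <- exp(u) / sum(exp(u))
  X <- unclass(E)
  mu <- as.numeric(crossprod(w, X))
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc)
  S <- (S + t(S)) / 2
  structure(list(logits = as.numeric(logits), weights = as.numeric(w),
                 mean = mu, covariance = S),
            class = "weighted_moments")
}

#' Influence gradients of the FID over an evaluation sample
#'
#' Differentiates the closed-form Gaussian 2-Wasserstein distance between
#' the softmax-weighted evaluation moments and a fixed reference Gaussian
#' with respect to the per-sample logits, evaluated at uniform weights
#' (logits all zero). The matrix square root is differentiated through the
#' symmetric eigendecomposition route, giving the closed form
#' `g_i = w_i (h_i - sum_j w_j h_j)` with
#' `h_i = 2 (mu - mu_ref) . x_i + (x_i - mu)^T G (x_i - mu)`,
#' `G = I - S_ref^{1/2} M^{-1/2} S_ref^{1/2}`, `M = S_ref^{1/2} S S_ref^{1/2}`.
#' When both inputs are raw embeddings a joint PCA at dimension `d` is
#' applied first with the basis held fixed during differentiation.
#'
#' @param E_eval Evaluation embedding matrix (or `structure_set`).
#' @param ref Reference: [gaussian_summary()] (no projection applied) or an
#'   embedding matrix / `structure_set` (joint PCA applied when `d` < p).
#' @param d Projection dimension used when `ref` is an embedding input.
#' @param embedder Embedder for structure inputs.
#' @param fd_check Spot-check the analytic gradient against central finite
#'   differences (h = 1e-5) on up to 5 coordinates and error if they
#'   disagree by more than 1e-3 relative.
#' @param eigen_floor Eigenvalue floor used when inverting the matrix square
#'   root (guards near-singular covariances).
#' @return Object of class `influence_report` with per-sample `gradients`
#'   (named by id, summing to 0), `ranking` (ids most-harmful first),
#'   `positive_influence_ids`, `negative_influence_ids` and `neutral_ids`
#'   (|gradient| < 1e-9).
#' @export
fid_influence <- function(E_eval, ref, d = NULL,
                          embedder = geometric_featurize, fd_check = FALSE,
                          eigen_floor = 1e-12) {
  E_eval <- .as_embedding(E_eval, embedder)
  if (inherits(ref, "gaussian_summary")) {
    if (length(ref$mean) != ncol(E_eval))
      stop("reference dimension does not match the evaluation embeddings")
    Y <- unclass(E_eval)
    ref_gauss <- ref
  } else {
    E_ref <- .as_embedding(ref, embedder)
    if (is.null(d)) d <- min(32L, ncol(E_ref))
    basis <- fit_joint_pca(E_ref, E_eval, d)
    Y <- unclass(project(E_eval, basis))
    ref_gauss <- fit_gaussian(project(E_ref, basis))
  }
  N <- nrow(Y)
  if (N < 2L) stop("influence needs at least 2 evaluation samples")
  h <- .influence_h(Y, ref_gauss, eigen_floor)
  w <- rep(1 / N, N)
  grads <- w * (h - sum(w * h))
  if (fd_check) {
    idx <- unique(round(seq(1, N, length.out = min(5L, N))))
    fd <- vapply(idx, function(i) .fid_of_logits_fd(Y, ref_gauss, i), numeric(1))
    rel <- abs(fd - grads[idx]) / max(sqrt(sum(grads^2)), 1e-12)
    if (any(!is.finite(rel)) || max(rel) > 1e-3)
      stop("analytic influence gradient failed the finite-difference check")
  }
  names(grads) <- rownames(E_eval)
  ord <- order(grads, decreasing = TRUE)
  neutral <- abs(grads) < 1e-9
  structure(
    list(gradients = grads,
         ranking = names(grads)[ord],
         positive_influence_ids = names(grads)[grads < 0 & !neutral],
         negative_influence_ids = names(grads)[grads > 0 & !neutral],
         neutral_ids = names(grads)[neutral]),
    class = "influence_report"
  )
}

#' dFID/dw_i at the uniform point (free-weight derivative)
#' @noRd
.influence_h <- function(Y, ref_gauss, eigen_floor = 1e-12) {
  N <- nrow(Y)
  wm <- weighted_moments(embedding_matrix(Y, ids = seq_len(N)), rep(0, N))
  mu <- wm$mean; S <- wm$covariance
  A <- .sym_sqrt(ref_gauss$covariance)
  M <- A %*% S %*% A
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  inv_sqrt <- e$vectors %*% ((1 / sqrt(pmax(e$values, eigen_floor))) *
                               t(e$vectors))
  G <- diag(ncol(Y)) - A %*% inv_sqrt %*% A
  dmu <- mu - ref_gauss$mean
  Yc <- sweep(Y, 2, mu)
  2 * as.numeric(Y %*% dmu) + rowSums((Yc %*% G) * Yc)
}

#' Central finite difference of the weighted FID wrt logit i
#' @noRd
.fid_of_logits_fd <- function(Y, ref_gauss, i, h = 1e-5) {
  f <- function(logits) {
    wm <- weighted_moments(embedding_matrix(Y, ids = seq_len(nrow(Y))), logits)
    as.numeric(frechet_gaussian_distance(
      gaussian_summary(wm$mean, wm$covariance), ref_gauss))
  }
  u <- rep(0, nrow(Y))
  up <- u; up[i] <- h
  dn <- u; dn[i] <- -h
  (f(up) - f(dn)) / (2 * h)
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf(
    "<influence_report> %d samples: %d harmful (grad > 0), %d helpful, %d neutral\n",
    length(x$gradients), length(x$negative_influence_ids),
    length(x$positive_influence_ids), length(x$neutral_ids)))
  top <- utils::head(x$ranking, 5L)
  cat("most harmful:", paste(top, collapse = ", "), "\n")
  invisible(x)
}
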