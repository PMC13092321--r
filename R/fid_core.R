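# The metric itself: Gaussian moment fits, the closed-form 2-Wasserstein
# distance between Gaussians, and the joint-PCA projection applied before
# the distance is taken.

#' Gaussian summary of an embedded sample
#'
#' @param mean Mean p-vector.
#' @param covariance p x p symmetric matrix (PSD up to roundoff).
#' @param n Sample count the moments were estimated from.
#' @return Object of class `gaussian_summary`.
#' @export
gaussian_summary <- function(mean, covariance, n = NA_integer_) {
  covariance <- as.matrix(covariance)
  p <- length(mean)
  if (!all(dim(covariance) == c(p, p)))
    stop("covariance must be p x p")
  if (!all(is.finite(mean)) || !all(is.finite(covariance)))
    stop("non-finite moments")
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric (within 1e-8)")
  structure(list(mean = as.numeric(mean), covariance = covariance, n = n),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> p = %d, n = %s\n", length(x$mean),
              format(x$n)))
  invisible(x)
}

#' Fit a Gaussian to an embedding matrix
#'
#' Mean is the row average; the covariance uses the biased 1/N normalization
#' (each sample weighted 1/N around the sample mean), the convention the
#' distance is defined with. Set `unbiased = TRUE` for the 1/(N-1) variant.
#'
#' @param E An [embedding_matrix()] or numeric matrix.
#' @param unbiased Use 1/(N-1) instead of 1/N.
#' @return A [gaussian_summary()].
#' @export
fit_gaussian <- function(E, unbiased = FALSE) {
  E <- .as_embedding(E)
  n <- nrow(E)
  mu <- colMeans(E)
  Xc <- sweep(unclass(E)[, , drop = FALSE], 2, mu)
  denom <- if (unbiased) max(n - 1L, 1L) else n
  S <- crossprod(Xc) / denom
  S <- (S + t(S)) / 2
  gaussian_summary(mu, S, n)
}

#' Closed-form 2-Wasserstein distance between two Gaussians
#'
#' Returns `||mu_x - mu_y||^2 + Tr(S_x + S_y - 2 (S_y S_x)^{1/2})`, with the
#' trace term evaluated through the numerically stable symmetric form
#' `Tr((S_x^{1/2} S_y S_x^{1/2})^{1/2})`; negative eigenvalues from roundoff
#' are clamped to zero and the final value is clamped to `[0, Inf)` (the raw
#' value is attached as attribute `raw`).
#'
#' @param gx,gy [gaussian_summary()] objects of matching dimension.
#' @return Nonnegative numeric distance.
#' @export
frechet_gaussian_distance <- function(gx, gy) {
  stopifnot(inherits(gx, "gaussian_summary"), inherits(gy, "gaussian_summary"))
  if (length(gx$mean) != length(gy$mean))
    stop("dimension mismatch between Gaussian summaries")
  dmu <- gx$mean - gy$mean
  tr_cross <- .trace_sqrt_cross(gx$covariance, gy$covariance)
  raw <- sum(dmu^2) + sum(diag(gx$covariance)) + sum(diag(gy$covariance)) -
    2 * tr_cross
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Tr((Sx^{1/2} Sy Sx^{1/2})^{1/2}) with eigenvalue clamping
#' @noRd
.trace_sqrt_cross <- function(Sx, Sy) {
  A <- .sym_sqrt(Sx)
  M <- A %*% Sy %*% A
  M <- (M + t(M)) / 2
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev)) {
    # degenerate decomposition: jitter the diagonal and retry
    M <- M + diag(1e-10, nrow(M))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  sum(sqrt(pmax(ev, 0)))
}

#' Symmetric PSD square root via eigendecomposition
#' @noRd
.sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Joint PCA basis
#'
#' @param center Pooled-mean p-vector.
#' @param components d x p matrix of orthonormal rows (principal directions).
#' @param explained_variance Nonincreasing d-vector of component variances.
#' @return Object of class `pca_basis`.
#' @export
pca_basis <- function(center, components, explained_variance) {
  components <- as.matrix(components)
  G <- components %*% t(components)
  if (max(abs(G - diag(nrow(components)))) > 1e-8)
    stop("components must have orthonormal rows")
  if (is.unsorted(rev(explained_variance)))
    stop("explained_variance must be nonincreasing")
  structure(list(center = as.numeric(center), components = components,
                 explained_variance = as.numeric(explained_variance)),
            class = "pca_basis")
}

#' Fit a PCA basis jointly on reference and evaluation embeddings
#'
#' The basis is fit on the concatenation of both matrices, centered at the
#' pooled mean, so that directions separating the two sets are emphasized;
#' no whitening is applied. Component signs are fixed deterministically.
#'
#' @param E_ref,E_eval Embedding matrices with equal column count.
#' @param d Number of components, `1 <= d <= min(p, N_ref + N_eval)`.
#' @return A [pca_basis()].
#' @export
fit_joint_pca <- function(E_ref, E_eval, d) {
  E_ref <- .as_embedding(E_ref); E_eval <- .as_embedding(E_eval)
  if (ncol(E_ref) != ncol(E_eval)) stop("embedding dimensions differ")
  Z <- rbind(unclass(E_ref), unclass(E_eval))
  p <- ncol(Z); n <- nrow(Z)
  if (d < 1 || d > min(p, n))
    stop("d must satisfy 1 <= d <= min(p, N_ref + N_eval) = ", min(p, n))
  center <- colMeans(Z)
  Zc <- sweep(Z, 2, center)
  sv <- svd(Zc, nu = 0, nv = min(n, p))
  comp <- t(sv$v[, seq_len(d), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(d)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  ev <- (sv$d[seq_len(d)]^2) / n
  pca_basis(center, comp, ev)
}

#' Project embeddings onto a PCA basis
#'
#' Rows are mapped to `(x - center) %*% t(components)`.
#'
#' @param E An [embedding_matrix()] (or numeric matrix).
#' @param basis A [pca_basis()].
#' @return An [embedding_matrix()] with d columns.
#' @export
project <- function(E, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  E <- .as_embedding(E)
  if (ncol(E) != length(basis$center))
    stop("embedding dimension does not match the basis")
  Y <- sweep(unclass(E), 2, basis$center) %*% t(basis$components)
  embedding_matrix(Y, ids = rownames(E),
                   embedder = paste0(attr(E, "embedder"), "+pca"))
}

#' Distributional distance between two structure samples
#'
#' End-to-end metric: embeds both inputs if they are structure sets, fits a
#' joint PCA at dimension `d`, projects, fits Gaussians (1/N covariance) and
#' returns the closed-form 2-Wasserstein distance between them. A degeneracy
#' warning is recorded when the pooled pre-projection covariance has
#' condition number above 1e12.
#'
#' @param ref,eval_set Reference and evaluation inputs: embedding matrices or
#'   structure sets.
#' @param d Projection dimension (default 32; capped checks as in
#'   [fit_joint_pca()]).
#' @param embedder Embedder used when structure sets are supplied.
#' @param unbiased Use 1/(N-1) covariances.
#' @return Object of class `fid_result` with fields `value`, `raw_value`,
#'   `d`, `n_ref`, `n_eval`, `degenerate_warning`.
#' @export
compute_fid <- function(ref, eval_set, d = 32L, embedder = geometric_featurize,
                        unbiased = FALSE) {
  E_ref <- .as_embedding(ref, embedder)
  E_eval <- .as_embedding(eval_set, embedder)
  if (ncol(E_ref) != ncol(E_eval)) stop("embedding dimensions differ")
  p <- ncol(E_ref)
  if (nrow(E_ref) < d + 1 || nrow(E_eval) < d + 1)
    warning("sample size below d + 1: projected covariances are rank-deficient")
  Z <- rbind(unclass(E_ref), unclass(E_eval))
  rownames(Z) <- NULL
  pooled <- fit_gaussian(Z)
  ev <- eigen(pooled$covariance, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- max(ev) / max(min(ev), .Machine$double.xmin) > 1e12
  basis <- fit_joint_pca(E_ref, E_eval, d)
  gx <- fit_gaussian(project(E_ref, basis), unbiased = unbiased)
  gy <- fit_gaussian(project(E_eval, basis), unbiased = unbiased)
  val <- frechet_gaussian_distance(gx, gy)
  structure(
    list(value = as.numeric(val), raw_value = attr(val, "raw"), d = d,
         n_ref = nrow(E_ref), n_eval = nrow(E_eval),
         degenerate_warning = degenerate),
    class = "fid_result"
  )
}

#' @export
print.fid_result <- function(x, ...) {
  cat(sprintf("<fid_result> value = %.6g (d = %d, n_ref = %d, n_eval = %d)%s\n",
              x$value, x$d, x$n_ref, x$n_eval,
              if (x$degenerate_warning) " [near-degenerate covariance]" else ""))
  invisible(x)
}
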