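# Synthetic backbones and Gaussian embedding clouds with known structure.
# These are first-class generators: every other module is testable on them
# without downloads or pretrained weights.

#' Build a backbone from per-residue dihedrals
#'
#' Chain growth with ideal bond lengths/angles (see the geometry constants in
#' the package source): residue i's phi is used to place its carbonyl carbon,
#' its psi to place the next amide nitrogen, omega fixed trans.
#' @noRd
.build_from_dihedrals <- function(phi, psi, id, omega = .BB_GEOM$omega) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- .BB_GEOM
  N <- CA <- C <- matrix(NA_real_, n, 3)
  # first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$len_n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$len_ca_c * c(-cos(ang), sin(ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$len_c_n, g$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             g$len_n_ca, g$ang_c_n_ca, omega)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            g$len_ca_c, g$ang_n_ca_c, phi[i])
    }
  }
  backbone_structure(id = id, N = N, CA = CA, C = C)
}

.PHI_HELIX <- -60; .PSI_HELIX <- -45
.PHI_STRAND <- -120; .PSI_STRAND <- 120

#' Ideal alpha-helix backbone
#'
#' Canonical helical dihedrals (phi ~ -60, psi ~ -45 degrees), giving a rise
#' of about 1.5 angstrom per residue and consecutive CA-CA distances of
#' 3.8 +/- 0.1 angstrom.
#'
#' @param n_res Number of residues (>= 4).
#' @param seed Unused for the ideal helix (kept for generator-interface
#'   uniformity).
#' @param id Structure id.
#' @return A [backbone_structure()].
#' @export
make_helix <- function(n_res, seed = NULL, id = sprintf("helix%d", n_res)) {
  if (n_res < 4) stop("a helix needs at least 4 residues")
  .build_from_dihedrals(rep(.PHI_HELIX, n_res), rep(.PSI_HELIX, n_res), id)
}

#' Ideal extended beta-strand backbone
#'
#' Extended dihedrals (phi ~ -120, psi ~ +120 degrees) with consecutive
#' CA-CA distances near 3.8 angstrom.
#'
#' @param n_res Number of residues (>= 3).
#' @param id Structure id.
#' @return A [backbone_structure()].
#' @export
make_strand <- function(n_res, id = sprintf("strand%d", n_res)) {
  if (n_res < 3) stop("a strand needs at least 3 residues")
  .build_from_dihedrals(rep(.PHI_STRAND, n_res), rep(.PSI_STRAND, n_res), id)
}

#' @noRd
.coil_dihedrals <- function(n) {
  # generic coil: broad sampling outside the tight helix basin
  phi <- stats::runif(n, -160, -50)
  psi <- ifelse(stats::runif(n) < 0.5,
                stats::runif(n, 30, 180),
                stats::runif(n, -180, -150))
  list(phi = phi, psi = psi)
}

#' Multi-segment synthetic backbone
#'
#' Concatenates ideal helix/strand segments and random-coil linkers into one
#' chain, rejecting self-clashing geometries (CA-CA below 2.5 angstrom for
#' non-adjacent residues) with bounded retries of the random coil dihedrals.
#'
#' @param plan List of `c(kind, length)` pairs (or a 2-column data.frame)
#'   with kind in `{"helix","strand","coil"}`; total length >= 6.
#' @param seed Integer seed for coil dihedrals and retries.
#' @param id Structure id.
#' @param max_retries Retries before giving up on a self-avoiding chain.
#' @return A [backbone_structure()] with segment boundaries in
#'   `attr(, "plan")`.
#' @export
make_multisegment <- function(plan, seed = 1L, id = "multiseg",
                              max_retries = 100L) {
  if (is.data.frame(plan)) plan <- lapply(seq_len(nrow(plan)), function(i)
    list(kind = as.character(plan[i, 1]), len = as.integer(plan[i, 2])))
  else plan <- lapply(plan, function(p) list(kind = as.character(p[[1]]),
                                             len = as.integer(p[[2]])))
  kinds <- vapply(plan, `[[`, character(1), "kind")
  lens <- vapply(plan, `[[`, integer(1), "len")
  if (!all(kinds %in% c("helix", "strand", "coil")))
    stop("segment kinds must be helix, strand or coil")
  if (sum(lens) < 6) stop("total planned length must be >= 6")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    phi <- psi <- numeric(0)
    for (k in seq_along(plan)) {
      ph <- switch(kinds[k],
        helix = rep(.PHI_HELIX, lens[k]),
        strand = rep(.PHI_STRAND, lens[k]),
        coil = NULL)
      if (is.null(ph)) {
        cd <- .coil_dihedrals(lens[k])
        ph <- cd$phi; ps <- cd$psi
      } else {
        ps <- switch(kinds[k], helix = rep(.PSI_HELIX, lens[k]),
                     strand = rep(.PSI_STRAND, lens[k]))
      }
      phi <- c(phi, ph); psi <- c(psi, ps)
    }
    s <- .build_from_dihedrals(phi, psi, id)
    D <- as.matrix(stats::dist(s$CA))
    sep <- abs(row(D) - col(D))
    if (min(D[sep >= 2]) >= 2.5) {
      boundaries <- data.frame(kind = kinds,
                               start = cumsum(c(0L, lens[-length(lens)])),
                               end = cumsum(lens))
      attr(s, "plan") <- boundaries
      return(s)
    }
    if (all(kinds != "coil")) break  # deterministic plan cannot improve
  }
  stop("could not generate a self-avoiding chain for this plan")
}

# -- seeded RNG hygiene -------------------------------------------------------

#' @noRd
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# -- Gaussian embedding clouds ------------------------------------------------

#' Specification of a Gaussian embedding cloud
#'
#' @param mean Mean p-vector.
#' @param covariance p x p symmetric positive-semidefinite matrix.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return An object of class `gaussian_cloud_spec`.
#' @export
gaussian_cloud_spec <- function(mean, covariance, n, seed = 1L) {
  covariance <- as.matrix(covariance)
  p <- length(mean)
  if (!all(dim(covariance) == c(p, p)))
    stop("covariance must be p x p for a p-dim mean")
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("covariance must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "gaussian_cloud_spec")
}

#' Sample a Gaussian embedding cloud
#'
#' Draws `spec$n` i.i.d. points from N(mean, covariance). The draw is
#' `mean + L z` with `L` the symmetric eigen square root of the covariance
#' and `z` standard normal, so singular (PSD) covariances are handled and
#' the single-draw case is exactly reproducible.
#'
#' @param spec A [gaussian_cloud_spec()].
#' @return An [embedding_matrix()] with ids `s1..sn`.
#' @export
sample_cloud <- function(spec) {
  stopifnot(inherits(spec, "gaussian_cloud_spec"))
  p <- length(spec$mean)
  e <- eigen(spec$covariance, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n * p), spec$n, p)
  X <- sweep(Z %*% L, 2, spec$mean, "+")
  embedding_matrix(X, ids = sprintf("s%d", seq_len(spec$n)),
                   embedder = "gaussian-cloud")
}

#' Clustered Gaussian embedding cloud
#'
#' Mixture of `k` unit-covariance Gaussians whose means are pairwise at
#' least `separation` apart (means are placed at `separation` times scaled
#' simplex-like directions), emulating cluster structure in an embedding
#' space. Returns the stacked points and their cluster labels.
#'
#' @param k Number of clusters (>= 2).
#' @param separation Minimum pairwise distance between cluster means.
#' @param per_cluster_n Draws per cluster.
#' @param p Embedding dimension (>= 2).
#' @param seed Integer seed for the draws.
#' @param means_seed Seed for placing the cluster means (defaults to `seed`);
#'   fix it while varying `seed` to draw independent samples from the same
#'   mixture.
#' @return List with `embeddings` (an [embedding_matrix()]) and `labels`
#'   (character vector aligned to rows).
#' @export
make_clustered_cloud <- function(k, separation, per_cluster_n, p, seed = 1L,
                                 means_seed = seed) {
  if (k < 2) stop("need at least k = 2 clusters")
  if (p < 2) stop("need embedding dimension p >= 2")
  means <- .cluster_means(k, p, separation, means_seed)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    sp <- gaussian_cloud_spec(means[j, ], diag(p), per_cluster_n,
                              seed = (seed + 7919 * j) %% 2147483647)
    rows[[j]] <- unclass(sample_cloud(sp))
  }
  X <- do.call(rbind, rows)
  ids <- sprintf("c%d_s%d", rep(seq_len(k), each = per_cluster_n),
                 rep(seq_len(per_cluster_n), k))
  labels <- sprintf("c%d", rep(seq_len(k), each = per_cluster_n))
  list(embeddings = embedding_matrix(X, ids, "gaussian-cloud"),
       labels = labels)
}

#' Random well-separated cluster means
#' @noRd
.cluster_means <- function(k, p, separation, seed) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (separation <= 0) return(matrix(0, k, p))
  # random unit directions, rescaled until pairwise distances >= separation
  for (attempt in 1:200) {
    U <- matrix(stats::rnorm(k * p), k, p)
    U <- U / sqrt(rowSums(U^2))
    dmin <- min(stats::dist(U))
    if (dmin > 1e-3) {
      M <- U * (separation / dmin)
      return(M)
    }
  }
  stop("failed to place separated cluster means")
}

#' Hierarchical clustered Gaussian cloud
#'
#' Two-level mixture: `k1` well-separated super-clusters, each split into
#' `k2` sub-clusters whose means are offset from the super-cluster mean by
#' the (smaller) `sub_separation`. Emulates a class hierarchy in embedding
#' space for multi-level diversity races.
#'
#' @param k1 Super-clusters (>= 2).
#' @param k2 Sub-clusters per super-cluster (>= 2).
#' @param separation Pairwise distance scale between super-cluster means.
#' @param sub_separation Distance scale between sub-cluster means within a
#'   super-cluster (should be well below `separation`).
#' @param per_cluster_n Draws per sub-cluster.
#' @param p Embedding dimension.
#' @param seed Draw seed.
#' @param means_seed Mean-placement seed (defaults to `seed`).
#' @return List with `embeddings` and `labels` (data.frame with `level1`,
#'   `level2` columns aligned to rows).
#' @export
make_hierarchical_cloud <- function(k1, k2, separation, sub_separation,
                                    per_cluster_n, p, seed = 1L,
                                    means_seed = seed) {
  if (k1 < 2 || k2 < 2) stop("need k1 >= 2 and k2 >= 2")
  super <- .cluster_means(k1, p, separation, means_seed)
  rows <- list(); l1 <- l2 <- character(0)
  idx <- 0L
  for (a in seq_len(k1)) {
    sub <- .cluster_means(k2, p, sub_separation,
                          (means_seed + 131 * a) %% 2147483647)
    for (b in seq_len(k2)) {
      idx <- idx + 1L
      sp <- gaussian_cloud_spec(super[a, ] + sub[b, ], diag(p),
                                per_cluster_n,
                                seed = (seed + 7919 * idx) %% 2147483647)
      rows[[idx]] <- unclass(sample_cloud(sp))
      l1 <- c(l1, rep(sprintf("A%d", a), per_cluster_n))
      l2 <- c(l2, rep(sprintf("A%d.%d", a, b), per_cluster_n))
    }
  }
  X <- do.call(rbind, rows)
  ids <- sprintf("h%d", seq_len(nrow(X)))
  list(embeddings = embedding_matrix(X, ids, "gaussian-cloud"),
       labels = data.frame(level1 = l1, level2 = l2,
                           stringsAsFactors = FALSE))
}

#' Write an embedding matrix as tab-separated text
#'
#' First line is a `#dim=<p> embedder=<tag>` header, then one row per
#' structure: id followed by p numeric columns.
#'
#' @param E An [embedding_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(E, path) {
  stopifnot(inherits(E, "embedding_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#dim=%d embedder=%s", ncol(E),
                     attr(E, "embedder")), con)
  rows <- cbind(rownames(E),
                matrix(formatC(E, format = "g", digits = 17), nrow(E)))
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}
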