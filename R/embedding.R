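# Structure -> fixed-length vector embeddings. The default embedder is a
# deterministic, rotation/translation-invariant geometric featurizer; vectors
# from external pretrained models enter through load_embeddings() or any
# function obeying the embedder contract (backbone -> numeric p-vector).

#' Embedding matrix container
#'
#' N structures x p dimensions numeric matrix with unique row ids and a
#' provenance tag describing the embedder.
#'
#' @param values N x p numeric matrix (all finite).
#' @param ids Character vector of N unique ids.
#' @param embedder Provenance tag.
#' @return A numeric matrix of class `embedding_matrix` with row names `ids`
#'   and attribute `embedder`.
#' @export
embedding_matrix <- function(values, ids = rownames(values),
                             embedder = "unknown") {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("embedding matrix must be a non-empty numeric matrix")
  if (!all(is.finite(values))) stop("embedding entries must all be finite")
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop("one id per row required")
  if (anyDuplicated(ids)) stop("embedding ids must be unique")
  rownames(values) <- ids
  attr(values, "embedder") <- as.character(embedder)
  class(values) <- c("embedding_matrix", class(values))
  values
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d (embedder: %s)\n",
              nrow(x), ncol(x), attr(x, "embedder")))
  invisible(x)
}

# `[.embedding_matrix`: subsetting rows keeps the class and tag.
#' @export
`[.embedding_matrix` <- function(x, i, j, ..., drop = FALSE) {
  tag <- attr(x, "embedder")
  y <- NextMethod(drop = FALSE)
  if (is.matrix(y) && !is.null(rownames(y))) {
    attr(y, "embedder") <- tag
    class(y) <- c("embedding_matrix", "matrix", "array")
  }
  y
}

.FEAT_DIST_BINS <- 22L   # log-spaced CA-CA distance histogram bins
.FEAT_RAMA_BINS <- 6L    # 6 x 6 coarse Ramachandran occupancy grid

#' Deterministic geometric backbone featurizer
#'
#' Concatenates rotation- and translation-invariant descriptors into one
#' fixed-length vector (64 dimensions at the default bin counts):
#' a normalized CA-CA pairwise-distance histogram over log-spaced bins
#' (3-60 angstrom), a coarse phi/psi occupancy histogram, secondary-structure
#' fractions (H, E, C), radius of gyration scaled by length^0.4, contact
#' density at 8 angstrom, and log length.
#'
#' @param s A `backbone` with at least 8 residues.
#' @param dist_bins,rama_bins Histogram resolutions.
#' @return Numeric feature vector.
#' @export
geometric_featurize <- function(s, dist_bins = .FEAT_DIST_BINS,
                                rama_bins = .FEAT_RAMA_BINS) {
  stopifnot(inherits(s, "backbone"))
  if (s$n < 8) stop("geometric featurizer needs at least 8 residues")
  ca <- s$CA
  D <- stats::dist(ca)
  breaks <- exp(seq(log(3), log(60), length.out = dist_bins + 1L))
  dh <- graphics::hist(pmin(pmax(as.vector(D), 3), 60 - 1e-9), breaks = breaks,
                       plot = FALSE)$counts
  dh <- dh / sum(dh)

  tor <- .backbone_torsions(s)
  ok <- is.finite(tor$phi) & is.finite(tor$psi)
  # grid offset by 5 degrees so canonical dihedrals (multiples of 15) never
  # sit on a bin edge, keeping the histogram stable under rigid motion
  wbin <- 360 / rama_bins
  ix <- floor(((tor$phi[ok] + 180 - 5) %% 360) / wbin) + 1L
  iy <- floor(((tor$psi[ok] + 180 - 5) %% 360) / wbin) + 1L
  rh <- numeric(rama_bins^2)
  for (t in seq_along(ix)) {
    cell <- (ix[t] - 1L) * rama_bins + iy[t]
    rh[cell] <- rh[cell] + 1
  }
  if (sum(rh) > 0) rh <- rh / sum(rh)

  ss <- assign_secondary_structure(s)$labels
  ssf <- c(mean(ss == "H"), mean(ss == "E"), mean(ss == "C"))

  rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  Dm <- as.matrix(D)
  sep <- abs(row(Dm) - col(Dm))
  ncontact <- sum(Dm <= 8 & sep >= 3) / 2
  c(dh, rh, ssf, rg / s$n^0.4, ncontact / s$n, log(s$n))
}

#' Backbone phi/psi torsions in degrees (NA at termini)
#' @noRd
.backbone_torsions <- function(s) {
  n <- s$n
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in seq_len(n)) {
      if (i > 1)
        phi[i] <- .dihedral(s$C[i - 1, ], s$N[i, ], s$CA[i, ], s$C[i, ])
      if (i < n)
        psi[i] <- .dihedral(s$N[i, ], s$CA[i, ], s$C[i, ], s$N[i + 1, ])
    }
  }
  list(phi = phi, psi = psi)
}

#' Embed a structure set
#'
#' Applies an embedder (any function mapping a `backbone` to a fixed-length
#' numeric vector) to every member, in set order. A failure on any structure
#' aborts the run with a per-structure error report; structures are never
#' silently dropped, since a changed sample size would bias the distance.
#'
#' @param set A `structure_set`.
#' @param embedder Embedding function (default [geometric_featurize()]).
#' @param tag Provenance tag recorded on the result.
#' @return An [embedding_matrix()], one row per structure.
#' @export
embed_set <- function(set, embedder = geometric_featurize,
                      tag = "geometric") {
  stopifnot(inherits(set, "structure_set"))
  res <- lapply(set$members, function(m) {
    tryCatch(list(ok = TRUE, v = as.numeric(embedder(m))),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  })
  bad <- !vapply(res, `[[`, logical(1), "ok")
  if (any(bad)) {
    msgs <- vapply(res[bad], `[[`, character(1), "msg")
    stop("embedder failed on ", sum(bad), " structure(s):\n",
         paste(sprintf("  %s: %s", names(res)[bad], msgs), collapse = "\n"))
  }
  p <- unique(vapply(res, function(r) length(r$v), integer(1)))
  if (length(p) != 1L) stop("embedder returned vectors of differing length")
  V <- do.call(rbind, lapply(res, `[[`, "v"))
  embedding_matrix(V, ids = names(set$members), embedder = tag)
}

#' Load an embedding table
#'
#' Tab-separated text as written by [write_embeddings()]: optional
#' `#dim=<p> embedder=<tag>` header, then id plus p numeric columns per row.
#'
#' @param path File path.
#' @return An [embedding_matrix()].
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path)
  tag <- "external"
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("embedder=(\\S+)", lines[1]))[[1]]
    if (length(m) == 2) tag <- m[2]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in embedding table (widths ",
         paste(unique(widths), collapse = ","), ")")
  if (widths[1] < 2L) stop("embedding table needs id + >= 1 numeric column")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate ids in embedding table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  V <- do.call(rbind, lapply(parts, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("non-numeric cell in embedding table row '", r[1], "'")
    v
  }))
  embedding_matrix(V, ids = ids, embedder = tag)
}

#' Resolve structures-or-embeddings input to an embedding matrix
#' @noRd
.as_embedding <- function(x, embedder = geometric_featurize,
                          tag = "geometric") {
  if (inherits(x, "embedding_matrix")) return(x)
  if (inherits(x, "structure_set")) return(embed_set(x, embedder, tag))
  if (is.matrix(x) && is.numeric(x)) return(embedding_matrix(x))
  stop("expected an embedding_matrix, numeric matrix or structure_set")
}
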