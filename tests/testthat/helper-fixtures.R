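# Shared fixtures, built in code at test time.

# rigid motion: rotation about a random axis + translation
rigid_transform <- function(s, seed = 1L) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.3, 2.8)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3, sd = 10)
  out <- s
  for (atom in c("N", "CA", "C", "O")) {
    if (is.null(s[[atom]])) next
    out[[atom]] <- sweep(s[[atom]] %*% t(R), 2, tr, "+")
  }
  out
}

# a small mixed-topology chain, deterministic given seed
mixed_chain <- function(seed, id = paste0("mx", seed),
                        plan = list(c("helix", 14), c("coil", 5),
                                    c("strand", 8))) {
  make_multisegment(plan, seed = seed, id = id)
}

mixed_set <- function(seeds, ...) {
  structure_set(lapply(seeds, function(s) mixed_chain(s, ...)))
}

# brute-force optimal assignment objective for uniform-marginal OT (N = M)
brute_force_ot <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) mean(C[cbind(seq_len(n), p)]), numeric(1)))
}

# brute-force minimum set cover size (threshold 1); NA if infeasible
brute_force_cover <- function(universe, candidates) {
  ids <- names(candidates)
  for (k in seq_along(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (cb in combos) {
      if (all(universe %in% unique(unlist(candidates[cb])))) return(k)
    }
  }
  NA_integer_
}
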