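# Optimal-transport distance between structure sets on a symmetrized
# TM-score cost: C_ij = 1 - (TM(a_i, b_j) + TM(b_j, a_i)) / 2, solved
# exactly with a successive-shortest-path min-cost-flow solver.

#' Transport problem container
#'
#' @param cost N x M cost matrix with entries in `[0, 1]`.
#' @param row_marginal,col_marginal Marginals (default uniform `1/N`, `1/M`).
#' @param D Optional underlying directed similarity matrix.
#' @param ids_a,ids_b Optional row/column ids.
#' @return Object of class `transport_problem`.
#' @export
transport_problem <- function(cost,
                              row_marginal = rep(1 / nrow(cost), nrow(cost)),
                              col_marginal = rep(1 / ncol(cost), ncol(cost)),
                              D = NULL, ids_a = NULL, ids_b = NULL) {
  cost <- as.matrix(cost)
  if (any(cost < -1e-9) || any(cost > 1 + 1e-9))
    stop("cost entries must lie in [0, 1]")
  if (length(row_marginal) != nrow(cost) || length(col_marginal) != ncol(cost))
    stop("marginal lengths must match the cost matrix")
  structure(list(cost = cost, row_marginal = as.numeric(row_marginal),
                 col_marginal = as.numeric(col_marginal), plan = NULL,
                 objective = NULL, D = D, ids_a = ids_a, ids_b = ids_b),
            class = "transport_problem")
}

#' @export
print.transport_problem <- function(x, ...) {
  cat(sprintf("<transport_problem> %d x %d%s\n", nrow(x$cost), ncol(x$cost),
              if (is.null(x$objective)) " (unsolved)"
              else sprintf(", objective = %.6g", x$objective)))
  invisible(x)
}

#' TM-score between two equal-length backbones
#'
#' Standard definition normalized by the length of the first (reference)
#' argument: `TM = mean(1 / (1 + (d_i / d0)^2))` with
#' `d0(L) = max(0.5, 1.24 (L - 15)^{1/3} - 1.8)`, under the identity residue
#' correspondence. The superposition is refined from fragment seeds (all
#' windows of length `min(L, 20)` at stride 5): each seed is superposed by
#' Kabsch, then the included-residue set is iterated (residues within the
#' inclusion cutoff, shrinking from `2 d0` to `d0`, at most 20 rounds) and
#' the best score over seeds is returned. Unequal lengths require an external
#' alignment; load precomputed scores with [load_tm_matrix()] instead.
#'
#' @param a,b `backbone` structures of equal residue count.
#' @return Score in (0, 1].
#' @export
tm_score <- function(a, b) {
  stopifnot(inherits(a, "backbone"), inherits(b, "backbone"))
  if (a$n != b$n)
    stop("built-in TM-score needs equal lengths; use load_tm_matrix() for ",
         "externally aligned pairs")
  L <- a$n
  if (L < 3) stop("need at least 3 residues")
  d0 <- max(0.5, 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8)
  P <- a$CA; Q <- b$CA
  w <- min(L, 20L)
  starts <- unique(c(seq(1L, L - w + 1L, by = 5L), L - w + 1L))
  score_of <- function(fit) {
    Qr <- .apply_superposition(Q, fit)
    d2 <- rowSums((Qr - P)^2)
    list(tm = mean(1 / (1 + d2 / d0^2)), d = sqrt(d2))
  }
  best <- 0
  for (s0 in starts) {
    sel <- s0:(s0 + w - 1L)
    fit <- .kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
    sc <- score_of(fit)
    best <- max(best, sc$tm)
    for (it in seq_len(20L)) {
      cut <- max(d0, 2 * d0 - (it - 1) * d0 / 10)  # shrink 2*d0 -> d0
      new_sel <- which(sc$d <= cut)
      if (length(new_sel) < 3L)
        new_sel <- order(sc$d)[seq_len(3L)]
      if (identical(new_sel, sel) && it > 1L) break
      sel <- new_sel
      fit <- .kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      sc <- score_of(fit)
      best <- max(best, sc$tm)
    }
  }
  best
}

#' Symmetrized transport cost between two structure sets
#'
#' Computes the directed similarity matrix `D_ij = kernel(A_i, B_j)` (first
#' argument is the reference for normalization), symmetrizes it into the
#' cost `C_ij = 1 - (D_ij + D_ji) / 2`, and attaches uniform marginals.
#'
#' @param setA,setB `structure_set`s.
#' @param kernel Pairwise scorer (default [tm_score()]).
#' @return An unsolved [transport_problem()].
#' @export
cost_matrix <- function(setA, setB, kernel = tm_score) {
  stopifnot(inherits(setA, "structure_set"), inherits(setB, "structure_set"))
  N <- length(setA$members); M <- length(setB$members)
  D <- matrix(NA_real_, N, M)   # kernel(A_i, B_j)
  Dt <- matrix(NA_real_, M, N)  # kernel(B_j, A_i)
  for (i in seq_len(N)) for (j in seq_len(M)) {
    res <- tryCatch(list(ab = kernel(setA$members[[i]], setB$members[[j]]),
                         ba = kernel(setB$members[[j]], setA$members[[i]])),
                    error = function(e)
                      stop("kernel failed on pair (", names(setA$members)[i],
                           ", ", names(setB$members)[j], "): ",
                           conditionMessage(e), call. = FALSE))
    D[i, j] <- res$ab; Dt[j, i] <- res$ba
  }
  C <- 1 - (D + t(Dt)) / 2
  C <- pmin(pmax(C, 0), 1)
  transport_problem(C, D = D, ids_a = names(setA$members),
                    ids_b = names(setB$members))
}

#' Solve a transport problem exactly
#'
#' Successive-shortest-path min-cost flow on the bipartite transport graph
#' (Dijkstra with node potentials), which is exact for this linear program.
#' The returned problem carries the optimal `plan` and `objective`.
#'
#' @param prob A [transport_problem()].
#' @return The problem with `plan` and `objective` filled in.
#' @export
solve_ot <- function(prob) {
  stopifnot(inherits(prob, "transport_problem"))
  a <- prob$row_marginal; b <- prob$col_marginal
  if (abs(sum(a) - sum(b)) > 1e-8)
    stop("infeasible marginals: sums differ (", sum(a), " vs ", sum(b), ")")
  C <- prob$cost
  N <- nrow(C); M <- ncol(C)
  Fm <- matrix(0, N, M)
  rem_a <- a; rem_b <- b
  pot <- numeric(N + M)  # node potentials, rows then cols
  max_iter <- 50L * (N + M) + 100L
  iter <- 0L
  while (sum(rem_a) > 1e-12) {
    iter <- iter + 1L
    if (iter > max_iter) stop("transport solver failed to converge")
    dist <- rep(Inf, N + M)
    parent <- integer(N + M)
    done <- rep(FALSE, N + M)
    dist[which(rem_a > 1e-15)] <- 0
    repeat {
      u <- which(!done & is.finite(dist))
      if (!length(u)) break
      u <- u[which.min(dist[u])]
      done[u] <- TRUE
      if (u <= N) {
        rc <- C[u, ] + pot[u] - pot[N + seq_len(M)]
        nd <- dist[u] + pmax(rc, 0)
        upd <- which(nd < dist[N + seq_len(M)] - 1e-15 &
                       !done[N + seq_len(M)])
        if (length(upd)) {
          dist[N + upd] <- nd[upd]
          parent[N + upd] <- u
        }
      } else {
        j <- u - N
        back <- which(Fm[, j] > 1e-15)
        if (length(back)) {
          rc <- -C[back, j] + pot[u] - pot[back]
          nd <- dist[u] + pmax(rc, 0)
          upd <- back[nd < dist[back] - 1e-15 & !done[back]]
          if (length(upd)) {
            dist[upd] <- (dist[u] + pmax(rc, 0))[match(upd, back)]
            parent[upd] <- u
          }
        }
      }
    }
    sinks <- N + which(rem_b > 1e-15)
    sinks <- sinks[is.finite(dist[sinks])]
    if (!length(sinks)) stop("transport solver: no augmenting path")
    t <- sinks[which.min(dist[sinks])]
    # trace path from the sink back to a source row
    path <- integer(0); node <- t
    repeat {
      path <- c(node, path)
      if (node <= N && parent[node] == 0L) break
      node <- parent[node]
    }
    bottleneck <- min(rem_a[path[1]], rem_b[t - N])
    if (length(path) > 2L) {
      for (k in seq(2L, length(path) - 1L)) {
        if (path[k] > N && path[k + 1L] <= N)  # backward arc col -> row
          bottleneck <- min(bottleneck, Fm[path[k + 1L], path[k] - N])
      }
    }
    # apply flow
    for (k in seq_len(length(path) - 1L)) {
      u <- path[k]; v <- path[k + 1L]
      if (u <= N) Fm[u, v - N] <- Fm[u, v - N] + bottleneck
      else Fm[v, u - N] <- Fm[v, u - N] - bottleneck
    }
    rem_a[path[1]] <- rem_a[path[1]] - bottleneck
    rem_b[t - N] <- rem_b[t - N] - bottleneck
    # potential update (Johnson); unreached nodes get the max reached
    # distance so reduced costs stay nonnegative everywhere
    reach <- is.finite(dist)
    dmax <- max(dist[reach])
    pot <- pot + ifelse(reach, dist, dmax)
  }
  prob$plan <- Fm
  prob$objective <- sum(Fm * C)
  prob
}

#' Optimal-transport TM-score distance between two structure sets
#'
#' Builds the symmetrized cost matrix (or accepts a precomputed
#' [transport_problem()]), solves the uniform-marginal transport problem
#' exactly and returns the objective: 0 means the sets can be perfectly
#' soft-matched structure by structure, 1 means no structural similarity.
#'
#' @param setA,setB `structure_set`s, or pass `prob` directly.
#' @param kernel Pairwise scorer for the built-in cost.
#' @param prob Optional precomputed [transport_problem()] (e.g. from
#'   [load_tm_matrix()]); when given, `setA`/`setB` are ignored.
#' @return Distance in `[0, 1]`.
#' @export
ot_tmscore <- function(setA = NULL, setB = NULL, kernel = tm_score,
                       prob = NULL) {
  if (is.null(prob)) prob <- cost_matrix(setA, setB, kernel)
  solved <- solve_ot(prob)
  solved$objective
}

#' Load a pairwise score table from an external aligner
#'
#' Tab-separated columns: query id, target id, score. The table must contain
#' every (idsA, idsB) pair; reverse-direction (idsB, idsA) rows are used for
#' the symmetrization when present, otherwise the single direction is used
#' for both. Conflicting duplicates are an error.
#'
#' @param path File path.
#' @param idsA,idsB Row and column structure ids.
#' @return An unsolved [transport_problem()] with the symmetrized cost.
#' @export
load_tm_matrix <- function(path, idsA, idsB) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("query", "target", "score"))
  key <- paste(tab$query, tab$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) {
      length(unique(tab$score[key == k])) > 1L
    }, logical(1))
    if (any(conflict))
      stop("duplicate pair(s) with differing scores: ",
           paste(gsub("\r", "->", unique(dup)[conflict]), collapse = ", "))
    tab <- tab[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  lookup <- function(q, t) tab$score[match(paste(q, t, sep = "\r"), key)]
  grid <- expand.grid(i = seq_along(idsA), j = seq_along(idsB))
  fwd <- lookup(idsA[grid$i], idsB[grid$j])
  if (anyNA(fwd)) {
    missing <- grid[is.na(fwd), , drop = FALSE]
    stop("missing pair(s) in score table: ",
         paste(sprintf("%s->%s", idsA[missing$i], idsB[missing$j])[
           seq_len(min(10L, nrow(missing)))], collapse = ", "))
  }
  D <- matrix(fwd, length(idsA), length(idsB))
  rev <- lookup(idsB[grid$j], idsA[grid$i])
  Drev <- matrix(ifelse(is.na(rev), fwd, rev), length(idsA), length(idsB))
  C <- pmin(pmax(1 - (D + Drev) / 2, 0), 1)
  transport_problem(C, D = D, ids_a = idsA, ids_b = idsB)
}
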