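# Diversity races: drop structures round by round under different ordering
# policies and watch how fast the distributional distance to a reference
# degrades. A clustered racer that degrades faster than the random racer
# shows the metric senses fold diversity.

#' Racer specification
#'
#' @param name Display name.
#' @param policy `"random"` or `"clustered"`.
#' @param level Label hierarchy level used by the clustered policy
#'   (1 = coarsest).
#' @return Object of class `racer_spec`.
#' @export
racer_spec <- function(name, policy = c("random", "clustered"), level = 1L) {
  policy <- match.arg(policy)
  structure(list(name = name, policy = policy, level = as.integer(level)),
            class = "racer_spec")
}

#' Cluster-prioritized ordering of a labelled set
#'
#' Groups members contiguously by their cluster at the given level; the
#' traversal order of clusters and the order within each cluster are both
#' randomized by the seed, so dropping along this ordering removes whole
#' clusters before touching the next.
#'
#' @param labels Character vector of per-member cluster labels.
#' @param seed Integer seed.
#' @return Integer permutation of `seq_along(labels)`.
#' @export
cluster_ordering <- function(labels, seed = 1L) {
  if (anyNA(labels)) stop("cluster labels required for a clustered ordering")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  clusters <- sample(unique(labels))
  unlist(lapply(clusters, function(cl) {
    ix <- which(labels == cl)
    if (length(ix) > 1L) sample(ix) else ix
  }), use.names = FALSE)
}

#' Race trajectory container
#' @noRd
.race_trajectory <- function(sizes, racer_names, mean_scores, sd_scores,
                             replicates, raw) {
  structure(list(rounds = sizes, racers = racer_names, scores = mean_scores,
                 score_sd = sd_scores, replicates = replicates, raw = raw),
            class = "race_trajectory")
}

#' @export
print.race_trajectory <- function(x, ...) {
  cat(sprintf("<race_trajectory> %d racer(s), %d round(s), %d replicate(s)\n",
              length(x$racers), length(x$rounds) - 1L, x$replicates))
  tab <- round(x$scores, 4)
  dimnames(tab) <- list(x$racers, paste0("n=", x$rounds))
  print(tab)
  invisible(x)
}

#' Fast FID against a fixed reference Gaussian in a fixed projected basis
#' @noRd
.fid_rows <- function(Yrows, ref_gauss) {
  g <- fit_gaussian(embedding_matrix(Yrows, ids = seq_len(nrow(Yrows))))
  as.numeric(frechet_gaussian_distance(g, ref_gauss))
}

#' Run a diversity race
#'
#' All racers start from the identical full set; at each round every racer
#' drops the same fixed number of structures according to its own ordering
#' (cluster-prioritized or uniform random), and the FID of the remaining
#' set to the reference is recorded. Orderings are redrawn per replicate
#' from seeds derived from `base_seed`, and mean/sd curves over replicates
#' are reported. One joint PCA, fit on (reference, full starting set), is
#' reused for every round so rounds are comparable; pass `refit_pca = TRUE`
#' to refit per round instead.
#'
#' @param set Evaluation input: `structure_set` (with labels for clustered
#'   racers) or [embedding_matrix()] plus `labels`.
#' @param reference Reference input: `structure_set` or embedding matrix.
#' @param racers List of [racer_spec()]s.
#' @param drop_per_round Structures removed per racer per round.
#' @param rounds Number of rounds; `drop_per_round * rounds` must be smaller
#'   than the set size.
#' @param replicates Independent reruns with fresh orderings.
#' @param base_seed Master seed; all replicate/racer seeds derive from it.
#' @param d Projection dimension for the internal FID.
#' @param labels Optional data.frame (id + one column per level) or vector
#'   when `set` is an embedding matrix.
#' @param embedder Embedder for structure inputs.
#' @param refit_pca Refit the joint PCA at every round.
#' @return A `race_trajectory`.
#' @export
run_race <- function(set, reference, racers, drop_per_round, rounds,
                     replicates = 1L, base_seed = 1L, d = 8L, labels = NULL,
                     embedder = geometric_featurize, refit_pca = FALSE) {
  E <- .as_embedding(set, embedder)
  E_ref <- .as_embedding(reference, embedder)
  lab_tab <- .resolve_labels(set, labels, rownames(E))
  N <- nrow(E)
  if (drop_per_round < 0 || rounds < 0) stop("negative race parameters")
  if (drop_per_round * rounds >= N)
    stop("too many rounds: the race would empty the set")
  need_lab <- vapply(racers, function(r) r$policy == "clustered", logical(1))
  if (any(need_lab) && is.null(lab_tab))
    stop("clustered racers need cluster labels")
  for (r in racers[need_lab]) {
    if (r$level > ncol(lab_tab))
      stop("no labels at hierarchy level ", r$level)
  }
  basis <- fit_joint_pca(E_ref, E, d)
  Yref <- project(E_ref, basis)
  Y <- project(E, basis)
  ref_gauss <- fit_gaussian(Yref)

  sizes <- N - drop_per_round * (0:rounds)
  R <- length(racers)
  raw <- array(NA_real_, c(R, rounds + 1L, replicates))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(base_seed)
  rep_seeds <- sample.int(2147483646L, replicates * R)
  k <- 0L
  for (rep in seq_len(replicates)) {
    for (ri in seq_len(R)) {
      k <- k + 1L
      spec <- racers[[ri]]
      ord <- if (spec$policy == "clustered")
        cluster_ordering(lab_tab[[spec$level]], seed = rep_seeds[k])
      else {
        set.seed(rep_seeds[k]); sample.int(N)
      }
      for (j in 0:rounds) {
        keep <- ord[seq(j * drop_per_round + 1L, N)]
        if (refit_pca) {
          b <- fit_joint_pca(E_ref, E[keep, , drop = FALSE], d)
          rg <- fit_gaussian(project(E_ref, b))
          raw[ri, j + 1L, rep] <-
            .fid_rows(unclass(project(E[keep, , drop = FALSE], b)), rg)
        } else {
          raw[ri, j + 1L, rep] <-
            .fid_rows(unclass(Y)[keep, , drop = FALSE], ref_gauss)
        }
      }
    }
  }
  mean_scores <- apply(raw, c(1, 2), mean)
  sd_scores <- apply(raw, c(1, 2), stats::sd)
  .race_trajectory(sizes, vapply(racers, `[[`, character(1), "name"),
                   mean_scores, sd_scores, replicates, raw)
}

#' Hierarchical diversity race
#'
#' Builds one clustered racer per label hierarchy level plus a random
#' baseline and delegates to [run_race()]. On a clean hierarchy the
#' final-round FID ordering follows the hierarchy: coarser levels (whole
#' super-clusters dropped first) degrade fastest, random slowest.
#'
#' @param set,reference,labels As in [run_race()].
#' @param levels Integer vector of hierarchy levels to race (1 = coarsest).
#' @param ... Passed to [run_race()].
#' @return A `race_trajectory`.
#' @export
hierarchy_race <- function(set, reference, levels, labels = NULL, ...) {
  racers <- c(
    lapply(levels, function(l)
      racer_spec(sprintf("clustered-L%d", l), "clustered", level = l)),
    list(racer_spec("random", "random"))
  )
  run_race(set, reference, racers, labels = labels, ...)
}

#' Normalize label input to a data.frame of one column per level
#' @noRd
.resolve_labels <- function(set, labels, ids) {
  if (is.null(labels) && inherits(set, "structure_set") &&
      !is.null(set$labels))
    labels <- set$labels
  if (is.null(labels)) return(NULL)
  if (is.atomic(labels)) {
    if (length(labels) != length(ids)) stop("one label per member required")
    return(data.frame(level1 = as.character(labels),
                      stringsAsFactors = FALSE))
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  first <- as.character(labels[[1L]])
  if (all(ids %in% first)) {
    out <- labels[match(ids, first), -1L, drop = FALSE]
  } else {
    out <- labels
  }
  if (anyNA(out)) stop("missing labels for some members")
  rownames(out) <- NULL
  out
}
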