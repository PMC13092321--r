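# Explanatory structure statistics: secondary-structure-aware contact order
# and greedy motif-cover counts. Contacts are CA-distance based (a declared
# substitute for rotamer-derived potential contacts: absolute values are not
# comparable to rotamer-based tables, but between-set orderings are).

.MIN_RUN <- c(H = 4L, E = 3L)

#' Assign secondary structure from backbone dihedrals
#'
#' Dihedral-basin classifier: a residue is H when (phi, psi) falls in the
#' helical basin (phi in [-100, -30], psi in [-80, -5] degrees), E in the
#' extended basin (phi in [-170, -70], psi in [90, 180] or [-180, -170]),
#' else C; termini without both dihedrals are C. Runs shorter than the
#' minimum segment length (4 for H, 3 for E) are smoothed to coil, and
#' maximal non-coil runs become segments.
#'
#' @param s A `backbone`.
#' @return Object of class `secondary_segments`: per-residue `labels` and a
#'   data.frame `segments` (kind, start, end; 0-based half-open).
#' @export
assign_secondary_structure <- function(s) {
  stopifnot(inherits(s, "backbone"))
  tor <- .backbone_torsions(s)
  lab <- rep("C", s$n)
  ok <- is.finite(tor$phi) & is.finite(tor$psi)
  phi <- tor$phi; psi <- tor$psi
  is_h <- ok & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  is_e <- ok & phi >= -170 & phi <= -70 &
    ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -170))
  lab[is_e] <- "E"
  lab[is_h] <- "H"
  lab <- .smooth_runs(lab)
  segments_from_labels(lab)
}

#' @noRd
.smooth_runs <- function(lab) {
  r <- rle(lab)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v %in% names(.MIN_RUN) && r$lengths[k] < .MIN_RUN[[v]])
      r$values[k] <- "C"
  }
  inverse.rle(r)
}

#' Build segments from per-residue labels
#'
#' @param labels Per-residue labels from `{"H","E","C"}` (sub-minimum runs
#'   are smoothed to coil first).
#' @return A `secondary_segments` object; `segments` has 0-based half-open
#'   `[start, end)` intervals of maximal non-coil runs.
#' @export
segments_from_labels <- function(labels) {
  if (!all(labels %in% c("H", "E", "C")))
    stop("labels must come from {H, E, C}")
  labels <- .smooth_runs(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != "C"
  segments <- data.frame(kind = r$values[keep], start = starts[keep],
                         end = ends[keep], stringsAsFactors = FALSE)
  structure(list(labels = labels, segments = segments),
            class = "secondary_segments")
}

#' @export
print.secondary_segments <- function(x, ...) {
  cat(sprintf("<secondary_segments> %d residues, %d segment(s): %s\n",
              length(x$labels), nrow(x$segments),
              paste(sprintf("%s[%d,%d)", x$segments$kind, x$segments$start,
                            x$segments$end), collapse = " ")))
  invisible(x)
}

#' Find CA-distance contacts
#'
#' All residue pairs `(i, j)` (0-based, `j - i >= min_sep`) with CA-CA
#' distance at or below the cutoff.
#'
#' @param s A `backbone`.
#' @param cutoff Distance cutoff in angstrom (default 8).
#' @param min_sep Minimum sequence separation (default 3).
#' @return data.frame with columns `i`, `j` (0-based), `distance`, and
#'   `order` (NA until [contact_order()] is applied).
#' @export
find_contacts <- function(s, cutoff = 8.0, min_sep = 3L) {
  stopifnot(inherits(s, "backbone"))
  D <- as.matrix(stats::dist(s$CA))
  idx <- which(upper.tri(D) & (col(D) - row(D) >= min_sep) & D <= cutoff,
               arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0),
                      order = integer(0)))
  out <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                    distance = D[idx], order = rep(NA_integer_, nrow(idx)))
  rownames(out) <- NULL
  out[order(out$i, out$j), , drop = FALSE]
}

#' Assign secondary-structure orders to contacts
#'
#' The order of a contact `(i, j)` is the number of distinct non-coil
#' secondary-structure segments lying entirely inside the open residue
#' interval `(i, j)`; a contact with both endpoints inside one segment has
#' order 0 (the same-segment rule is then a special case: no whole segment
#' can fit strictly between).
#'
#' @param s A `backbone` (used only for bounds checking; may be NULL).
#' @param segments A `secondary_segments`.
#' @param contacts data.frame from [find_contacts()] (or with `i`, `j`).
#' @return The contacts data.frame with `order` filled in.
#' @export
contact_order <- function(s = NULL, segments, contacts) {
  stopifnot(inherits(segments, "secondary_segments"))
  n <- length(segments$labels)
  if (nrow(contacts) == 0L) return(contacts)
  if (any(contacts$i < 0L | contacts$j >= n | contacts$i >= contacts$j))
    stop("contact indices out of range")
  seg <- segments$segments
  contacts$order <- vapply(seq_len(nrow(contacts)), function(k) {
    i <- contacts$i[k]; j <- contacts$j[k]
    # segments entirely inside the open interval (i, j):
    # start > i and end - 1 < j  <=>  start >= i + 1, end <= j
    sum(seg$start >= i + 1L & seg$end <= j)
  }, numeric(1))
  contacts
}

#' Pooled contact-order statistics over a structure set
#'
#' Computes contacts and their orders for every member and pools all
#' contacts across the set for the mean and median; a per-structure
#' breakdown is included. A set with zero contacts is flagged undefined
#' (`NA` statistics), never reported as 0.
#'
#' @param set A `structure_set`.
#' @param cutoff,min_sep Contact definition, as in [find_contacts()].
#' @return List with `mean_order`, `median_order`, `n_contacts`,
#'   `undefined` flag and `per_structure` data.frame.
#' @export
set_contact_stats <- function(set, cutoff = 8.0, min_sep = 3L) {
  stopifnot(inherits(set, "structure_set"))
  per <- lapply(set$members, function(m) {
    segs <- assign_secondary_structure(m)
    ct <- contact_order(m, segs, find_contacts(m, cutoff, min_sep))
    ct
  })
  orders <- unlist(lapply(per, `[[`, "order"), use.names = FALSE)
  tab <- data.frame(
    id = names(set$members),
    n_contacts = vapply(per, nrow, integer(1)),
    mean_order = vapply(per, function(ct)
      if (nrow(ct)) mean(ct$order) else NA_real_, numeric(1)),
    row.names = NULL
  )
  if (!length(orders)) {
    return(list(mean_order = NA_real_, median_order = NA_real_,
                n_contacts = 0L, undefined = TRUE, per_structure = tab))
  }
  list(mean_order = mean(orders), median_order = stats::median(orders),
       n_contacts = length(orders), undefined = FALSE, per_structure = tab)
}

# -- motif cover --------------------------------------------------------------

#' Match a backbone motif against a target by sliding-window RMSD
#'
#' Single-segment motifs are slid over every window of the target and
#' superposed with Kabsch; windows with CA-RMSD at or below the cutoff are
#' matches. A multi-segment motif (a list of backbones) tries ordered
#' placements of its segments with at least one-residue gaps, up to
#' `max_placements` combinations, superposing all segment CAs jointly.
#'
#' @param motif A `backbone` or list of `backbone` segments.
#' @param target A `backbone`.
#' @param rmsd_cut RMSD cutoff in angstrom.
#' @param max_placements Placement budget for multi-segment motifs.
#' @return data.frame of matches: one row per placement, with `rmsd` and a
#'   `residues` list-column of covered 0-based residue indices.
#' @export
match_motif <- function(motif, target, rmsd_cut = 1.0,
                        max_placements = 2000L) {
  stopifnot(inherits(target, "backbone"))
  segs <- if (inherits(motif, "backbone")) list(motif) else motif
  stopifnot(all(vapply(segs, inherits, logical(1), "backbone")))
  lens <- vapply(segs, function(m) m$n, integer(1))
  L <- target$n
  if (sum(lens) + (length(segs) - 1L) > L)
    return(data.frame(rmsd = numeric(0),
                      residues = I(list())))
  motif_ca <- do.call(rbind, lapply(segs, `[[`, "CA"))
  placements <- .ordered_placements(lens, L, max_placements)
  hits <- list()
  for (pl in placements) {
    resid <- unlist(mapply(function(st, ln) st:(st + ln - 1L), pl, lens,
                           SIMPLIFY = FALSE))
    fit <- .kabsch(target$CA[resid, , drop = FALSE], motif_ca)
    if (fit$rmsd <= rmsd_cut)
      hits[[length(hits) + 1L]] <- list(rmsd = fit$rmsd, residues = resid - 1L)
  }
  data.frame(rmsd = vapply(hits, `[[`, numeric(1), "rmsd"),
             residues = I(lapply(hits, `[[`, "residues")))
}

#' Ordered non-overlapping window placements (1-based starts)
#' @noRd
.ordered_placements <- function(lens, L, budget) {
  k <- length(lens)
  out <- list()
  recurse <- function(acc, next_min, depth) {
    if (length(out) >= budget) return()
    if (depth > k) { out[[length(out) + 1L]] <<- acc; return() }
    remaining <- if (depth < k) sum(lens[(depth + 1L):k]) + (k - depth) else 0L
    last_start <- L - remaining - lens[depth] + 1L
    if (last_start < next_min) return()
    for (st in next_min:last_start) {
      recurse(c(acc, st), st + lens[depth] + 1L, depth + 1L)
      if (length(out) >= budget) return()
    }
  }
  recurse(integer(0), 1L, 1L)
  out
}

#' Greedy set cover over motif candidates
#'
#' Iteratively selects the candidate covering the most still-uncovered
#' elements (ties broken by smallest motif id for determinism) until the
#' covered fraction reaches `tau` or no candidate adds coverage. When `tau`
#' is unreachable a partial result is returned with `reached < tau` flagged.
#'
#' @param universe Character vector of elements to cover.
#' @param candidates Named list: motif id -> character vector of covered
#'   elements.
#' @param tau Target covered fraction (default 1).
#' @return Object of class `cover_result` with `selected`, `coverage_curve`,
#'   `n_to_threshold`, `reached` and `tau`.
#' @export
greedy_cover <- function(universe, candidates, tau = 1.0) {
  if (!length(candidates)) stop("candidate set must be non-empty")
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  ids <- names(candidates)
  if (is.null(ids)) ids <- as.character(seq_along(candidates))
  cand <- lapply(candidates, function(x) intersect(unique(x), universe))
  uncovered <- universe
  selected <- character(0)
  curve <- numeric(0)
  while (length(uncovered) && (1 - length(uncovered) / length(universe)) < tau) {
    gains <- vapply(cand, function(x) sum(x %in% uncovered), integer(1))
    if (max(gains) == 0L) break
    pick <- ids[gains == max(gains)]
    pick <- sort(pick)[1L]
    selected <- c(selected, pick)
    uncovered <- setdiff(uncovered, cand[[pick]])
    curve <- c(curve, 1 - length(uncovered) / length(universe))
  }
  reached <- if (length(curve)) curve[length(curve)] else 0
  structure(list(selected = selected, coverage_curve = curve,
                 n_to_threshold = if (reached >= tau - 1e-12)
                   length(selected) else NA_integer_,
                 reached = reached, tau = tau),
            class = "cover_result")
}

#' @export
print.cover_result <- function(x, ...) {
  cat(sprintf("<cover_result> %d motif(s) selected, coverage %.1f%% (tau = %g%s)\n",
              length(x$selected), 100 * x$reached, x$tau,
              if (is.na(x$n_to_threshold)) ", threshold not reached" else ""))
  invisible(x)
}

#' Motif-cover analysis of a structure set
#'
#' The universe is every residue plus every CA contact across the set; each
#' library motif's candidate set is everything it covers over all
#' structures ([match_motif()] per structure: residues in matched windows,
#' plus contacts with both endpoints covered by the same match). Greedy
#' cover then estimates how many motifs explain the set — a low-diversity
#' set needs fewer motifs than a high-diversity one.
#'
#' @param set A `structure_set`.
#' @param motif_library Named list of motifs (each a `backbone` or a list of
#'   `backbone` segments).
#' @param rmsd_cut Match cutoff in angstrom.
#' @param tau Coverage threshold.
#' @param cutoff,min_sep Contact definition.
#' @return List with the `cover_result` and the universe/candidate sizes.
#' @export
cover_analysis <- function(set, motif_library, rmsd_cut = 1.0, tau = 1.0,
                           cutoff = 8.0, min_sep = 3L) {
  stopifnot(inherits(set, "structure_set"))
  if (!length(motif_library)) stop("empty motif library")
  if (is.null(names(motif_library)))
    names(motif_library) <- sprintf("motif%03d", seq_along(motif_library))
  universe <- character(0)
  contact_tab <- list()
  for (id in names(set$members)) {
    m <- set$members[[id]]
    universe <- c(universe, sprintf("%s:r%d", id, 0:(m$n - 1L)))
    ct <- find_contacts(m, cutoff, min_sep)
    if (nrow(ct))
      universe <- c(universe, sprintf("%s:c%d-%d", id, ct$i, ct$j))
    contact_tab[[id]] <- ct
  }
  candidates <- lapply(names(motif_library), function(mid) {
    covered <- character(0)
    for (id in names(set$members)) {
      hits <- match_motif(motif_library[[mid]], set$members[[id]], rmsd_cut)
      if (!nrow(hits)) next
      for (resid in hits$residues) {
        covered <- c(covered, sprintf("%s:r%d", id, resid))
        ct <- contact_tab[[id]]
        if (nrow(ct)) {
          inside <- ct$i %in% resid & ct$j %in% resid
          if (any(inside))
            covered <- c(covered,
                         sprintf("%s:c%d-%d", id, ct$i[inside], ct$j[inside]))
        }
      }
    }
    unique(covered)
  })
  names(candidates) <- names(motif_library)
  res <- greedy_cover(universe, candidates, tau)
  list(cover = res, universe_size = length(unique(universe)),
       candidate_sizes = lengths(candidates))
}
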