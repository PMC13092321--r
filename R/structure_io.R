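# Reading, writing and filtering single-chain protein backbones.

#' Backbone structure container
#'
#' Holds one protein chain as ordered backbone coordinates (N, CA, C and
#' optionally O), the unit every geometric operation in the package consumes.
#' Residues are indexed 0-based and contiguous internally; author residue
#' numbering from the source file is retained separately for reporting.
#'
#' @param id Character identifier.
#' @param N,CA,C Numeric n x 3 coordinate matrices (angstrom), one row per
#'   residue, in sequence order.
#' @param O Optional n x 3 matrix of carbonyl oxygens.
#' @param chain Chain identifier (single character, default `"A"`).
#' @param author_numbering Optional integer vector of source-file residue
#'   numbers; defaults to `1:n` on write.
#' @param ss_labels Optional per-residue labels from `{"H","E","C"}`.
#' @return An object of class `backbone`.
#' @export
backbone_structure <- function(id, N, CA, C, O = NULL, chain = "A",
                               author_numbering = NULL, ss_labels = NULL) {
  N <- as.matrix(N); CA <- as.matrix(CA); C <- as.matrix(C)
  n <- nrow(CA)
  if (n < 1L) stop("backbone must contain at least one residue")
  for (m in list(N, CA, C)) {
    if (!is.numeric(m) || ncol(m) != 3L || nrow(m) != n)
      stop("N, CA, C must be numeric n x 3 matrices of equal length")
    if (!all(is.finite(m))) stop("backbone coordinates must all be finite")
  }
  if (!is.null(O)) {
    O <- as.matrix(O)
    if (nrow(O) != n || ncol(O) != 3L || !all(is.finite(O)))
      stop("O must be a finite n x 3 matrix")
  }
  if (!is.null(author_numbering)) {
    author_numbering <- as.integer(author_numbering)
    if (length(author_numbering) != n)
      stop("author_numbering length must equal residue count")
    if (any(diff(author_numbering) <= 0L))
      stop("author numbering must be strictly increasing")
  }
  if (!is.null(ss_labels)) {
    if (length(ss_labels) != n || !all(ss_labels %in% c("H", "E", "C")))
      stop("ss_labels must be per-residue labels from {H, E, C}")
  }
  structure(
    list(id = as.character(id), n = n, N = N, CA = CA, C = C, O = O,
         chain = as.character(chain), author_numbering = author_numbering,
         ss_labels = ss_labels),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s: %d residues, chain %s%s\n", x$id, x$n, x$chain,
              if (is.null(x$O)) " (N,CA,C)" else " (N,CA,C,O)"))
  invisible(x)
}

#' Number of residues in a backbone
#' @param s A `backbone`.
#' @return Integer residue count.
#' @export
residue_count <- function(s) {
  stopifnot(inherits(s, "backbone"))
  s$n
}

#' Ordered collection of backbone structures
#'
#' A set of [backbone_structure()] objects with unique ids and optional
#' cluster labels (one column per hierarchy level).
#'
#' @param members List of `backbone` objects.
#' @param labels Optional data.frame whose first column is the structure id
#'   and remaining columns are cluster labels, one per hierarchy level; every
#'   member must be labelled at every level.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(members, labels = NULL) {
  if (length(members) == 0L) stop("structure set must be non-empty")
  ok <- vapply(members, inherits, logical(1), what = "backbone")
  if (!all(ok)) stop("all members must be backbone structures")
  ids <- vapply(members, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("structure ids must be unique within a set")
  names(members) <- ids
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (ncol(labels) < 2L) stop("labels need an id column plus >= 1 level")
    if (anyDuplicated(labels[[1L]])) stop("duplicate ids in label table")
    miss <- setdiff(ids, as.character(labels[[1L]]))
    if (length(miss))
      stop("missing cluster labels for: ", paste(miss, collapse = ", "))
    labels <- labels[match(ids, as.character(labels[[1L]])), , drop = FALSE]
    rownames(labels) <- NULL
  }
  structure(list(members = members, labels = labels), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  lens <- vapply(x$members, function(m) m$n, integer(1))
  cat(sprintf("<structure_set> %d structures, lengths %d-%d%s\n",
              length(x$members), min(lens), max(lens),
              if (is.null(x$labels)) ""
              else sprintf(", %d label level(s)", ncol(x$labels) - 1L)))
  invisible(x)
}

#' @export
length.structure_set <- function(x) length(x$members)

#' Structure ids of a set
#' @param set A `structure_set`.
#' @return Character vector of ids in set order.
#' @export
set_ids <- function(set) {
  stopifnot(inherits(set, "structure_set"))
  names(set$members)
}

.BB_ATOMS <- c("N", "CA", "C", "O")

#' Read a protein backbone from a PDB or mmCIF file
#'
#' Parses the file (dialect chosen by extension, `.cif`/`.mmcif` vs PDB),
#' keeps the first model, drops heteroatoms and waters, selects one chain
#' and returns the ordered N/CA/C(/O) backbone. Residues missing any of
#' N/CA/C are dropped with a warning by default; with `strict = TRUE` such
#' files are rejected. Alternate locations keep the highest-occupancy
#' conformer.
#'
#' @param path File path.
#' @param chain Optional chain selector; required when the file holds more
#'   than one protein chain.
#' @param id Identifier for the returned structure (default: file base name).
#' @param strict Reject structures with incomplete backbone residues instead
#'   of truncating them.
#' @return A [backbone_structure()].
#' @export
read_structure <- function(path, chain = NULL, id = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("file has chains {", paste(chains, collapse = ","),
           "}; pass a chain selector")
    chain <- chains[[1L]]
  }
  if (!(chain %in% chains)) stop("chain '", chain, "' not present in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  # highest-occupancy alt-loc conformer per (residue, atom)
  if (!is.null(at$o)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$resno, at$insert, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at <- at[at$elety %in% .BB_ATOMS, , drop = FALSE]
  if (nrow(at) == 0L) stop("no backbone atoms for chain ", chain, " in ", path)
  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resno <- at$resno[!duplicated(rkey)]
  ukeys <- unique(rkey)
  coord <- function(atom) {
    out <- matrix(NA_real_, length(ukeys), 3)
    sel <- at$elety == atom
    out[match(rkey[sel], ukeys), ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    out
  }
  Nm <- coord("N"); CAm <- coord("CA"); Cm <- coord("C"); Om <- coord("O")
  complete <- stats::complete.cases(Nm) & stats::complete.cases(CAm) &
    stats::complete.cases(Cm)
  if (!all(complete)) {
    if (strict)
      stop(sum(!complete), " residue(s) missing backbone atoms in ", path)
    warning(sum(!complete), " residue(s) missing N/CA/C dropped from ",
            basename(path))
  }
  if (!any(complete)) stop("no residue with a complete backbone in ", path)
  has_o <- all(stats::complete.cases(Om[complete, , drop = FALSE]))
  backbone_structure(
    id = if (is.null(id)) sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                              ignore.case = TRUE) else id,
    N = Nm[complete, , drop = FALSE],
    CA = CAm[complete, , drop = FALSE],
    C = Cm[complete, , drop = FALSE],
    O = if (has_o) Om[complete, , drop = FALSE] else NULL,
    chain = chain,
    author_numbering = resno[complete]
  )
}

#' Write a backbone to a PDB file
#'
#' Emits backbone ATOM records only (N, CA, C and O when present). Author
#' numbering is preserved when available, else residues are numbered 1..n.
#'
#' @param s A `backbone`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "backbone"))
  atoms <- c("N", "CA", "C", if (!is.null(s$O)) "O")
  k <- length(atoms)
  resno <- if (is.null(s$author_numbering)) seq_len(s$n) else s$author_numbering
  xyz <- matrix(NA_real_, s$n * k, 3)
  for (j in seq_along(atoms)) xyz[seq(j, by = k, length.out = s$n), ] <- s[[atoms[j]]]
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(xyz)),
      resno = rep(resno, each = k),
      resid = rep("GLY", s$n * k),
      elety = rep(atoms, s$n),
      chain = rep(substr(s$chain, 1, 1), s$n * k)
    )
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Filter a structure set by chain length
#'
#' Keeps members whose residue count lies in `[min_len, max_len]`
#' (inclusive), preserving order and any cluster labels.
#'
#' @param set A `structure_set`.
#' @param min_len,max_len Inclusive length bounds.
#' @return A `structure_set` (possibly with zero survivors, in which case an
#'   empty-member list is returned with class kept via an internal marker).
#' @export
filter_set <- function(set, min_len, max_len) {
  stopifnot(inherits(set, "structure_set"))
  if (min_len > max_len) stop("min_len must be <= max_len")
  lens <- vapply(set$members, function(m) m$n, integer(1))
  keep <- lens >= min_len & lens <= max_len
  members <- set$members[keep]
  labels <- if (!is.null(set$labels)) set$labels[keep, , drop = FALSE] else NULL
  structure(list(members = members, labels = labels), class = "structure_set")
}

#' Read a cluster label table
#'
#' Tab-separated text, no header: structure id, then one label column per
#' hierarchy level (level 1 coarsest).
#'
#' @param path File path.
#' @return data.frame with columns `id`, `level1`, `level2`, ...
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("label table needs id + >= 1 label column")
  names(tab) <- c("id", paste0("level", seq_len(ncol(tab) - 1L)))
  if (anyDuplicated(tab$id)) stop("duplicate ids in label table")
  tab
}
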