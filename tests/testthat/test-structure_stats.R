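test_that("dihedral-basin assignment labels ideal fixtures correctly", {
  hseg <- assign_secondary_structure(make_helix(20))
  expect_equal(nrow(hseg$segments), 1L)
  expect_equal(hseg$segments$kind, "H")
  expect_gte(hseg$segments$end - hseg$segments$start, 16L)
  eseg <- assign_secondary_structure(make_strand(10))
  expect_equal(nrow(eseg$segments), 1L)
  expect_equal(eseg$segments$kind, "E")
  # unstructured random walks yield at most one spurious segment
  coil <- make_multisegment(list(c("coil", 25)), seed = 13)
  expect_lte(nrow(assign_secondary_structure(coil)$segments), 1L)
})

test_that("sub-minimum-length runs are smoothed to coil", {
  lab <- c("C", "H", "H", "C", "E", "E", "E", "C", "H", "H", "H", "H")
  seg <- segments_from_labels(lab)
  # the 2-residue H run dies, the 3-residue E and 4-residue H survive
  expect_equal(seg$segments$kind, c("E", "H"))
  expect_equal(seg$labels[2:3], c("C", "C"))
})

test_that("CA contacts: helix pattern, extended strand, separation filter", {
  h <- make_helix(20)
  ct <- find_contacts(h)
  expect_true(all(sort(unique(ct$j - ct$i)) == c(3L, 4L)))
  expect_equal(nrow(find_contacts(make_strand(30))), 0L)
  expect_equal(nrow(find_contacts(make_helix(5), min_sep = 10L)), 0L)
})

test_that("contact order counts whole segments strictly between the contact", {
  # helix contacts are all intra-segment: order 0 throughout
  h <- make_helix(20)
  segs <- assign_secondary_structure(h)
  ct <- contact_order(h, segs, find_contacts(h))
  expect_true(all(ct$order == 0))
  # helix-coil-strand-coil-helix: a helix1/helix2 contact has one whole
  # strand segment strictly between -> order 1
  lab <- c(rep("H", 10), rep("C", 3), rep("E", 6), rep("C", 3), rep("H", 10))
  seg <- segments_from_labels(lab)
  ct1 <- contact_order(NULL, seg,
                       data.frame(i = 4L, j = 26L, distance = 6,
                                  order = NA_integer_))
  expect_equal(ct1$order, 1)
  # a contact across a coil linker with no complete segment inside: order 0
  ct0 <- contact_order(NULL, seg,
                       data.frame(i = 9L, j = 13L, distance = 6,
                                  order = NA_integer_))
  expect_equal(ct0$order, 0)
  # endpoints inside the strand segment itself: order 0
  cts <- contact_order(NULL, seg,
                       data.frame(i = 13L, j = 18L, distance = 5,
                                  order = NA_integer_))
  expect_equal(cts$order, 0)
})

test_that("contact order is invariant under rigid motion", {
  s <- mixed_chain(6)
  segs <- assign_secondary_structure(s)
  ct <- contact_order(s, segs, find_contacts(s))
  sr <- rigid_transform(s, seed = 4)
  ctr <- contact_order(sr, assign_secondary_structure(sr),
                       find_contacts(sr))
  expect_equal(ct$order, ctr$order)
})

test_that("pooled set statistics: helix truths, duplication invariance, arithmetic", {
  helices <- structure_set(lapply(1:3, function(i)
    make_helix(20, id = paste0("h", i))))
  st <- set_contact_stats(helices)
  expect_equal(st$mean_order, 0)
  expect_equal(st$median_order, 0)
  dup <- structure_set(c(helices$members,
                         lapply(helices$members, function(m) {
                           m$id <- paste0(m$id, "b"); m
                         })))
  st2 <- set_contact_stats(dup)
  expect_equal(st2$mean_order, st$mean_order)
  expect_equal(st2$median_order, st$median_order)
  # pooled multiset {0,0,2} + {4}: mean 1.5, median 1.0
  pooled <- c(0, 0, 2, 4)
  expect_equal(mean(pooled), 1.5)
  expect_equal(median(pooled), 1.0)
  # a set with no contacts is undefined, not zero
  strands <- structure_set(list(make_strand(30)))
  st3 <- set_contact_stats(strands)
  expect_true(st3$undefined)
  expect_true(is.na(st3$mean_order))
})

test_that("motif matching: self-match, class separation, threshold limit", {
  target <- mixed_chain(9, plan = list(c("helix", 12), c("coil", 4),
                                       c("strand", 8)))
  frag <- backbone_structure("frag", target$N[6:13, ], target$CA[6:13, ],
                             target$C[6:13, ])
  hits <- match_motif(frag, target, rmsd_cut = 0.5)
  expect_gte(nrow(hits), 1L)
  best <- which.min(hits$rmsd)
  expect_lt(hits$rmsd[best], 1e-6)
  expect_equal(hits$residues[[best]], 5:12)
  # helix fragment cannot match a pure strand
  expect_equal(nrow(match_motif(make_helix(8), make_strand(20),
                                rmsd_cut = 0.5)), 0L)
  # an enormous cutoff matches every window
  all_hits <- match_motif(make_helix(8), make_strand(20), rmsd_cut = 1e6)
  expect_equal(nrow(all_hits), 13L)
})

test_that("greedy cover: curated instances, greedy bound, concave curve", {
  r1 <- greedy_cover(c("a", "b", "c"), list(m1 = c("a", "b", "c")))
  expect_equal(r1$selected, "m1")
  expect_equal(r1$coverage_curve, 1)
  expect_equal(r1$n_to_threshold, 1L)
  r2 <- greedy_cover(c("a", "b", "c", "d"),
                     list(m1 = c("a", "b"), m2 = "c", m3 = "d",
                          m4 = c("c", "d")))
  expect_equal(r2$selected, c("m1", "m4"))
  expect_equal(r2$n_to_threshold, 2L)
  expect_equal(r2$n_to_threshold,
               brute_force_cover(c("a", "b", "c", "d"),
                                 list(m1 = c("a", "b"), m2 = "c", m3 = "d",
                                      m4 = c("c", "d"))))
  singles <- greedy_cover(letters[1:5],
                          setNames(as.list(letters[1:5]), letters[1:5]))
  expect_equal(length(singles$selected), 5L)
  # random small instances: within the ln|U| + 1 factor of the optimum
  set.seed(17)
  for (r in 1:40) {
    U <- letters[seq_len(sample(5:12, 1))]
    k <- sample(3:6, 1)
    cand <- lapply(seq_len(k), function(i)
      sample(U, sample(seq_along(U), 1)))
    names(cand) <- sprintf("m%d", seq_len(k))
    if (!all(U %in% unlist(cand))) next
    g <- greedy_cover(U, cand)
    opt <- brute_force_cover(U, cand)
    expect_lte(length(g$selected), ceiling((log(length(U)) + 1) * opt))
    expect_true(all(diff(g$coverage_curve) >= -1e-12))
    gains <- diff(c(0, g$coverage_curve))
    expect_true(all(diff(gains) <= 1e-12))  # marginal gains nonincreasing
  }
  # unreachable threshold: partial result, flagged
  part <- greedy_cover(c("a", "b"), list(m1 = "a"))
  expect_true(is.na(part$n_to_threshold))
  expect_equal(part$reached, 0.5)
  expect_error(greedy_cover(character(0), list(m1 = "a")), "empty")
  expect_error(greedy_cover("a", list()), "non-empty")
})

test_that("cover analysis: fewer motifs explain a low-diversity set", {
  lib <- list(hfrag = make_helix(8, id = "hfrag"),
              sfrag = make_strand(8, id = "sfrag"))
  low <- structure_set(lapply(1:4, function(i)
    make_helix(20, id = paste0("h", i))))
  hi <- structure_set(list(
    make_helix(20, id = "h1"), make_strand(20, id = "s1"),
    mixed_chain(5, id = "m1", plan = list(c("helix", 10), c("coil", 4),
                                          c("strand", 8)))))
  cl <- cover_analysis(low, lib, rmsd_cut = 0.8, tau = 0.8)
  ch <- cover_analysis(hi, lib, rmsd_cut = 0.8, tau = 0.8)
  expect_lte(length(cl$cover$selected), length(ch$cover$selected))
  # one structure class + its own fragment: a single motif suffices
  expect_equal(length(cl$cover$selected), 1L)
  expect_error(cover_analysis(low, list()), "empty")
})
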