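test_that("cluster orderings are contiguous by cluster and seed-deterministic", {
  labels <- c("a", "b", "a", "c", "b", "b")
  ord <- cluster_ordering(labels, seed = 3)
  runs <- rle(labels[ord])
  expect_equal(sort(runs$lengths), c(1L, 2L, 3L))
  expect_equal(length(runs$values), 3L)
  expect_identical(ord, cluster_ordering(labels, seed = 3))
  expect_false(identical(ord, cluster_ordering(labels, seed = 4)))
  one <- cluster_ordering(rep("x", 4), seed = 1)
  expect_setequal(one, 1:4)
})

test_that("degenerate races behave: zero rounds, zero drops, reproducibility", {
  cc <- make_clustered_cloud(3, 6, 20, 4, seed = 2)
  ref <- make_clustered_cloud(3, 6, 20, 4, seed = 9, means_seed = 2)
  racers <- list(racer_spec("random", "random"),
                 racer_spec("clustered", "clustered"))
  tr0 <- run_race(cc$embeddings, ref$embeddings, racers,
                  drop_per_round = 5, rounds = 0, replicates = 3,
                  base_seed = 1, d = 4, labels = cc$labels)
  expect_equal(ncol(tr0$scores), 1L)
  expect_lt(diff(range(tr0$scores[, 1])), 1e-9)
  trc <- run_race(cc$embeddings, ref$embeddings, racers,
                  drop_per_round = 0, rounds = 3, replicates = 2,
                  base_seed = 1, d = 4, labels = cc$labels)
  expect_lt(max(abs(sweep(trc$scores, 1, trc$scores[, 1]))), 1e-9)
  trA <- run_race(cc$embeddings, ref$embeddings, racers,
                  drop_per_round = 6, rounds = 4, replicates = 3,
                  base_seed = 7, d = 4, labels = cc$labels)
  trB <- run_race(cc$embeddings, ref$embeddings, racers,
                  drop_per_round = 6, rounds = 4, replicates = 3,
                  base_seed = 7, d = 4, labels = cc$labels)
  expect_identical(trA$raw, trB$raw)
  expect_error(run_race(cc$embeddings, ref$embeddings, racers,
                        drop_per_round = 30, rounds = 2, replicates = 1,
                        base_seed = 1, d = 4, labels = cc$labels),
               "too many rounds")
  # remaining set sizes are equal across racers by construction
  expect_equal(trA$rounds, 60 - 6 * (0:4))
})

test_that("clustered racers degrade the distance faster than random ones", {
  cc <- make_clustered_cloud(5, 8, 100, 8, seed = 2)
  ref <- make_clustered_cloud(5, 8, 100, 8, seed = 99, means_seed = 2)
  tr <- run_race(cc$embeddings, ref$embeddings,
                 list(racer_spec("random", "random"),
                      racer_spec("clustered", "clustered")),
                 drop_per_round = 50, rounds = 8, replicates = 20,
                 base_seed = 7, d = 8, labels = cc$labels)
  final <- dim(tr$scores)[2]
  expect_gte(tr$scores[2, final], tr$scores[1, final])
  gap <- tr$raw[2, final, ] - tr$raw[1, final, ]
  expect_gte(mean(gap > 0), 0.9)
  # clustered-racer curve rises in expectation along rounds
  expect_true(all(diff(tr$scores[2, ]) > -1e-6))
})

test_that("hierarchy races order racers by hierarchy level", {
  hc <- make_hierarchical_cloud(4, 3, 12, 4, 30, 8, seed = 2)
  hr <- make_hierarchical_cloud(4, 3, 12, 4, 30, 8, seed = 50,
                                means_seed = 2)
  tr <- hierarchy_race(hc$embeddings, hr$embeddings, levels = c(1, 2),
                       labels = hc$labels, drop_per_round = 40, rounds = 7,
                       replicates = 20, base_seed = 7, d = 8)
  final <- length(tr$rounds)
  expect_gte(tr$scores[1, final], tr$scores[2, final])  # L1 >= L2
  expect_gte(tr$scores[2, final], tr$scores[3, final])  # L2 >= random
  # identical labels at both levels: racers statistically indistinguishable
  same <- data.frame(level1 = hc$labels$level1, level2 = hc$labels$level1)
  tr2 <- hierarchy_race(hc$embeddings, hr$embeddings, levels = c(1, 2),
                        labels = same, drop_per_round = 40, rounds = 7,
                        replicates = 20, base_seed = 7, d = 8)
  m1 <- tr2$scores[1, final]; m2 <- tr2$scores[2, final]
  pooled_sd <- sqrt(mean(c(tr2$score_sd[1, final], tr2$score_sd[2, final])^2))
  expect_lt(abs(m1 - m2), pooled_sd)
})

test_that("clustered racers require labels at the requested level", {
  cc <- make_clustered_cloud(3, 6, 10, 4, seed = 2)
  ref <- make_clustered_cloud(3, 6, 10, 4, seed = 9, means_seed = 2)
  expect_error(
    run_race(cc$embeddings, ref$embeddings,
             list(racer_spec("clustered", "clustered")),
             drop_per_round = 3, rounds = 2, replicates = 1, base_seed = 1,
             d = 4),
    "labels")
  expect_error(
    run_race(cc$embeddings, ref$embeddings,
             list(racer_spec("clustered", "clustered", level = 2)),
             drop_per_round = 3, rounds = 2, replicates = 1, base_seed = 1,
             d = 4, labels = cc$labels),
    "level 2")
})
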