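test_that("condition correlation handles duplicate and mirrored rows", {
  m <- matrix(rnorm(44), 2, 22,
              dimnames = list(c("a", "b"), NULL))
  m[2, ] <- m[1, ]
  r <- condition_correlation(as_feature_matrix(m))
  expect_equal(r["a", "b"], 1)
  m[2, ] <- -m[1, ]
  r <- condition_correlation(as_feature_matrix(m))
  expect_equal(r["a", "b"], -1)
  m[2, ] <- 0
  expect_error(condition_correlation(as_feature_matrix(m)), "b")
})

test_that("worked-example correlations match the brute-force Pearson oracle", {
  fm <- table2_features(normalize = TRUE)
  r <- condition_correlation(fm)
  for (i in 1:4) for (j in 1:4)
    expect_equal(r[i, j], pearson_bf(unclass(fm)[i, ], unclass(fm)[j, ]),
                 tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("worked-example clustering recovers the reference grouping", {
  fm <- table2_features(normalize = TRUE)
  r <- condition_correlation(fm)
  cl <- cluster_conditions(r, linkage = "average", k = 2)
  grp <- cl$clusters
  expect_equal(grp[["CLC"]], grp[["VBL"]])
  expect_equal(grp[["Control"]], grp[["PTX"]])
  expect_false(grp[["PTX"]] == grp[["CLC"]])
  # brute force: of all 7 two-block partitions, the reference one has the
  # lowest mean within-block correlation distance
  parts <- two_block_partitions(rownames(r))
  costs <- vapply(parts, partition_cost, numeric(1), d = 1 - r)
  best <- parts[[which.min(costs)]]
  key <- vapply(best, function(b) paste(sort(b), collapse = ","),
                character(1))
  expect_setequal(key, c("CLC,VBL", "Control,PTX"))
  # the stabilizer anti-correlates with both disruptors
  expect_lt(r["PTX", "CLC"], 0)
  expect_lt(r["PTX", "VBL"], 0)
  expect_gt(r["CLC", "VBL"], 0)
})

test_that("clustering is invariant to condition order", {
  fm <- table2_features(normalize = TRUE)
  r <- condition_correlation(fm)
  ref <- cluster_conditions(r, k = 2)$clusters
  ref_sets <- unname(split(names(ref), ref))
  all_perms <- do.call(rbind, combinat_perms(4))
  for (i in seq_len(nrow(all_perms))) {
    p <- all_perms[i, ]
    cl <- cluster_conditions(r[p, p], k = 2)$clusters
    sets <- unname(split(names(cl), cl))
    expect_setequal(vapply(sets, function(s) paste(sort(s), collapse = ","),
                           character(1)),
                    vapply(ref_sets, function(s) paste(sort(s), collapse = ","),
                           character(1)))
  }
})

test_that("cluster mechanics: first merge, singletons, monotone heights", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6.01),
             c = c(6, 1, 5, 2, 4, 3))
  r <- condition_correlation(as_feature_matrix(m))
  cl <- cluster_conditions(r, k = 2)
  expect_equal(sort(cl$tree$merge[1, ]), c(-2, -1))  # identical pair first
  expect_false(is.unsorted(cl$tree$height))
  expect_equal(unname(cluster_conditions(r, k = 3)$clusters), 1:3)
  expect_error(cluster_conditions(r, linkage = "ward"), "average")
  expect_error(cluster_conditions(r, k = 9), "k")
})

test_that("correlation distance ignores positive affine feature rescaling", {
  fm <- table2_features(normalize = TRUE)
  r <- condition_correlation(fm)
  m2 <- unclass(fm)
  m2[2, ] <- 3.7 * m2[2, ] + 0.4
  r2 <- condition_correlation(as_feature_matrix(m2))
  expect_equal(r2, r, tolerance = 1e-12)
})

test_that("archetype recovery scores perfectly on separable replicates", {
  cfg <- acquisition_config(duration = 2, initial_cells_min = 5,
                            initial_cells_max = 8)
  arcs <- builtin_archetypes()
  recs <- list()
  truth <- character()
  for (a in c("control", "stabilizer", "disruptor")) {
    for (rep_i in 1:2) {
      cond <- paste0(a, "_r", rep_i)
      truth[cond] <- a
      recs[[cond]] <- simulate_trajectories(cfg, arcs[[a]],
                                            seed = 50 + rep_i,
                                            condition = cond)
    }
  }
  records <- do.call(rbind, recs)
  rep_out <- archetype_recovery_report(records, truth)
  expect_equal(rep_out$agreement, 1.0)
  expect_error(archetype_recovery_report(
    records[records$condition %in% c("control_r1", "control_r2"), ],
    truth), "2 archetypes")
  expect_error(archetype_recovery_report(
    records[records$condition %in% c("control_r1", "stabilizer_r1"), ],
    truth), "2 replicate")
})

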