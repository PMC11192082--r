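test_that("knn_index handles simple geometries deterministically", {
  # three collinear points: middle point's neighbor is the nearer endpoint
  coords <- cbind(c(0, 1, 5), 0)
  rownames(coords) <- c("a", "b", "c")
  nn <- knn_index(as_embedding(coords), k = 1)
  expect_equal(unname(nn$idx["b", 1]), 1L)  # "a" at dist 1 beats "c" at 4

  # unit square: each corner's 2 neighbors are the edge-adjacent corners
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  rownames(sq) <- c("p1", "p2", "p3", "p4")
  nn2 <- knn_index(as_embedding(sq), k = 2)
  expect_setequal(nn2$idx["p1", ], c(2L, 4L))
  expect_setequal(nn2$idx["p3", ], c(2L, 4L))

  expect_error(knn_index(as_embedding(sq), k = 4), "smaller")
})

test_that("knn_index matches the exhaustive pairwise-distance oracle", {
  set.seed(11)
  coords <- matrix(rnorm(200 * 5), 200, 5)
  rownames(coords) <- sprintf("c%05d", 1:200)
  nn <- knn_index(as_embedding(coords), k = 25)
  expect_equal(unname(nn$idx), oracle_knn(coords, 25))
})

test_that("refine_labels fixes uniform labels and follows unanimous votes", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(20, 20)), sd = 1, seed = 4)
  uni <- structure(rep("only", 60), names = rownames(blobs$coords))
  ref <- refine_labels(blobs$coords, uni, k = 10)
  expect_equal(ref$label, unname(uni))

  # one mislabeled cell surrounded by the other blob gets relabeled,
  # unanimously
  lab <- blobs$labels
  lab[5] <- "blob2"   # cell 5 sits deep in blob1 territory
  ref2 <- refine_labels(blobs$coords, lab, k = 10)
  expect_equal(ref2$label[5], "blob1")
  expect_equal(ref2$confidence[5], 1.0)
  expect_equal(ref2$refined_from[5], "blob2")

  expect_error(refine_labels(blobs$coords, replace(lab, 2, NA), k = 10),
               "allow_missing")
  ref3 <- refine_labels(blobs$coords, replace(lab, 2, NA), k = 10,
                        allow_missing = TRUE)
  expect_true(is.na(ref3$label[2]))
})

test_that("refinement matches the majority-vote oracle and reduces planted label noise", {
  blobs <- make_blobs(34, rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                      sd = 1, seed = 8)
  truth <- blobs$labels
  set.seed(9)
  noisy <- truth
  flip <- sample(length(truth), round(0.08 * length(truth)))
  noisy[flip] <- vapply(flip, function(i) {
    sample(setdiff(unique(truth), truth[i]), 1)
  }, character(1))

  ref <- refine_labels(blobs$coords, noisy, k = 25)
  expect_equal(ref$label,
               unname(oracle_refine(blobs$coords, noisy, 25)))
  expect_lt(mean(ref$label != truth), mean(noisy != truth))
})

test_that("refinement is idempotent once neighborhoods are homogeneous", {
  blobs <- make_blobs(40, rbind(c(0, 0), c(25, 0)), sd = 1, seed = 2)
  set.seed(3)
  noisy <- blobs$labels
  noisy[sample(80, 6)] <- sample(unique(blobs$labels), 6, replace = TRUE)
  once <- refine_labels(blobs$coords, noisy, k = 15)
  twice <- refine_labels(blobs$coords, once, k = 15)
  expect_equal(twice$label, once$label)
})

test_that("neighbor_purity is exact on separated clusters and matches the brute-force oracle", {
  blobs <- make_blobs(50, rbind(c(0, 0), c(100, 0)), sd = 1, seed = 6)
  pm <- neighbor_purity(blobs$coords, blobs$labels, k = 30)
  expect_equal(unclass(pm), diag(2) * 100,
               ignore_attr = TRUE)

  set.seed(12)
  coords <- matrix(rnorm(300 * 4), 300, 4)
  rownames(coords) <- sprintf("c%05d", 1:300)
  labels <- structure(sample(c("A", "B", "C"), 300, replace = TRUE),
                      names = rownames(coords))
  pm2 <- neighbor_purity(coords, labels, k = 40)
  expect_equal(unclass(pm2), oracle_purity(coords, labels, 40),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(rowSums(unclass(pm2))), rep(100, 3), tolerance = 1e-6)
})

test_that("neighbor_purity is invariant to rigid motion and label permutation", {
  set.seed(13)
  coords <- matrix(rnorm(150 * 3), 150, 3)
  rownames(coords) <- sprintf("c%05d", 1:150)
  labels <- structure(sample(c("A", "B"), 150, replace = TRUE),
                      names = rownames(coords))
  pm <- neighbor_purity(coords, labels, k = 20)

  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved <- sweep(coords %*% rot, 2, c(5, -3, 2), "+")
  rownames(moved) <- rownames(coords)
  pm_m <- neighbor_purity(moved, labels, k = 20)
  expect_equal(unclass(pm_m), unclass(pm), tolerance = 1e-9)

  relab <- structure(c(A = "Z", B = "Y")[labels], names = names(labels))
  pm_r <- neighbor_purity(coords, relab, k = 20)
  expect_equal(unclass(pm_r)[c("Z", "Y"), c("Z", "Y")],
               unclass(pm)[c("A", "B"), c("A", "B")], ignore_attr = TRUE)

  # declared-but-empty label class is dropped with a warning
  f <- factor(labels, levels = c("A", "B", "GHOST"))
  names(f) <- names(labels)
  expect_warning(neighbor_purity(coords, f, k = 20), "GHOST")
})

test_that("batch_mixing_report separates good from corrupted integrations", {
  cfg <- sim_config(n_genes = 200, n_cells_per_batch = c(120, 120),
                    n_populations = 2, seed = 21)
  sim <- simulate_multibatch_counts(cfg)
  rep_good <- batch_mixing_report(sim$embedding, sim$truth$batch,
                                  sim$truth$cell_labels, k = 50)
  # ideal embedding, balanced batches: batch diagonal near batch proportions
  expect_equal(unname(diag(unclass(rep_good$batch_purity))), c(50, 50),
               tolerance = 7)

  # translate one batch far away: batch diagonal ~ 100
  coords <- sim$embedding$coords
  coords[sim$truth$batch == "batch2", ] <-
    coords[sim$truth$batch == "batch2", ] + 1000
  rep_bad <- batch_mixing_report(as_embedding(coords), sim$truth$batch,
                                 sim$truth$cell_labels, k = 50)
  expect_equal(unname(diag(unclass(rep_bad$batch_purity))), c(100, 100),
               tolerance = 1e-9)

  # state retention: ideal >= batch-corrupted, same data
  corr <- corrupt_embedding(sim$embedding, sim$truth$batch, shift = 6,
                            seed = 3)
  rep_corr <- batch_mixing_report(corr, sim$truth$batch,
                                  sim$truth$cell_labels, k = 50)
  expect_gte(rep_good$state_retention_score, rep_corr$state_retention_score)
})
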