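test_that("row_wilcoxon agrees with stats::wilcox.test including ties", {
  set.seed(17)
  x <- rbind(matrix(rnorm(5 * 40), 5, 40),
             matrix(rpois(5 * 40, 2), 5, 40))   # tied integer rows
  a <- 1:18; b <- 19:40
  p_pkg <- row_wilcoxon(x, a, b)
  p_ref <- apply(x, 1, function(v) {
    stats::wilcox.test(v[a], v[b], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(unname(p_pkg), unname(p_ref), tolerance = 1e-12)
  # constant row: no information, p = 1
  expect_equal(row_wilcoxon(matrix(1, 1, 40), a, b), 1)
})

test_that("find_markers recovers planted markers and filters nulls", {
  cfg <- sim_config(n_genes = 400, n_cells_per_batch = c(150, 150),
                    n_populations = 2,
                    marker_spec = data.frame(population = "pop1",
                                             n_markers = 8, log2fc = 2),
                    seed = 23)
  sim <- simulate_multibatch_counts(cfg)
  lab <- sim$truth$cell_labels
  mk <- find_markers(sim$counts, lab, "pop1")
  planted <- sim$truth$marker_truth$gene
  expect_true(all(planted %in% mk$gene))
  expect_true(all(mk$p_adj >= mk$p_raw))
  expect_true(all(mk$p_adj < 1e-5 & mk$log2_fold_change > 0.5))

  # permuted labels: nothing should pass the Bonferroni + fold-change filter
  set.seed(5)
  perm <- structure(sample(lab), names = names(lab))
  expect_equal(nrow(find_markers(sim$counts, perm, "pop1")), 0)

  expect_error(find_markers(sim$counts, lab, "pop1",
                            reference = character(0)), "at least 3 cells")

  # full table mode flags rather than drops
  full <- find_markers(sim$counts, lab, "pop1", filter = FALSE)
  expect_equal(nrow(full), 400)
  expect_equal(sum(full$significant), nrow(mk))
})

test_that("fisher_overlap_test equals the hypergeometric tail sum", {
  # zero intersection: P(X >= 0) = 1
  expect_equal(fisher_overlap_test(0, 5, 5, 20), 1)
  # (3, 5, 5, 20): direct summation of the pmf over {3, 4, 5}
  manual <- sum(dhyper(3:5, 5, 15, 5))
  expect_equal(fisher_overlap_test(3, 5, 5, 20), manual, tolerance = 1e-12)
  # maximal overlap: single extreme point
  expect_equal(fisher_overlap_test(4, 4, 10, 30), dhyper(4, 4, 26, 10),
               tolerance = 1e-12)
  expect_error(fisher_overlap_test(6, 5, 5, 20), "n_intersect")
  expect_error(fisher_overlap_test(0, 25, 5, 20), "universe")
  # forced overlap: n_a + n_b > universe makes small intersections impossible
  expect_error(fisher_overlap_test(0, 15, 10, 20), "forced")
})

test_that("jaccard_match computes overlap coefficients over the shared universe", {
  uni <- sprintf("G%03d", 1:2000)
  mk_a <- data.frame(population = "P1", gene = uni[1:30])
  mk_b <- data.frame(population = "Q1", gene = uni[11:50])
  ov <- jaccard_match(mk_a, mk_b, uni, uni)
  expect_equal(ov$jaccard["P1", "Q1"], 20 / 50)       # |A|=30 |B|=40 |I|=20
  expect_equal(ov$fisher_p["P1", "Q1"],
               sum(dhyper(20:30, 30, 1970, 40)), tolerance = 1e-12)

  ident <- jaccard_match(mk_a, mk_a, uni, uni)
  expect_equal(ident$jaccard[1, 1], 1.0)
  disj <- jaccard_match(mk_a,
                        data.frame(population = "Q1", gene = uni[100:120]),
                        uni, uni)
  expect_equal(disj$jaccard[1, 1], 0.0)
  expect_error(jaccard_match(mk_a, mk_b, uni[1:5], uni[6:10]),
               "empty shared universe")
})

test_that("ortholog mapping matches case-normalized or explicit tables and is symmetric", {
  mouse_uni <- c("Comp", "Sfrp2", "Acta2", "Cthrc1", "Postn", "Meox1",
                 "Cilp", "Fbln1")
  human_uni <- toupper(mouse_uni)
  mk_m <- data.frame(population = "MFC", gene = c("Comp", "Sfrp2", "Cilp"))
  mk_h <- data.frame(population = "AS-4", gene = c("COMP", "SFRP2", "FBLN1"))
  ov <- jaccard_match(mk_m, mk_h, mouse_uni, human_uni)
  expect_equal(ov$pairs$n_intersect, 2)
  expect_equal(ov$jaccard[1, 1], 2 / 4)

  # bijective explicit map: swapping datasets transposes the matrices
  map <- data.frame(from = mouse_uni, to = human_uni)
  ov1 <- jaccard_match(mk_m, mk_h, mouse_uni, human_uni, ortholog_map = map)
  inv <- data.frame(from = human_uni, to = mouse_uni)
  ov2 <- jaccard_match(mk_h, mk_m, human_uni, mouse_uni, ortholog_map = inv)
  expect_equal(unname(ov1$jaccard), unname(t(ov2$jaccard)))
  expect_equal(unname(ov1$fisher_p), unname(t(ov2$fisher_p)))
})

test_that("module_score is centered, recovers planted shifts, and is stable", {
  counts <- null_counts(2000, 200, seed = 31)
  # set = every gene: controls come from the same pool, score ~ 0
  ms_all <- module_score(counts, rownames(counts), seed = 1)
  expect_lt(max(abs(ms_all)), 0.05)

  # shift a small gene set by +delta (log scale) in half the cells; the
  # set is a small fraction of the pool so control contamination by set
  # genes is negligible and the planted shift is recovered
  delta <- 1.0
  norm <- as.matrix(normalize_log(counts))
  set <- rownames(counts)[sample(2000, 30)]
  half <- colnames(counts)[1:100]
  norm[set, half] <- norm[set, half] + delta
  ms <- module_score(norm, set, seed = 2, normalized = TRUE)
  gap <- mean(ms[half]) - mean(ms[setdiff(colnames(counts), half)])
  expect_equal(gap, delta, tolerance = 0.1)

  # two control-sampling seeds agree in rank order
  ms_a <- module_score(norm, set, seed = 3, normalized = TRUE)
  ms_b <- module_score(norm, set, seed = 4, normalized = TRUE)
  expect_gte(cor(ms_a, ms_b, method = "spearman"), 0.95)

  expect_error(module_score(counts, character(0)), "empty")
  expect_error(module_score(counts, c("nope1", "nope2")), "none")
})

test_that("regulon_activity normalizes against the permutation null", {
  counts <- null_counts(500, 120, seed = 41)
  set.seed(42)
  regs <- data.frame(tf = "tf1",
                     target = rownames(counts)[sample(500, 10)],
                     weight = runif(10, 0.5, 1.5))
  # all-zero weights: raw 0, sd 0 -> normalized 0 with warning
  regs0 <- transform(regs, weight = 0)
  expect_warning(act0 <- regulon_activity(counts, regs0, times = 20,
                                          seed = 1), "zero permutation sd")
  expect_true(all(act0 == 0))

  # regulon under minsize is dropped with a warning
  small <- data.frame(tf = "tiny", target = rownames(counts)[1:4],
                      weight = 1)
  expect_warning(
    expect_error(regulon_activity(counts, small, minsize = 5), "minsize"),
    "tiny")
  both <- rbind(regs, small)
  expect_warning(act <- regulon_activity(counts, both, times = 50, seed = 2),
                 "tiny")
  expect_equal(rownames(act), "tf1")

  # planted active regulon scores highest in its population
  cfg <- sim_config(n_genes = 400, n_cells_per_batch = c(100, 100),
                    n_populations = 2,
                    marker_spec = data.frame(population = "pop1",
                                             n_markers = 8, log2fc = 1.5),
                    seed = 43)
  sim <- simulate_multibatch_counts(cfg)
  planted <- data.frame(tf = "planted",
                        target = sim$truth$marker_truth$gene, weight = 1)
  act_p <- regulon_activity(sim$counts, planted, times = 100, seed = 3)
  byp <- summarize_activity(act_p, sim$truth$cell_labels)
  expect_gt(byp["planted", "pop1"], byp["planted", "pop2"])
})

test_that("fold_change_correlation joins on significant genes by value", {
  set.seed(51)
  genes <- sprintf("g%03d", 1:200)
  lfc_a <- rnorm(200, 0, 1)
  tab_a <- data.frame(gene = genes, log2_fold_change = lfc_a,
                      significant = abs(lfc_a) > 1)
  expect_equal(fold_change_correlation(tab_a, tab_a), 1.0)
  tab_neg <- transform(tab_a, log2_fold_change = -log2_fold_change)
  expect_equal(fold_change_correlation(tab_a, tab_neg), -1.0)

  # planted correlation 0.8 between the two tables' effect sizes
  lfc_b <- 0.8 * lfc_a + sqrt(1 - 0.8^2) * rnorm(200)
  tab_b <- data.frame(gene = genes, log2_fold_change = lfc_b,
                      significant = abs(lfc_b) > 1)
  expect_equal(fold_change_correlation(tab_a, tab_b), 0.8, tolerance = 0.1)

  expect_error(fold_change_correlation(tab_a[1:2, ], tab_a[1:2, ]),
               "fewer than 3")
})
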