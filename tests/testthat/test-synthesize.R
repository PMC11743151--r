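test_that("MTI fixture has the requested shape and passes the filter", {
  fix <- generate_mti_fixture(n_mirnas = 3, targets_per_mirna = 5,
                              n_genes = 100, seed = 4)
  expect_equal(nrow(fix), 15)
  expect_identical(fix, generate_mti_fixture(n_mirnas = 3,
                                             targets_per_mirna = 5,
                                             n_genes = 100, seed = 4))
  idx <- build_target_index(filter_mtis(fix))
  expect_length(idx, 3)
  expect_true(all(vapply(idx, anyDuplicated, 0L) == 0))

  # saturated catalogue: every gene is a target of every miRNA
  sat <- build_target_index(filter_mtis(
    generate_mti_fixture(n_mirnas = 2, targets_per_mirna = 20, n_genes = 20,
                         seed = 1)
  ))
  expect_equal(
    target_membership(sprintf("G%04d", 1:20), sat[[1]]),
    rep(1L, 20)
  )
})

test_that("count simulation is reproducible and exchangeable at delta 0", {
  idx <- make_index(list("hsa-miR-x-5p" = sprintf("G%04d", 1:20)))
  s1 <- generate_single_cell_dataset(idx, planted_mirnas = names(idx),
                                     n_genes = 100, n_cells = 50, seed = 3)
  s2 <- generate_single_cell_dataset(idx, planted_mirnas = names(idx),
                                     n_genes = 100, n_cells = 50, seed = 3)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_true(all(grepl("_(ctrl|case)$", colnames(s1$counts$counts))))

  s0 <- generate_single_cell_dataset(idx, planted_mirnas = names(idx),
                                     n_genes = 200, n_cells = 200,
                                     delta = 0, seed = 5)
  m <- s0$counts$counts
  pl <- colnames(m) %in% s0$truth$planted_barcodes
  ks <- suppressWarnings(stats::ks.test(rowMeans(m[, pl]),
                                        rowMeans(m[, !pl])))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted signal is recovered across seeds", {
  # delta = 2, 20 targets, 200 planted of 400 cells; the planted miRNA's
  # mean -log10 activity p must exceed background by >= 1 order of magnitude
  gaps <- vapply(1:20, function(i) {
    pd <- planted_dataset(seed = 700 + i)
    a <- compute_activity(
      preprocess_counts(pd$sim$counts, sample_n = Inf)$zscores,
      pd$index, cpus = 1
    )
    pl <- colnames(a$pvalues) %in% pd$sim$truth$planted_barcodes
    mir <- pd$sim$truth$planted_mirnas
    mean(-log10(a$pvalues[mir, pl])) - mean(-log10(a$pvalues[mir, !pl]))
  }, 0)
  expect_true(all(gaps >= 1))
})

test_that("universal activity across disjoint target subsets is detected", {
  # one miRNA with 200 targets; each tenth of the cells represses a
  # different 20-target subset, so the miRNA is active everywhere while no
  # single target is repressed in more than 10% of cells
  n_sub <- 10
  per_sub <- 20
  idx <- build_target_index(filter_mtis(generate_mti_fixture(
    n_mirnas = 1, targets_per_mirna = n_sub * per_sub, n_genes = 2000,
    seed = 11
  )))
  tg <- idx[[1]]
  cells <- split(1:200, rep(seq_len(n_sub), length.out = 200))
  plant <- lapply(seq_len(n_sub), function(i) {
    list(targets = tg[((i - 1) * per_sub + 1):(i * per_sub)],
         cells = cells[[i]])
  })
  sim <- generate_single_cell_dataset(idx, n_genes = 2000, n_cells = 200,
                                      populations = NULL, plant = plant,
                                      delta = 3, seed = 12)
  a <- compute_activity(
    preprocess_counts(sim$counts, sample_n = Inf)$zscores, idx, cpus = 1
  )
  expect_gte(mean(a$pvalues < 0.01), 0.95)
})

test_that("spatial simulation plants activity inside the region", {
  idx <- build_target_index(filter_mtis(generate_mti_fixture(
    n_mirnas = 2, targets_per_mirna = 20, n_genes = 400, seed = 2
  )))
  sim <- generate_spatial_dataset(idx, planted_mirnas = names(idx)[1],
                                  grid = c(20, 20), n_genes = 400,
                                  delta = 3, seed = 6)
  expect_equal(ncol(sim$counts$counts), 400)
  expect_equal(nrow(sim$counts$coords), 400)
  a <- compute_activity(
    preprocess_counts(sim$counts, sample_n = Inf)$zscores, idx, cpus = 1
  )
  rep <- spatial_scores(a)
  planted_score <- rep$score[rep$mirna == names(idx)[1]]
  expect_gt(planted_score, 0.35) # left half of the grid
  expect_lt(planted_score, 0.65)
  expect_lt(rep$score[rep$mirna == names(idx)[2]], 0.05)

  # empty region: the "planted" miRNA behaves as a null
  sim0 <- generate_spatial_dataset(idx, planted_mirnas = names(idx)[1],
                                   grid = c(8, 8), n_genes = 200,
                                   region = function(x, y) FALSE,
                                   delta = 3, seed = 6)
  expect_length(sim0$truth$planted_barcodes, 0)

  sim1 <- generate_spatial_dataset(idx, planted_mirnas = names(idx)[1],
                                   grid = c(8, 8), n_genes = 200,
                                   region = function(x, y) x == 1 & y == 1,
                                   delta = 3, seed = 6)
  expect_equal(sim1$truth$planted_barcodes, "spot_1_1")
})

test_that("binomial downsampling thins counts as expected", {
  x <- make_counts(matrix(rpois(2000, 20), 50))
  expect_identical(downsample_counts(x, 1), x)

  frac <- 0.3
  d1 <- downsample_counts(x, frac, seed = 9)
  d2 <- downsample_counts(x, frac, seed = 9)
  expect_identical(d1$counts, d2$counts)
  expect_true(all(d1$counts <= x$counts))
  tot <- sum(x$counts)
  sd_tot <- sqrt(tot * frac * (1 - frac))
  expect_lt(abs(sum(d1$counts) - frac * tot), 3 * sd_tot)
})
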