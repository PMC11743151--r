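activity_from_matrix <- function(pv, populations = NULL, coords = NULL) {
  structure(list(pvalues = pv, species = "homo_sapiens",
                 coords = coords, populations = populations),
            class = "mir_activity")
}

test_that("spatial scores count strictly-significant spots", {
  pv <- rbind(
    mirA = c(1e-6, 1e-7, 0.5, 1e-4),
    mirB = c(1, 1, 1, 1),
    mirC = c(1e-5, 1e-5, 1e-5, 1e-5) # boundary: not counted
  )
  colnames(pv) <- paste0("s", 1:4)
  rep <- spatial_scores(activity_from_matrix(pv))
  expect_equal(rep$score[rep$mirna == "mirA"], 0.5)
  expect_equal(rep$score[rep$mirna == "mirB"], 0)
  expect_equal(rep$score[rep$mirna == "mirC"], 0)
  expect_equal(rep$rank, 1:3)
  expect_equal(rep$mirna[1], "mirA") # sorted descending by score

  # spot order must not matter
  perm <- pv[, c(3, 1, 4, 2)]
  expect_equal(spatial_scores(activity_from_matrix(perm)), rep)
})

test_that("total scores are BH-corrected average p-values", {
  one <- activity_from_matrix(rbind(m1 = c(0.2, 0.4)))
  expect_equal(total_scores(one)$score, 0.3) # BH with m = 1 is identity

  two <- activity_from_matrix(rbind(m1 = c(0.01, 0.01), m2 = c(0.04, 0.04)))
  rep <- total_scores(two)
  expect_equal(rep$score, c(0.02, 0.04)) # step-up by hand
  expect_true(all(rep$score >= rep$mean_p))

  perm <- activity_from_matrix(rbind(m1 = c(0.01, 0.01), m2 = c(0.04, 0.04))[, 2:1])
  expect_equal(total_scores(perm), rep)
})

test_that("rank-sum p-value matches the normal approximation and wilcox.test", {
  p <- wrs_pvalue(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(p, 2 * pnorm(-4.5 / sqrt(5.25)), tolerance = 1e-12)
  expect_equal(signif(p, 3), 0.0495)

  expect_equal(wrs_pvalue(rep(2, 5), rep(2, 7)), 1) # degenerate ties

  set.seed(4)
  for (rep_i in 1:10) {
    x <- sample(1:8, 12, replace = TRUE) # heavy ties
    y <- sample(2:9, 15, replace = TRUE)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    )
    expect_equal(wrs_pvalue(x, y), ref, tolerance = 1e-10)
  }
})

test_that("comparative scores rank differential activity with BH control", {
  pv <- rbind(
    diffed = c(rep(1e-6, 3), rep(0.9, 3)),
    flat = rep(0.5, 6)
  )
  colnames(pv) <- paste0("c", 1:6)
  pops <- stats::setNames(rep(c("case", "ctrl"), each = 3), colnames(pv))
  rep <- suppressWarnings(
    comparative_scores(activity_from_matrix(pv, populations = pops))
  )
  expect_equal(rep$mirna[1], "diffed")
  expect_equal(rep$score[rep$mirna == "flat"], 1)
  expect_equal(attr(rep, "populations"), c("case", "ctrl"))

  # invariant under monotone transforms of the p-values
  rep2 <- suppressWarnings(
    comparative_scores(activity_from_matrix(-log10(pv), populations = pops))
  )
  expect_equal(rep2$wrs_p, rep[match(rep2$mirna, rep$mirna), ]$wrs_p)

  # cell order must not matter
  perm <- pv[, c(4, 2, 6, 1, 3, 5)]
  rep3 <- suppressWarnings(
    comparative_scores(activity_from_matrix(perm, populations = pops[colnames(perm)]))
  )
  expect_equal(rep3$wrs_p, rep$wrs_p)

  one_pop <- stats::setNames(rep("a", 6), colnames(pv))
  expect_error(
    comparative_scores(activity_from_matrix(pv, populations = one_pop)),
    "exactly two"
  )
})

test_that("tiering promotes consistently high differential activity", {
  m <- 100
  lvl <- seq_len(m) / 10 # known quantiles: 0.97 -> ~9.73, 0.9 -> ~9.01
  report <- tibble::tibble(
    mirna = sprintf("mir%03d", seq_len(m)),
    wrs_p = rep(0.5, m),
    score = rep(0.5, m),
    mean_neglog10_1 = lvl,
    mean_neglog10_2 = rev(lvl),
    rank = seq_len(m),
    tier = "none",
    mode = "comparative"
  )
  report$score[99] <- 1e-12  # level at 0.99 quantile -> tier 1
  report$score[95] <- 1e-12  # level at 0.95 quantile -> tier 2
  report$score[50] <- 1e-3   # significant-ish but not below 1e-8 -> tier 3
  out <- assign_comparative_tiers(report)
  expect_equal(out$tier[out$mirna == "mir099"], "1")
  expect_equal(out$tier[out$mirna == "mir095"], "2")
  expect_equal(out$tier[out$mirna == "mir050"], "3")
  expect_equal(out$rank, seq_len(m))
  expect_equal(out$tier, sort(out$tier)) # tier blocks in order
})

test_that("bonferroni and significance brackets follow the conventions", {
  expect_equal(bonferroni_pairwise(0.001, 100), 0.1)
  expect_equal(bonferroni_pairwise(0.5, 3), 1)
  expect_equal(bonferroni_pairwise(c(0.2, 0.9), 1), c(0.2, 0.9))

  expect_equal(
    significance_bracket(c(0.2, 0.03, 5e-3, 5e-4, 5e-5, 1)),
    c("ns", "*", "**", "***", "****", "ns")
  )
})
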