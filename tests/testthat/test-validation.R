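test_that("precursor copies are summed into the mature id", {
  m <- rbind("hsa-mir-Y-1" = c(5, 0), "hsa-mir-Y-2" = c(7, 1),
             "hsa-mir-21" = c(3, 3))
  out <- sum_precursor_expression(m)
  expect_equal(unname(out["hsa-mir-Y", ]), c(12, 1))
  expect_equal(unname(out["hsa-mir-21", ]), c(3, 3))

  plain <- rbind("hsa-miR-16-5p" = c(1, 2))
  expect_equal(sum_precursor_expression(plain), plain)

  zero <- rbind("hsa-mir-Z-1" = c(0, 0), "hsa-mir-Z-2" = c(0, 0),
                "hsa-mir-9" = c(1, 1))
  expect_equal(rownames(sum_precursor_expression(zero)), "hsa-mir-9")

  # a numeric miRNA number is not a copy suffix
  named <- rbind("hsa-mir-3609" = c(4, 4))
  expect_equal(rownames(sum_precursor_expression(named)), "hsa-mir-3609")

  tib <- tibble::tibble(mirna = c("hsa-mir-7-1", "hsa-mir-7-2"),
                        s1 = c(2, 3))
  out_t <- sum_precursor_expression(tib)
  expect_equal(out_t$mirna, "hsa-mir-7")
  expect_equal(out_t$s1, 5)
})

test_that("activity classification uses the two-threshold rule", {
  cls <- classify_activity(c(a = 0.04, b = 0.07, c = 0.2))
  expect_equal(cls$label, c("active", "neither", "non_active"))
  expect_error(classify_activity(c(a = 0)), "scores > 0")
})

test_that("strand collapsing prefers active calls", {
  cls <- tibble::tibble(
    mirna = c("miR-A-5p", "miR-A-3p", "miR-B-5p", "miR-B-3p",
              "miR-C-5p", "miR-C-3p"),
    label = c("active", "non_active", "non_active", "active",
              "neither", "neither")
  )
  out <- collapse_strands(cls)
  expect_equal(out$label[out$mirna == "miR-A"], "active")
  expect_equal(out$label[out$mirna == "miR-B"], "active") # not non-active
  expect_equal(out$label[out$mirna == "miR-C"], "neither")
})

test_that("expression/activity agreement is an mHG test on the sorted list", {
  expr <- c(m1 = 10, m2 = 8, m3 = 5, m4 = 1)
  cls <- tibble::tibble(mirna = names(expr),
                        label = c("active", "active", "non_active",
                                  "non_active"))
  top <- expression_activity_agreement(expr, cls, "top_active")
  # active ids occupy the top half: statistic P(X >= 2 | HG(4, 2, 2)) = 1/6
  expect_equal(top$statistic, 1 / 6)
  expect_equal(top$pvalue, mhg_pvalue_bruteforce(c(1, 1, 0, 0)))

  bottom <- expression_activity_agreement(expr, cls, "bottom_nonactive")
  expect_equal(bottom$statistic, 1 / 6)

  all_active <- tibble::tibble(mirna = names(expr), label = "active")
  expect_equal(
    expression_activity_agreement(expr, all_active, "top_active")$pvalue, 1
  )
  expect_error(
    expression_activity_agreement(c(zz = 1), cls), "shared"
  )
})

test_that("agreement detects planted expression-activity coupling", {
  hits <- null_hits <- logical(20)
  for (i in 1:20) {
    set.seed(400 + i)
    m <- 80
    ids <- sprintf("mir%03d", seq_len(m))
    active <- seq_len(25) # the first 25 are truly active
    labels <- ifelse(seq_len(m) %in% active, "active", "non_active")
    # coupled: active miRNAs are expressed higher on average
    expr <- stats::setNames(
      rlnorm(m, meanlog = ifelse(labels == "active", 2, 0)), ids
    )
    cls <- tibble::tibble(mirna = ids, label = labels)
    hits[i] <-
      expression_activity_agreement(expr, cls, "top_active")$pvalue < 0.05
    # null: expression independent of the labels
    expr0 <- stats::setNames(rlnorm(m, meanlog = 1), ids)
    null_hits[i] <-
      expression_activity_agreement(expr0, cls, "top_active")$pvalue < 0.05
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(!null_hits), 0.9)
})

test_that("target-expression comparison mirrors the rank-sum conventions", {
  m <- matrix(5, nrow = 2, ncol = 6,
              dimnames = list(c("T1", "T2"), paste0("c", 1:6)))
  pops <- stats::setNames(rep(c("a", "b"), each = 3), colnames(m))
  x <- mir_counts(m, populations = pops)
  expect_equal(compare_target_expression(x, c("T1", "T2")), 1)

  m2 <- rbind(T1 = c(1, 2, 3, 10, 11, 12), T2 = c(2, 3, 4, 11, 12, 13))
  colnames(m2) <- paste0("c", 1:6)
  x2 <- mir_counts(m2, populations = pops)
  expect_equal(signif(compare_target_expression(x2, c("T1", "T2")), 3),
               0.0495)
  expect_error(compare_target_expression(x2, "ZZ"), "no target genes")
})

test_that("planted activity is corroborated at the expression level", {
  pd <- planted_dataset(seed = 55, n_mirnas = 4, n_cells = 300)
  norm <- preprocess_counts(pd$sim$counts, sample_n = Inf)$counts
  p <- compare_target_expression(
    norm, pd$index[[pd$sim$truth$planted_mirnas]]
  )
  expect_lt(p, 0.01)
})
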