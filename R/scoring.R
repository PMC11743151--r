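#' Spatial activity scores
#'
#' The score of a miRNA on spot data is the fraction of spots whose activity
#' p-value falls strictly below `threshold`; miRNAs are ranked by descending
#' score so the most broadly active come first.
#'
#' @param a A `mir_activity` object.
#' @param threshold Activity p-value below which a spot counts as active.
#' @return A ranked-report tibble with columns `mirna`, `score`, `rank`,
#'   `tier`, `mode`.
#' @export
spatial_scores <- function(a, threshold = 1e-5) {
  stopifnot(inherits(a, "mir_activity"), nrow(a$pvalues) > 0)
  score <- rowMeans(a$pvalues < threshold)
  tibble::tibble(mirna = rownames(a$pvalues), score = unname(score)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(), tier = "none", mode = "spatial")
}

#' Total activity scores
#'
#' Averages activity p-values across all cells per miRNA and applies
#' Benjamini-Hochberg correction across miRNAs to the averages; the corrected
#' value is the activity score and miRNAs are ranked ascending by it.
#'
#' @param a A `mir_activity` object.
#' @return Ranked-report tibble with `mirna`, `mean_p`, `score`, `rank`,
#'   `tier`, `mode`.
#' @export
total_scores <- function(a) {
  stopifnot(inherits(a, "mir_activity"), nrow(a$pvalues) > 0)
  mean_p <- rowMeans(a$pvalues)
  tibble::tibble(
    mirna = rownames(a$pvalues),
    mean_p = unname(mean_p),
    score = p.adjust(mean_p, method = "BH")
  ) |>
    dplyr::arrange(.data$score, .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(), tier = "none", mode = "total")
}

#' Two-sided Wilcoxon rank-sum p-value (normal approximation)
#'
#' Midrank-based large-sample test with tie correction and no continuity
#' correction. The degenerate case where every pooled value is identical has
#' zero rank variance and returns 1 by convention.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
wrs_pvalue <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  n <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Comparative activity scores between two populations
#'
#' For each miRNA, compares the activity p-values of the two cell populations
#' by a two-sided Wilcoxon rank-sum test; the BH-corrected test p-value is
#' the activity score. Comparisons are meaningful for populations of at least
#' ~100 cells; smaller groups trigger a warning. Per-population mean
#' activity levels (mean of -log10 p across cells) are reported alongside for
#' the tiering rule.
#'
#' @param a A `mir_activity` object.
#' @param populations Optional labels per sample (default: those embedded in
#'   `a`); exactly two distinct values are required.
#' @return Ranked-report tibble with `mirna`, `wrs_p`, `score` and the two
#'   `mean_neglog10_*` level columns, sorted ascending by score. The
#'   population names are attached as the `"populations"` attribute.
#' @export
comparative_scores <- function(a, populations = NULL) {
  stopifnot(inherits(a, "mir_activity"))
  populations <- populations %||% a$populations
  if (is.null(populations)) {
    stop("comparative mode needs population labels", call. = FALSE)
  }
  populations <- populations[colnames(a$pvalues)]
  pops <- sort(unique(populations))
  if (length(pops) != 2) {
    stop("comparative mode requires exactly two populations, got ",
         length(pops), call. = FALSE)
  }
  in1 <- populations == pops[1]
  if (min(sum(in1), sum(!in1)) < 100) {
    warning("populations below 100 cells; comparative scores are unstable",
            call. = FALSE)
  }
  wrs <- apply(a$pvalues, 1, function(p) wrs_pvalue(p[in1], p[!in1]))
  lvl1 <- rowMeans(-log10(a$pvalues[, in1, drop = FALSE]))
  lvl2 <- rowMeans(-log10(a$pvalues[, !in1, drop = FALSE]))
  out <- tibble::tibble(
    mirna = rownames(a$pvalues),
    wrs_p = unname(wrs),
    score = unname(p.adjust(wrs, method = "BH")),
    mean_neglog10_1 = unname(lvl1),
    mean_neglog10_2 = unname(lvl2)
  ) |>
    dplyr::arrange(.data$score, .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(), tier = "none",
                  mode = "comparative")
  attr(out, "populations") <- pops
  out
}

#' Tier the comparative ranking by consistency of activity
#'
#' Highlights miRNAs that are not only differentially active but show
#' consistently high activity in at least one population. Tier 1: mean
#' activity level at or above the 0.97 quantile (across miRNAs) in at least
#' one population *and* activity score below `score_threshold`; tier 2: the
#' same with the 0.9 quantile; tier 3: everything else, sorted by score.
#' Activity level is measured as the per-population mean of -log10 p, so
#' "high activity" means small activity p-values; quantiles use the standard
#' empirical estimator with linear interpolation.
#'
#' @param report Output of [comparative_scores()].
#' @param quantiles Quantile cut-offs for tiers 1 and 2.
#' @param score_threshold Activity-score ceiling for tiers 1 and 2.
#' @return The report re-ranked: tier 1 rows first, then tier 2, then tier 3,
#'   each sorted ascending by score.
#' @export
assign_comparative_tiers <- function(report, quantiles = c(0.97, 0.9),
                                     score_threshold = 1e-8) {
  stopifnot(all(c("score", "mean_neglog10_1", "mean_neglog10_2") %in%
                  names(report)))
  lvl <- cbind(report$mean_neglog10_1, report$mean_neglog10_2)
  q1 <- apply(lvl, 2, quantile, probs = quantiles[1], names = FALSE)
  q2 <- apply(lvl, 2, quantile, probs = quantiles[2], names = FALSE)
  hi1 <- lvl[, 1] >= q1[1] | lvl[, 2] >= q1[2]
  hi2 <- lvl[, 1] >= q2[1] | lvl[, 2] >= q2[2]
  sig <- report$score < score_threshold
  new_tier <- dplyr::case_when(hi1 & sig ~ "1", hi2 & sig ~ "2", .default = "3")
  pops <- attr(report, "populations")
  out <- report |>
    dplyr::mutate(tier = new_tier) |>
    dplyr::arrange(.data$tier, .data$score, .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "populations") <- pops
  out
}

#' Bonferroni adjustment for a family of comparisons
#'
#' @param pvals Numeric vector of p-values.
#' @param n_comparisons Size of the family.
#' @return `pmin(1, pvals * n_comparisons)`.
#' @export
bonferroni_pairwise <- function(pvals, n_comparisons) {
  stopifnot(n_comparisons >= 1)
  pmin(1, pvals * n_comparisons)
}

#' Significance brackets for figures
#'
#' Maps p-values onto the conventional annotation: `ns` for p > 0.05, `*` for
#' (0.01, 0.05], `**` for (0.001, 0.01], `***` for (1e-4, 1e-3], `****` for
#' p <= 1e-4.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_bracket <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  dplyr::case_when(
    p > 0.05 ~ "ns",
    p > 0.01 ~ "*",
    p > 1e-3 ~ "**",
    p > 1e-4 ~ "***",
    .default = "****"
  )
}
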