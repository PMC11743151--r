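#' Sum precursor rows into mature miRNA expression
#'
#' Expression catalogues sometimes report the precursor copies of a miRNA
#' (ids ending in `-1`, `-2`, ...) rather than the mature form. Rows whose id
#' carries such a numeric copy suffix are summed into the base name; rows that
#' end up all-zero are removed. A trailing `-<digits>` group is treated as a
#' copy suffix only when stripping it leaves a name that does not end in the
#' bare family token (`mir`/`miR`/`let`), so ids like `hsa-mir-3609`, where
#' the digits are the miRNA number itself, are left untouched.
#'
#' @param expr Matrix (miRNA rows, sample columns, rownames = ids) or tibble
#'   whose first column `mirna` holds the ids and remaining columns are
#'   numeric.
#' @return Object of the same shape with precursors collapsed.
#' @export
sum_precursor_expression <- function(expr) {
  tib <- inherits(expr, "data.frame")
  if (tib) {
    stopifnot(names(expr)[1] == "mirna")
    m <- as.matrix(expr[-1])
    rownames(m) <- expr$mirna
  } else {
    m <- as.matrix(expr)
  }
  ids <- rownames(m)
  base <- sub("-[0-9]{1,2}$", "", ids)
  suffixed <- ids != base & !grepl("(^|-)(mir|miR|let)$", base)
  key <- ifelse(suffixed, base, ids)
  out <- rowsum(m, group = key, reorder = FALSE)
  out <- out[rowSums(out) > 0, , drop = FALSE]
  if (tib) {
    tibble::as_tibble(out, rownames = "mirna")
  } else {
    out
  }
}

#' Classify miRNAs as active / non-active / neither
#'
#' A miRNA is *active* when its activity value is below 0.05, *non-active*
#' above 0.1, and *neither* in between. The input can be per-sample activity
#' p-values or aggregated scores (e.g. mean activity p over all cells); the
#' thresholds are the same either way.
#'
#' @param scores Named numeric vector of activity values in `(0, 1]`.
#' @param active_lt,nonactive_gt Classification thresholds.
#' @return Tibble with columns `mirna` and `label`
#'   (`active`/`non_active`/`neither`).
#' @export
classify_activity <- function(scores, active_lt = 0.05, nonactive_gt = 0.1) {
  stopifnot(!is.null(names(scores)), all(scores > 0 & scores <= 1))
  tibble::tibble(
    mirna = names(scores),
    label = dplyr::case_when(
      scores < active_lt ~ "active",
      scores > nonactive_gt ~ "non_active",
      .default = "neither"
    )
  )
}

#' Collapse strand-specific activity calls onto strandless ids
#'
#' Expression catalogues often carry one row per miRNA with the strands
#' summed, while activity is called per mature strand (`-5p`/`-3p`). The
#' strandless miRNA is considered active if at least one strand is active; it
#' is non-active only if some strand is non-active *and* no strand is active
#' (a non-active call with an active sibling strand is excluded); otherwise
#' neither.
#'
#' @param classification Tibble from [classify_activity()] with ids carrying
#'   optional `-5p`/`-3p` suffixes.
#' @return Tibble with strandless `mirna` and collapsed `label`.
#' @export
collapse_strands <- function(classification) {
  classification |>
    dplyr::mutate(mirna = sub("-[35]p$", "", .data$mirna)) |>
    dplyr::summarise(
      label = dplyr::case_when(
        any(.data$label == "active") ~ "active",
        any(.data$label == "non_active") ~ "non_active",
        .default = "neither"
      ),
      .by = "mirna"
    )
}

#' Expression/activity agreement by the mHG test
#'
#' Tests whether miRNAs called active concentrate among the most expressed
#' miRNAs (`end = "top_active"`: sort by descending expression, mark active
#' ids) or whether non-active miRNAs concentrate among the least expressed
#' (`end = "bottom_nonactive"`: sort ascending, mark non-active ids). Only
#' miRNAs present in both inputs take part; expression ties are broken by id
#' for determinism.
#'
#' @param expression Named numeric vector of expression values (strandless
#'   ids).
#' @param classification Tibble with `mirna` and `label`, typically from
#'   [collapse_strands()].
#' @param end `"top_active"` or `"bottom_nonactive"`.
#' @return An `mhg_result` with the exact agreement p-value.
#' @export
expression_activity_agreement <- function(expression, classification,
                                          end = c("top_active",
                                                  "bottom_nonactive")) {
  end <- match.arg(end)
  stopifnot(!is.null(names(expression)))
  shared <- intersect(names(expression), classification$mirna)
  if (length(shared) < 2) {
    stop("fewer than two miRNAs shared between expression and activity",
         call. = FALSE)
  }
  expr <- expression[shared]
  ord <- if (end == "top_active") {
    order(-expr, names(expr), method = "radix")
  } else {
    order(expr, names(expr), method = "radix")
  }
  ranked <- names(expr)[ord]
  label <- if (end == "top_active") "active" else "non_active"
  flagged <- classification$mirna[classification$label == label]
  mhg_test(as.integer(ranked %in% flagged))
}

#' Compare target expression between two populations
#'
#' Direct expression-level counterpart of the comparative activity test: for
#' each cell, averages the normalised expression of the miRNA's target genes,
#' then compares the two populations of per-cell means by a two-sided
#' Wilcoxon rank-sum test. A differential-activity call is corroborated when
#' this test agrees.
#'
#' @param x A normalised [mir_counts()] object.
#' @param targets Character vector of target gene symbols.
#' @param populations Optional labels per sample (default: embedded labels);
#'   exactly two distinct values required.
#' @return Two-sided WRS p-value.
#' @export
compare_target_expression <- function(x, targets, populations = NULL) {
  stopifnot(inherits(x, "mir_counts"))
  populations <- populations %||% x$populations
  if (is.null(populations)) stop("population labels required", call. = FALSE)
  populations <- populations[colnames(x$counts)]
  pops <- sort(unique(populations))
  stopifnot(length(pops) == 2)
  rows <- toupper(rownames(x$counts)) %in% toupper(targets)
  if (!any(rows)) stop("no target genes present in the matrix", call. = FALSE)
  per_cell <- colMeans(x$counts[rows, , drop = FALSE])
  wrs_pvalue(per_cell[populations == pops[1]], per_cell[populations == pops[2]])
}
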