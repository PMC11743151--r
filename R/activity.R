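#' Rank genes for one sample by ascending z-score
#'
#' An active miRNA represses its targets, so they should sit at the *low* end
#' of the sample's standardised expression; the gene list is therefore sorted
#' smallest-z first. Ties are broken by ascending gene identifier so that the
#' ranking never depends on the storage order of the matrix.
#'
#' @param z A `mir_zscores` object.
#' @param sample Barcode (or column index) of the sample.
#' @return Character vector of gene identifiers, most repressed first.
#' @export
rank_genes_for_sample <- function(z, sample) {
  stopifnot(inherits(z, "mir_zscores"))
  col <- z$z[, sample]
  rownames(z$z)[order(col, rownames(z$z), method = "radix")]
}

#' Binary target-membership vector over a ranked gene list
#'
#' @param ranked Character vector of gene ids, most repressed first.
#' @param targets Character vector of target symbols (matched after
#'   uppercasing both sides).
#' @return Integer 0/1 vector aligned with `ranked`.
#' @export
target_membership <- function(ranked, targets) {
  as.integer(toupper(ranked) %in% toupper(targets))
}

#' Compute the miRNA-by-sample activity matrix
#'
#' For every (miRNA, cell/spot) pair, ranks the genes by ascending z-score,
#' marks the miRNA's targets in that ranking, and applies the exact mHG test;
#' the resulting p-value is the *activity p-value* of the pair. A miRNA with
#' no targets present in the matrix gets the constant row 1 exactly. Samples
#' are independent, so the computation is parallelised across them with a
#' deterministic merge: the result is identical for any worker count.
#'
#' @param z A `mir_zscores` object.
#' @param index A `target_index`.
#' @param mirnas Optional subset of miRNA ids to evaluate (default: all in
#'   the index); unknown ids raise an error listing the offenders.
#' @param cpus Number of worker processes (default: all available).
#' @return A `mir_activity` object: list with the `pvalues` matrix
#'   (miRNA rows, sample columns), `species`, and the sample metadata.
#' @export
compute_activity <- function(z, index, mirnas = NULL,
                             cpus = parallel::detectCores()) {
  stopifnot(inherits(z, "mir_zscores"), inherits(index, "target_index"))
  if (is.null(mirnas)) {
    mirnas <- names(index)
  } else {
    unknown <- setdiff(mirnas, names(index))
    if (length(unknown) > 0) {
      stop("miRNA id(s) not in the target index: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  genes_upper <- toupper(rownames(z$z))
  member <- vapply(index[mirnas], function(tg) genes_upper %in% tg,
                   logical(length(genes_upper)))
  member <- matrix(member, nrow = length(genes_upper),
                   dimnames = list(NULL, mirnas))

  one_sample <- function(s) {
    ord <- order(z$z[, s], rownames(z$z), method = "radix")
    activity_pvalues_cpp(member[ord, , drop = FALSE])
  }
  samples <- colnames(z$z)
  cpus <- max(1L, as.integer(cpus))
  cols <- if (cpus > 1L) {
    parallel::mclapply(samples, one_sample, mc.cores = cpus)
  } else {
    lapply(samples, one_sample)
  }
  pv <- do.call(cbind, cols)
  dimnames(pv) <- list(mirnas, samples)

  structure(
    list(pvalues = pv, species = attr(index, "species"),
         coords = z$coords, populations = z$populations),
    class = "mir_activity"
  )
}

#' @export
print.mir_activity <- function(x, ...) {
  cat("<mir_activity> ", nrow(x$pvalues), " miRNAs x ", ncol(x$pvalues),
      " samples", sep = "")
  if (!is.null(x$populations)) {
    cat(" (populations: ", paste(unique(x$populations), collapse = "/"), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.mir_activity <- function(x) dim(x$pvalues)

#' Tidy an activity matrix into long format
#'
#' @param x A `mir_activity` object.
#' @param ... Unused.
#' @return Tibble with columns `mirna`, `barcode`, `p.value`, `neglog10_p`,
#'   plus `population`, `x`, `y` when available.
#' @export
tidy.mir_activity <- function(x, ...) {
  out <- tibble::as_tibble(x$pvalues, rownames = "mirna") |>
    tidyr::pivot_longer(-"mirna", names_to = "barcode", values_to = "p.value") |>
    dplyr::mutate(neglog10_p = -log10(.data$p.value))
  if (!is.null(x$populations)) {
    out$population <- unname(x$populations[out$barcode])
  }
  if (!is.null(x$coords)) {
    out <- dplyr::left_join(out, x$coords, by = "barcode")
  }
  out
}

#' One-row summary of an activity matrix
#'
#' @param x A `mir_activity` object.
#' @param threshold Activity p-value below which a (miRNA, sample) pair is
#'   called active.
#' @param ... Unused.
#' @return Tibble with counts and the overall active fraction.
#' @export
glance.mir_activity <- function(x, threshold = 1e-5, ...) {
  tibble::tibble(
    n_mirnas = nrow(x$pvalues),
    n_samples = ncol(x$pvalues),
    frac_active = mean(x$pvalues < threshold),
    min_p = min(x$pvalues)
  )
}
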