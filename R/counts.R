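#' Count matrix container for cells or spots
#'
#' Light wrapper around a gene-by-sample count matrix carrying the optional
#' per-sample metadata the pipeline needs: spatial coordinates for spot data
#' and population labels for comparative analyses.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = cell/spot barcodes), non-negative.
#' @param coords Optional tibble/data frame with columns `barcode`, `x`, `y`.
#' @param populations Optional character vector of population labels, either
#'   named by barcode or in column order.
#' @return An object of class `mir_counts`.
#' @export
mir_counts <- function(counts, coords = NULL, populations = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs gene rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be non-negative and complete", call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- tibble::as_tibble(coords)
    stopifnot(all(c("barcode", "x", "y") %in% names(coords)))
  }
  if (!is.null(populations)) {
    if (!is.null(names(populations))) {
      populations <- populations[colnames(counts)]
    }
    stopifnot(length(populations) == ncol(counts))
    populations <- stats::setNames(as.character(populations), colnames(counts))
  }
  structure(list(counts = counts, coords = coords, populations = populations),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("<mir_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples", sep = "")
  if (!is.null(x$coords)) cat(", spatial")
  if (!is.null(x$populations)) {
    cat(", populations: ", paste(unique(x$populations), collapse = "/"))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

# rebuild the object after subsetting columns, keeping metadata aligned
subset_samples <- function(x, keep) {
  counts <- x$counts[, keep, drop = FALSE]
  pops <- if (is.null(x$populations)) NULL else x$populations[colnames(counts)]
  coords <- if (is.null(x$coords)) {
    NULL
  } else {
    x$coords[x$coords$barcode %in% colnames(counts), , drop = FALSE]
  }
  mir_counts(counts, coords = coords, populations = pops)
}

#' Clean a raw count matrix
#'
#' Collapses duplicated gene symbols (the row with the larger total count is
#' kept; ties keep the first), removes all-zero gene rows, and among samples
#' with bit-identical count vectors keeps only the first in input order.
#'
#' @param x A [mir_counts()] object.
#' @return Cleaned `mir_counts`; errors if nothing survives.
#' @export
clean_counts <- function(x) {
  stopifnot(inherits(x, "mir_counts"))
  counts <- x$counts

  if (anyDuplicated(rownames(counts))) {
    totals <- rowSums(counts)
    ord <- order(factor(rownames(counts), levels = unique(rownames(counts))),
                 -totals)
    counts <- counts[ord, , drop = FALSE]
    counts <- counts[!duplicated(rownames(counts)), , drop = FALSE]
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  dup_cells <- duplicated(t(counts))
  if (any(dup_cells)) {
    message("removing ", sum(dup_cells), " duplicate expression profile(s)")
    counts <- counts[, !dup_cells, drop = FALSE]
  }
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stop("matrix is empty after cleaning", call. = FALSE)
  }
  out <- x
  out$counts <- counts
  subset_samples(out, colnames(counts))
}

#' Drop low-coverage cells
#'
#' Removes samples whose total count falls below `min_reads` (strict `<`);
#' cells with very few reads can distort per-gene z-scores, so dropping them
#' before standardisation is recommended for sparse datasets.
#'
#' @param x A [mir_counts()] object.
#' @param min_reads Minimum total reads per retained cell.
#' @return Filtered `mir_counts`.
#' @export
filter_low_count_cells <- function(x, min_reads = 1000) {
  stopifnot(inherits(x, "mir_counts"))
  totals <- colSums(x$counts)
  keep <- totals >= min_reads
  if (!any(keep)) stop("all cells fall below `min_reads`", call. = FALSE)
  if (any(!keep)) message("dropping ", sum(!keep), " cell(s) with < ",
                          min_reads, " reads")
  subset_samples(x, colnames(x$counts)[keep])
}

#' Subsample cells for tractability
#'
#' Large datasets are reduced to `n` cells by uniform sampling without
#' replacement (the default of 10,000 trades little statistical power for a
#' large speedup). With `stratify = TRUE` and population labels present, an
#' equal share of `n` is drawn from each population. The default seed is
#' fixed so repeated pipeline runs select the same cells; pass your own seed
#' to resample.
#'
#' @param x A [mir_counts()] object.
#' @param n Target number of cells.
#' @param seed Integer seed controlling the draw.
#' @param stratify Draw equally per population?
#' @return `mir_counts` with at most `n` columns, in original column order.
#' @export
sample_cells <- function(x, n = 10000, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(x, "mir_counts"), n >= 1)
  S <- ncol(x$counts)
  if (S <= n) return(x)
  barcodes <- colnames(x$counts)
  keep <- withr::with_seed(seed, {
    if (stratify && !is.null(x$populations)) {
      pops <- split(barcodes, x$populations[barcodes])
      quota <- floor(n / length(pops))
      unlist(lapply(pops, function(b) {
        if (length(b) <= quota) b else sample(b, quota)
      }), use.names = FALSE)
    } else {
      sample(barcodes, n)
    }
  })
  subset_samples(x, barcodes[barcodes %in% keep])
}

#' Normalise each cell or spot to a common total
#'
#' Scales every column so that its sum equals `total` (10,000 by default),
#' removing depth differences between cells/spots before standardisation.
#'
#' @param x A [mir_counts()] object.
#' @param total Target column sum.
#' @return `mir_counts` with real-valued normalised counts.
#' @export
normalize_total <- function(x, total = 10000) {
  stopifnot(inherits(x, "mir_counts"), total > 0)
  sums <- colSums(x$counts)
  if (any(sums == 0)) {
    stop("zero-total sample(s) present; run clean_counts() first", call. = FALSE)
  }
  out <- x
  out$counts <- sweep(x$counts, 2, sums / total, "/")
  out
}

#' Per-gene z-score standardisation
#'
#' Transforms each gene's normalised counts into z-scores
#' `z(g, s) = (c(g, s) - a(g)) / sigma(g)` with the mean `a(g)` and the
#' *population* standard deviation `sigma(g)` (denominator `1/S`, not
#' `1/(S-1)`) taken across all `S` samples. Genes with zero variance carry no
#' ranking information and are dropped with a warning.
#'
#' @param x A normalised [mir_counts()] object with at least two samples.
#' @return A `mir_zscores` object: list with the z-score matrix `z`, per-gene
#'   `mean` and `sd`, and the sample metadata carried over.
#' @export
zscore_by_gene <- function(x) {
  stopifnot(inherits(x, "mir_counts"))
  S <- ncol(x$counts)
  if (S < 2) stop("z-scores require at least two samples", call. = FALSE)
  a <- rowMeans(x$counts)
  sigma <- sqrt(rowMeans((x$counts - a)^2))
  drop <- sigma == 0
  if (any(drop)) {
    warning(sum(drop), " constant gene(s) dropped (zero variance)",
            call. = FALSE)
  }
  z <- (x$counts[!drop, , drop = FALSE] - a[!drop]) / sigma[!drop]
  structure(
    list(z = z, mean = a[!drop], sd = sigma[!drop],
         coords = x$coords, populations = x$populations),
    class = "mir_zscores"
  )
}

#' @export
print.mir_zscores <- function(x, ...) {
  cat("<mir_zscores> ", nrow(x$z), " genes x ", ncol(x$z), " samples\n",
      sep = "")
  invisible(x)
}

#' @export
dim.mir_zscores <- function(x) dim(x$z)

#' Standard preprocessing pipeline
#'
#' Applies, in order: [clean_counts()], optionally
#' [filter_low_count_cells()], [sample_cells()], [normalize_total()] and
#' [zscore_by_gene()]. The fixed order matters: depth normalisation must see
#' the final cell set, and z-scores must see normalised values.
#'
#' @param x A raw [mir_counts()] object.
#' @param min_reads If non-`NULL`, threshold for the low-coverage filter
#'   (opt-in; recommended for sparse single-cell data).
#' @param sample_n,seed,stratify Passed to [sample_cells()]; `sample_n = Inf`
#'   disables sampling.
#' @param total Passed to [normalize_total()].
#' @return List with the normalised `counts` (`mir_counts`) and the
#'   `zscores` (`mir_zscores`).
#' @export
preprocess_counts <- function(x, min_reads = NULL, sample_n = 10000,
                              seed = 1L, stratify = FALSE, total = 10000) {
  x <- clean_counts(x)
  if (!is.null(min_reads)) x <- filter_low_count_cells(x, min_reads)
  if (is.finite(sample_n)) {
    x <- sample_cells(x, n = sample_n, seed = seed, stratify = stratify)
  }
  norm <- normalize_total(x, total = total)
  list(counts = norm, zscores = zscore_by_gene(norm))
}
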