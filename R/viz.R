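#' Preprocess counts for a 2-D embedding
#'
#' Standard single-cell reduction ahead of a UMAP-style layout, applied in
#' order: cells with fewer than `min_genes` detected genes are excluded,
#' genes detected in fewer than `min_cells` cells are excluded, cells below
#' the bottom and above the top `trim` quantile of total counts are removed
#' as outliers, counts are normalised to `total` per cell and
#' log(1 + x)-transformed, the `n_hvg` most variable genes are kept, and the
#' matrix is reduced to `n_pcs` principal components. The 2-D coordinates are
#' then delegated to an existing embedding implementation (uwot's UMAP) and
#' treated as opaque.
#'
#' @param x A raw [mir_counts()] object.
#' @param min_genes,min_cells,trim,total,n_hvg,n_pcs Tuning parameters; the
#'   defaults follow common single-cell practice.
#' @param seed Seed for the embedding.
#' @return List with `reduced` (cells x PCs matrix) and `coords` (tibble
#'   `barcode`, `x`, `y`).
#' @export
embedding_preprocess <- function(x, min_genes = 200, min_cells = 3,
                                 trim = 0.02, total = 10000, n_hvg = 2000,
                                 n_pcs = 50, seed = 1L) {
  stopifnot(inherits(x, "mir_counts"))
  m <- x$counts
  m <- m[, colSums(m > 0) >= min_genes, drop = FALSE]
  m <- m[rowSums(m > 0) >= min_cells, , drop = FALSE]
  totals <- colSums(m)
  qs <- quantile(totals, c(trim, 1 - trim))
  m <- m[, totals >= qs[1] & totals <= qs[2], drop = FALSE]
  if (ncol(m) < 10) stop("too few cells after filtering", call. = FALSE)
  m <- sweep(m, 2, colSums(m) / total, "/")
  m <- log1p(m)
  vars <- apply(m, 1, stats::var)
  m <- m[order(vars, decreasing = TRUE)[seq_len(min(n_hvg, nrow(m)))], ,
         drop = FALSE]
  n_pcs <- min(n_pcs, ncol(m) - 1, nrow(m))
  pca <- stats::prcomp(t(m), rank. = n_pcs, center = TRUE, scale. = FALSE)
  reduced <- pca$x
  emb <- if (requireNamespace("uwot", quietly = TRUE)) {
    withr::with_seed(seed, uwot::umap(reduced))
  } else {
    reduced[, 1:2, drop = FALSE] # fall back to the leading PCs
  }
  coords <- tibble::tibble(barcode = colnames(m),
                           x = emb[, 1], y = emb[, 2])
  list(reduced = reduced, coords = coords)
}

#' Activity map for one miRNA
#'
#' Scatter of cells/spots at their (spatial or embedding) coordinates
#' coloured by -log10 of the activity p-value, so bright regions mark strong
#' inferred activity.
#'
#' @param coords Tibble with `barcode`, `x`, `y`.
#' @param a A `mir_activity` object.
#' @param mirna miRNA id to plot.
#' @return A ggplot object.
#' @export
activity_map <- function(coords, a, mirna) {
  stopifnot(inherits(a, "mir_activity"), mirna %in% rownames(a$pvalues))
  df <- coords[coords$barcode %in% colnames(a$pvalues), , drop = FALSE]
  df$neglog10_p <- -log10(a$pvalues[mirna, df$barcode])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$neglog10_p)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = "-log10(p)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste(mirna, "activity"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-population activity histograms for one miRNA
#'
#' Overlaid histograms of -log10 activity p-values, one layer per
#' population; separation of the layers visualises differential activity.
#'
#' @param a A `mir_activity` object with population labels.
#' @param mirna miRNA id to plot.
#' @param populations Optional labels overriding those embedded in `a`.
#' @return A ggplot object.
#' @export
comparative_histograms <- function(a, mirna, populations = NULL) {
  stopifnot(inherits(a, "mir_activity"), mirna %in% rownames(a$pvalues))
  populations <- populations %||% a$populations
  if (is.null(populations)) stop("population labels required", call. = FALSE)
  df <- tibble::tibble(
    neglog10_p = -log10(a$pvalues[mirna, ]),
    population = unname(populations[colnames(a$pvalues)])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$neglog10_p,
                                   fill = .data$population)) +
    ggplot2::geom_histogram(alpha = 0.55, position = "identity", bins = 30) +
    ggplot2::labs(title = paste(mirna, "activity by population"),
                  x = "-log10(activity p-value)", y = "cells") +
    ggplot2::theme_minimal()
}

#' @describeIn activity_map `autoplot` method: activity map when coordinates
#'   are available, otherwise comparative histograms.
#' @param object A `mir_activity` object.
#' @param ... Unused.
#' @export
autoplot.mir_activity <- function(object, mirna, ...) {
  if (!is.null(object$coords)) {
    activity_map(object$coords, object, mirna)
  } else {
    comparative_histograms(object, mirna)
  }
}
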