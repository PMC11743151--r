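strip_gz <- function(path) sub("\\.gz$", "", path)

read_dense_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric entries in ", path, call. = FALSE)
  }
  m
}

read_mtx_counts <- function(dir) {
  find_one <- function(stems) {
    for (stem in stems) {
      for (ext in c("", ".gz")) {
        p <- file.path(dir, paste0(stem, ext))
        if (file.exists(p)) return(p)
      }
    }
    stop("no ", stems[1], " found in ", dir, call. = FALSE)
  }
  mtx <- find_one("matrix.mtx")
  feat <- find_one(c("features.tsv", "genes.tsv"))
  bar <- find_one("barcodes.tsv")
  m <- as.matrix(Matrix::readMM(mtx))
  features <- utils::read.delim(feat, header = FALSE)
  barcodes <- utils::read.delim(bar, header = FALSE)[[1]]
  genes <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop("dimension mismatch between matrix/features/barcodes in ", dir,
         call. = FALSE)
  }
  dimnames(m) <- list(as.character(genes), as.character(barcodes))
  m
}

#' Read one or more count matrices
#'
#' Supports dense delimiter-separated tables (`.tsv`/`.txt`, optionally
#' gzip-compressed; genes in rows, first column gene ids, header of cell
#' barcodes) and MatrixMarket triplets (a directory containing
#' `matrix.mtx[.gz]` with `features.tsv`/`genes.tsv` and `barcodes.tsv`).
#' Several inputs are merged on the union of gene ids with absent entries set
#' to zero; colliding barcodes across files are suffixed with the file index
#' (with a warning) so no cells are silently lost. When `cache` is given, the
#' assembled matrix is serialised there and reused on the next call.
#'
#' @param paths Character vector of files and/or MatrixMarket directories.
#' @param cache Optional path of an `.rds` cache of the assembled matrix.
#' @return A [mir_counts()] object.
#' @export
read_counts <- function(paths, cache = NULL) {
  if (!is.null(cache) && file.exists(cache)) {
    return(readRDS(cache))
  }
  mats <- lapply(paths, function(p) {
    if (dir.exists(p)) return(read_mtx_counts(p))
    ext <- tools::file_ext(strip_gz(p))
    if (!ext %in% c("tsv", "txt")) {
      stop("unrecognised count file extension: ", p, call. = FALSE)
    }
    read_dense_counts(p)
  })
  if (length(mats) > 1) {
    all_bars <- unlist(lapply(mats, colnames))
    if (anyDuplicated(all_bars)) {
      warning("barcodes collide across files; suffixing with file index",
              call. = FALSE)
      mats <- lapply(seq_along(mats), function(i) {
        m <- mats[[i]]
        colnames(m) <- paste0(colnames(m), "_", i)
        m
      })
    }
    genes <- Reduce(union, lapply(mats, rownames))
    mats <- lapply(mats, function(m) {
      out <- matrix(0, length(genes), ncol(m),
                    dimnames = list(genes, colnames(m)))
      out[rownames(m), ] <- m
      out
    })
  }
  counts <- do.call(cbind, mats)
  out <- mir_counts(counts)
  if (!is.null(cache)) saveRDS(out, cache)
  out
}

#' Read a spatial positions table
#'
#' Comma-separated table with columns `barcode`, `x`, `y` (header optional if
#' in that order).
#'
#' @param path Positions file.
#' @return Tibble with `barcode`, `x`, `y`; duplicate barcodes are an error.
#' @export
read_spatial_positions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(df))) {
    names(df)[1:3] <- c("barcode", "x", "y")
  }
  if (anyDuplicated(df$barcode)) {
    stop("duplicate barcode(s) in ", path, call. = FALSE)
  }
  tibble::as_tibble(df[c("barcode", "x", "y")])
}

#' Attach spatial positions to a count matrix
#'
#' Positions without a matching barcode in the counts are dropped with a
#' warning; counted barcodes without a position stay in the matrix (they
#' contribute to statistics but not to maps).
#'
#' @param x A [mir_counts()] object.
#' @param positions Tibble from [read_spatial_positions()].
#' @return `mir_counts` with coordinates attached.
#' @export
attach_positions <- function(x, positions) {
  stopifnot(inherits(x, "mir_counts"))
  extra <- setdiff(positions$barcode, colnames(x$counts))
  if (length(extra) > 0) {
    warning(length(extra), " position(s) without counts dropped",
            call. = FALSE)
    positions <- positions[!positions$barcode %in% extra, , drop = FALSE]
  }
  x$coords <- positions
  x
}

report_html <- function(report, plot_files) {
  rows <- vapply(seq_len(nrow(report)), function(i) {
    mir <- report$mirna[i]
    link <- if (!is.null(plot_files) && mir %in% names(plot_files)) {
      sprintf('<a href="%s">map</a>', basename(plot_files[[mir]]))
    } else {
      ""
    }
    sprintf("<tr><td>%d</td><td>%s</td><td>%.3g</td><td>%s</td><td>%s</td></tr>",
            report$rank[i], mir, report$score[i], report$tier[i], link)
  }, "")
  paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>miRNA activity report</title></head><body>",
    "<h1>Ranked miRNA activity (", report$mode[1], " mode)</h1>",
    "<table border='1'><tr><th>rank</th><th>miRNA</th><th>score</th>",
    "<th>tier</th><th>plot</th></tr>",
    paste(rows, collapse = ""), "</table></body></html>"
  )
}

#' Write pipeline outputs
#'
#' Writes the activity matrix as a tab-separated table (miRNA rows, sample
#' columns), the ranked report as TSV and as a static HTML listing, and
#' activity plots for the `top_k` highest-ranked miRNAs (maps when
#' coordinates are available, comparative histograms when population labels
#' are).
#'
#' @param activity A `mir_activity` object.
#' @param report Ranked-report tibble.
#' @param dir Output directory (created if missing).
#' @param top_k Number of top-ranked miRNAs to plot; 0 disables plotting.
#' @param coords Optional coordinates overriding those in `activity`.
#' @return Invisibly, a named list of written paths.
#' @export
write_outputs <- function(activity, report, dir, top_k = 10, coords = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  matrix_path <- file.path(dir, "activity_matrix.tsv")
  utils::write.table(activity$pvalues, matrix_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  report_path <- file.path(dir, "report.tsv")
  readr::write_tsv(report, report_path, progress = FALSE)

  coords <- coords %||% activity$coords
  plot_files <- list()
  if (top_k > 0) {
    for (mir in utils::head(report$mirna, top_k)) {
      p <- if (!is.null(coords)) {
        activity_map(coords, activity, mir)
      } else if (!is.null(activity$populations)) {
        comparative_histograms(activity, mir)
      } else {
        next
      }
      f <- file.path(dir, paste0("activity_", gsub("[^A-Za-z0-9._-]", "_", mir),
                                 ".png"))
      ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
      plot_files[[mir]] <- f
    }
  }
  html_path <- file.path(dir, "report.html")
  writeLines(report_html(report, plot_files), html_path)
  invisible(list(matrix = matrix_path, report = report_path,
                 html = html_path, plots = plot_files))
}
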