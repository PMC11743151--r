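infer_mode <- function(counts, populations) {
  if (!is.null(counts$coords)) return("spatial")
  if (!is.null(populations) || !is.null(counts$populations)) {
    return("comparative")
  }
  "total"
}

# population labels recovered from the substrings embedded in barcodes
populations_from_barcodes <- function(barcodes, population_strings) {
  hits <- sapply(population_strings, function(p) grepl(p, barcodes, fixed = TRUE))
  hits <- matrix(hits, nrow = length(barcodes))
  n <- rowSums(hits)
  if (any(n != 1)) {
    stop(sum(n != 1), " barcode(s) match ", "zero or several population ",
         "strings; labels must be unique across cells", call. = FALSE)
  }
  stats::setNames(population_strings[apply(hits, 1, which)], barcodes)
}

#' End-to-end miRNA activity pipeline
#'
#' Reads counts (and optional spatial positions), builds the target index
#' from a filtered interaction table, preprocesses (clean, optional
#' low-coverage filter, subsample, depth-normalise, z-score), computes the
#' activity matrix, aggregates it in the requested mode, and writes the
#' outputs. The mode is inferred when not given: positions present means
#' spatial; two population strings mean comparative; otherwise total.
#'
#' @param data_path Count file(s)/directory for [read_counts()], or a
#'   ready-made [mir_counts()] object.
#' @param mti Path to an interaction table for [read_mti()], or a
#'   `target_index`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param mode `"spatial"`, `"total"` or `"comparative"` (default inferred).
#' @param species Passed to [build_target_index()] when `mti` is a path.
#' @param populations Two population strings searched for inside barcodes
#'   (comparative mode).
#' @param positions_path Optional spatial positions CSV.
#' @param mirnas Optional subset of miRNAs to evaluate.
#' @param cpus Worker processes for [compute_activity()].
#' @param sample_size Cell subsample size (`Inf` disables).
#' @param activity_threshold Spot-level significance threshold for spatial
#'   scores.
#' @param min_reads Optional low-coverage cell filter.
#' @param top_k Number of miRNAs to plot.
#' @param seed Seed for the cell subsample.
#' @return List with `activity` (`mir_activity`), `report` (ranked tibble),
#'   `mode`, and `files` when outputs were written.
#' @export
run_activity_pipeline <- function(data_path, mti, out_dir = NULL,
                                  mode = NULL,
                                  species = "homo_sapiens",
                                  populations = NULL,
                                  positions_path = NULL,
                                  mirnas = NULL,
                                  cpus = 1L,
                                  sample_size = 10000,
                                  activity_threshold = 1e-5,
                                  min_reads = NULL,
                                  top_k = 10,
                                  seed = 1L) {
  counts <- if (inherits(data_path, "mir_counts")) {
    data_path
  } else {
    read_counts(data_path)
  }
  if (!is.null(positions_path)) {
    counts <- attach_positions(counts, read_spatial_positions(positions_path))
  }
  if (!is.null(populations)) {
    stopifnot(length(populations) == 2)
    counts$populations <- populations_from_barcodes(colnames(counts$counts),
                                                    populations)
  }
  index <- if (inherits(mti, "target_index")) {
    mti
  } else {
    build_target_index(filter_mtis(read_mti(mti)), species = species)
  }
  mode <- mode %||% infer_mode(counts, populations)

  pre <- preprocess_counts(
    counts, min_reads = min_reads, sample_n = sample_size, seed = seed,
    stratify = mode == "comparative"
  )
  activity <- compute_activity(pre$zscores, index, mirnas = mirnas,
                               cpus = cpus)
  report <- switch(
    mode,
    spatial = spatial_scores(activity, threshold = activity_threshold),
    total = total_scores(activity),
    comparative = assign_comparative_tiers(comparative_scores(activity))
  )
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_outputs(activity, report, out_dir, top_k = top_k)
  }
  list(activity = activity, report = report, mode = mode, files = files)
}
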