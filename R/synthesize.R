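#' Synthetic miRNA-target interaction fixture
#'
#' Builds an interaction table in the same tidy layout as [read_mti()]
#' output: every row functional with one strong evidence, so the whole table
#' survives [filter_mtis()]. Target sets are drawn without replacement from a
#' shared gene universe `G0001, G0002, ...`.
#'
#' @param n_mirnas Number of miRNAs.
#' @param targets_per_mirna Targets drawn for each miRNA.
#' @param n_genes Size of the gene universe.
#' @param seed Integer seed.
#' @param species Species prefix for the generated ids.
#' @param disjoint If `TRUE`, target sets are drawn mutually disjoint
#'   (requires `n_mirnas * targets_per_mirna <= n_genes`), so each miRNA's
#'   signal is attributable to it alone; by default sets are drawn
#'   independently and may overlap, as real catalogues do.
#' @return Tibble with `mirna`, `target`, `support_type`, `functional`,
#'   `strength`.
#' @export
generate_mti_fixture <- function(n_mirnas = 10, targets_per_mirna = 20,
                                 n_genes = 500, seed = 1L,
                                 species = c("homo_sapiens", "mus_musculus"),
                                 disjoint = FALSE) {
  species <- match.arg(species)
  stopifnot(targets_per_mirna <= n_genes)
  if (disjoint) stopifnot(n_mirnas * targets_per_mirna <= n_genes)
  prefix <- c(homo_sapiens = "hsa", mus_musculus = "mmu")[[species]]
  genes <- sprintf("G%04d", seq_len(n_genes))
  mirnas <- sprintf("%s-miR-sim%d-5p", prefix, seq_len(n_mirnas))
  withr::with_seed(seed, {
    targets <- if (disjoint) {
      sample(genes, n_mirnas * targets_per_mirna)
    } else {
      unlist(lapply(mirnas, function(m) sample(genes, targets_per_mirna)))
    }
    tibble::tibble(
      mirna = rep(mirnas, each = targets_per_mirna),
      target = targets,
      support_type = "Functional MTI",
      functional = TRUE,
      strength = "strong"
    )
  })
}

# negative-binomial baseline: per-gene means log-normal across genes,
# common dispersion; returns mu vector
baseline_means <- function(n_genes, mean_log_mu, sd_log_mu) {
  rlnorm(n_genes, meanlog = mean_log_mu, sdlog = sd_log_mu)
}

# multiplicative knock-down factor chosen so the post-z-score shift of the
# gene is ~ -delta: a mean drop of delta * sd is a factor 1 - delta * cv,
# cv the NB coefficient of variation; clipped at 0 (complete silencing) for
# noisy genes whose dynamic range cannot absorb the full shift
knockdown_factor <- function(mu, dispersion, delta) {
  cv <- sqrt(mu + mu^2 / dispersion) / mu
  pmax(0, 1 - delta * cv)
}

#' Synthetic single-cell dataset with planted miRNA activity
#'
#' Simulates a gene-by-cell count matrix with negative-binomial noise
#' (log-normal means across genes, fixed dispersion) and plants activity for
#' the chosen miRNAs: in planted cells, the means of their target genes are
#' multiplied by `exp(-delta * cv)` where `cv` is the gene's coefficient of
#' variation, so that after normalisation and z-scoring the targets shift
#' down by roughly `delta` standard deviations. Planting acts on the means,
#' not on the z-scores, so the entire pipeline (normalisation included) is
#' exercised. With population labels, the labels are embedded in the cell
#' barcodes, as comparative mode expects, and planting defaults to the second
#' population.
#'
#' @param index A `target_index`, e.g. from
#'   `build_target_index(filter_mtis(generate_mti_fixture(...)))`.
#' @param planted_mirnas Character vector of miRNA ids to make active
#'   (may be empty for a pure null dataset).
#' @param n_genes Gene universe size; gene ids follow the fixture convention.
#' @param n_cells Total number of cells.
#' @param delta Planted effect size on the z-score scale (>= 0).
#' @param populations Two labels, or `NULL` for unlabelled data.
#' @param planted_cells Barcode indices of planted cells; defaults to the
#'   second population when labels are present, else the first half.
#' @param plant Optional explicit plant plan overriding
#'   `planted_mirnas`/`planted_cells`: a list of entries
#'   `list(targets = <gene ids>, cells = <column indices>)`, each knocked
#'   down independently. Supports scenarios where different target subsets
#'   are repressed in different cell subsets ("universal" activity).
#' @param mean_log_mu,sd_log_mu Log-normal parameters of per-gene means.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List with `counts` (a [mir_counts()]) and `truth` (planted
#'   miRNAs, planted barcodes, `delta`, generator parameters, `seed`).
#' @export
generate_single_cell_dataset <- function(index,
                                         planted_mirnas = character(),
                                         n_genes = 500, n_cells = 400,
                                         delta = 2,
                                         populations = c("ctrl", "case"),
                                         planted_cells = NULL,
                                         plant = NULL,
                                         mean_log_mu = log(20), sd_log_mu = 0.8,
                                         dispersion = 10, seed = 1L) {
  stopifnot(delta >= 0, all(planted_mirnas %in% names(index)))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(populations)) {
    stopifnot(length(populations) == 2)
    half <- ceiling(n_cells / 2)
    pop <- rep(populations, c(half, n_cells - half))
    barcodes <- sprintf("cell%04d_%s", seq_len(n_cells), pop)
  } else {
    pop <- NULL
    barcodes <- sprintf("cell%04d", seq_len(n_cells))
  }
  if (is.null(planted_cells)) {
    planted_cells <- if (is.null(pop)) {
      seq_len(floor(n_cells / 2))
    } else {
      which(pop == populations[2])
    }
  }

  if (is.null(plant)) {
    plant <- if (length(planted_mirnas) > 0) {
      list(list(targets = unique(unlist(index[planted_mirnas])),
                cells = planted_cells))
    } else {
      list()
    }
  }
  counts <- withr::with_seed(seed, {
    mu <- baseline_means(n_genes, mean_log_mu, sd_log_mu)
    m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = dispersion),
                nrow = n_genes)
    if (delta > 0) {
      for (entry in plant) {
        tg_rows <- which(genes %in% toupper(entry$targets))
        if (length(tg_rows) == 0 || length(entry$cells) == 0) next
        mu_kd <- mu[tg_rows] * knockdown_factor(mu[tg_rows], dispersion, delta)
        m[tg_rows, entry$cells] <- matrix(
          rnbinom(length(tg_rows) * length(entry$cells),
                  mu = mu_kd, size = dispersion),
          nrow = length(tg_rows)
        )
      }
    }
    m
  })
  dimnames(counts) <- list(genes, barcodes)
  list(
    counts = mir_counts(counts, populations = pop),
    truth = list(
      planted_mirnas = planted_mirnas,
      planted_barcodes = barcodes[planted_cells],
      delta = delta,
      params = list(mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
                    dispersion = dispersion),
      seed = seed
    )
  )
}

#' Synthetic spatial dataset with a planted active region
#'
#' Lays spots on an integer grid and plants activity (as in
#' [generate_single_cell_dataset()]) in the spots satisfying the region
#' predicate, emulating a tissue domain where the miRNA is switched on.
#'
#' @param index A `target_index`.
#' @param planted_mirnas miRNAs active inside the region.
#' @param grid Integer vector `c(nx, ny)` of grid dimensions.
#' @param region Predicate `function(x, y)` returning `TRUE` inside the
#'   active region.
#' @inheritParams generate_single_cell_dataset
#' @return List with `counts` (a [mir_counts()] with coordinates) and
#'   `truth`.
#' @export
generate_spatial_dataset <- function(index, planted_mirnas = character(),
                                     grid = c(20, 20),
                                     region = function(x, y) x <= grid[1] / 2,
                                     n_genes = 500, delta = 2,
                                     mean_log_mu = log(20), sd_log_mu = 0.8,
                                     dispersion = 10, seed = 1L) {
  xy <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]))
  planted <- which(mapply(region, xy$x, xy$y))
  sim <- generate_single_cell_dataset(
    index, planted_mirnas = planted_mirnas, n_genes = n_genes,
    n_cells = nrow(xy), delta = delta, populations = NULL,
    planted_cells = planted, mean_log_mu = mean_log_mu,
    sd_log_mu = sd_log_mu, dispersion = dispersion, seed = seed
  )
  barcodes <- sprintf("spot_%d_%d", xy$x, xy$y)
  colnames(sim$counts$counts) <- barcodes
  sim$counts$coords <- tibble::tibble(barcode = barcodes, x = xy$x, y = xy$y)
  sim$truth$planted_barcodes <- barcodes[planted]
  sim
}

#' Binomial downsampling of a count matrix
#'
#' Replaces each count by a `Binomial(count, fraction)` draw, emulating
#' shallower sequencing of the same library; `fraction = 1` is the identity.
#'
#' @param x A [mir_counts()] object with integer counts.
#' @param fraction Retention probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return Downsampled `mir_counts`.
#' @export
downsample_counts <- function(x, fraction, seed = 1L) {
  stopifnot(inherits(x, "mir_counts"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(x)
  out <- x
  out$counts[] <- withr::with_seed(
    seed,
    rbinom(length(x$counts), size = as.integer(x$counts), prob = fraction)
  )
  out
}
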