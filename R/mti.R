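#' Read a miRNA-target interaction table
#'
#' Reads a tab-delimited interaction catalogue in the column layout used by
#' experimentally-validated MTI databases (one row per supporting evidence)
#' and maps it onto the tidy layout used by [filter_mtis()]. Required columns
#' (matched case-insensitively, ignoring spaces/underscores): `miRNA`,
#' `Target Gene`, `Support Type`.
#'
#' @param path Path to a tab-delimited file (may be gzip-compressed).
#' @param weak_pattern Regular expression identifying weak-evidence support
#'   types; everything else among functional rows counts as strong evidence.
#' @param nonfunctional_pattern Regular expression identifying non-functional
#'   interaction rows.
#' @return A tibble with columns `mirna`, `target`, `support_type`,
#'   `functional` (logical) and `strength` (`"strong"` or `"weak"`).
#' @export
read_mti <- function(path,
                     weak_pattern = "\\(Weak\\)",
                     nonfunctional_pattern = "Non-Functional") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  key <- gsub("[ _]", "", tolower(names(raw)))
  need <- c(mirna = "mirna", target = "targetgene", support_type = "supporttype")
  idx <- match(need, key)
  if (anyNA(idx)) {
    stop("missing MTI column(s): ", paste(names(need)[is.na(idx)], collapse = ", "),
         " in ", path, call. = FALSE)
  }
  out <- tibble::tibble(
    mirna = as.character(raw[[idx[1]]]),
    target = as.character(raw[[idx[2]]]),
    support_type = as.character(raw[[idx[3]]])
  )
  out$functional <- !grepl(nonfunctional_pattern, out$support_type)
  out$strength <- ifelse(grepl(weak_pattern, out$support_type), "weak", "strong")
  out
}

#' Filter miRNA-target interactions by evidence strength
#'
#' Keeps an interaction pair if it is functional and is backed by at least one
#' strong evidence or at least two weak evidences. Evidence rows are pooled
#' per `(mirna, target)` pair before the rule is applied, because catalogues
#' store one row per supporting reference; non-functional rows are discarded
#' and contribute no evidence. The operation is idempotent.
#'
#' @param records Tibble with columns `mirna`, `target`, `functional`
#'   (logical) and `strength` (`"strong"`/`"weak"`), e.g. from [read_mti()].
#' @param min_weak Number of weak evidences that substitute for one strong.
#' @return The functional rows of `records` belonging to retained pairs.
#' @export
filter_mtis <- function(records, min_weak = 2L) {
  stopifnot(all(c("mirna", "target", "functional", "strength") %in% names(records)))
  bad <- !records$strength %in% c("strong", "weak")
  if (any(bad)) {
    stop("malformed strength label in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::filter(.data$functional) |>
    dplyr::group_by(.data$mirna, .data$target) |>
    dplyr::filter(any(.data$strength == "strong") ||
                    sum(.data$strength == "weak") >= min_weak) |>
    dplyr::ungroup()
}

#' Build a per-miRNA target index
#'
#' Groups filtered interactions by miRNA, restricts to the species implied by
#' the identifier prefix (`hsa-` for human, `mmu-` for mouse), uppercases gene
#' symbols and removes duplicates.
#'
#' @param filtered Filtered interaction tibble from [filter_mtis()].
#' @param species `"homo_sapiens"` or `"mus_musculus"`.
#' @return A `target_index`: named list mapping each miRNA to its character
#'   vector of uppercase target symbols, with a `species` attribute.
#' @export
build_target_index <- function(filtered,
                               species = c("homo_sapiens", "mus_musculus")) {
  species <- match.arg(species)
  prefix <- c(homo_sapiens = "hsa-", mus_musculus = "mmu-")[[species]]
  keep <- startsWith(filtered$mirna, prefix)
  map <- split(toupper(filtered$target[keep]), filtered$mirna[keep])
  map <- lapply(map, function(g) sort(unique(g)))
  map <- map[lengths(map) > 0]
  if (length(map) == 0) {
    stop("no ", species, " interactions survive filtering", call. = FALSE)
  }
  structure(map, species = species, class = "target_index")
}

#' @export
print.target_index <- function(x, ...) {
  sizes <- lengths(x)
  cat("<target_index> ", length(x), " miRNAs (", attr(x, "species"), "), ",
      "targets per miRNA: ", min(sizes), "-", max(sizes),
      " (median ", stats::median(sizes), ")\n", sep = "")
  invisible(x)
}

#' Serialise / deserialise a target index
#'
#' Plain-text round trip: one line per miRNA with a comma-joined target list.
#'
#' @param index A `target_index`.
#' @param path Output (input) file path.
#' @return `write_target_index()` returns `path` invisibly;
#'   `read_target_index()` returns a `target_index`.
#' @export
write_target_index <- function(index, path) {
  df <- tibble::tibble(
    mirna = names(index),
    targets = vapply(index, paste, "", collapse = ",")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_target_index
#' @param species Species recorded on the restored index.
#' @export
read_target_index <- function(path, species = c("homo_sapiens", "mus_musculus")) {
  species <- match.arg(species)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  map <- lapply(strsplit(df$targets, ",", fixed = TRUE), sort)
  names(map) <- df$mirna
  structure(map, species = species, class = "target_index")
}

#' Pairwise Jaccard similarity of target lists
#'
#' `J(A, B) = |A intersect B| / |A union B|` for every pair of miRNAs in the
#' index; a quick screen for miRNAs whose activity maps are bound to look
#' alike because they regulate nearly the same genes.
#'
#' @param index A `target_index` with at least two miRNAs.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
target_jaccard <- function(index) {
  stopifnot(length(index) >= 2)
  m <- length(index)
  out <- matrix(1, m, m, dimnames = list(names(index), names(index)))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      inter <- length(intersect(index[[i]], index[[j]]))
      uni <- length(index[[i]]) + length(index[[j]]) - inter
      out[i, j] <- out[j, i] <- if (uni == 0) 0 else inter / uni
    }
  }
  out
}

#' Hypergeometric overlap test for two sets
#'
#' Tests whether the observed overlap between two sets drawn from a common
#' universe is larger (`side = "over"`) or smaller (`side = "under"`) than
#' expected by chance: `P(X >= overlap)` resp. `P(X <= overlap)` for
#' `X ~ Hypergeometric(universe_size, |A|, |B|)`. Used e.g. to show that the
#' most-active spots of two miRNAs avoid each other.
#'
#' @param set_a,set_b Character (or other atomic) vectors of member ids.
#' @param universe_size Size of the common universe.
#' @param side `"over"` or `"under"`.
#' @return The overlap p-value.
#' @seealso [overlap_pvalue()] for the count-based form.
#' @export
set_overlap_pvalue <- function(set_a, set_b, universe_size,
                               side = c("over", "under")) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  overlap_pvalue(length(intersect(set_a, set_b)), length(set_a),
                 length(set_b), universe_size, side)
}

#' @rdname set_overlap_pvalue
#' @param overlap Observed overlap count.
#' @param n_a,n_b Set sizes.
#' @export
overlap_pvalue <- function(overlap, n_a, n_b, universe_size,
                           side = c("over", "under")) {
  side <- match.arg(side)
  stopifnot(n_a <= universe_size, n_b <= universe_size, overlap >= 0)
  if (overlap > min(n_a, n_b)) {
    stop("overlap exceeds the smaller set", call. = FALSE)
  }
  if (side == "over") {
    hypergeometric_tail(universe_size, n_a, n_b, overlap)
  } else {
    phyper(overlap, n_a, universe_size - n_a, n_b)
  }
}
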