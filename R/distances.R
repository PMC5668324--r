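#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an IUPAC ambiguity code are
#' excluded (pairwise deletion). With transition proportion P and transversion
#' proportion Q over the compared sites, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When either logarithm
#' argument is non-positive the distance is saturated and reported as `Inf`
#' with `defined = FALSE`.
#'
#' @param a,b Aligned gapped DNA strings of equal length (or character vectors
#'   of single characters).
#' @return List with `distance` (proportion; `Inf` when undefined), `sites`
#'   (compared-site count) and `defined` (logical).
#' @export
k2p_distance <- function(a, b) {
  ca <- if (length(a) == 1) seq_to_chars(normalize_seq(a)) else a
  cb <- if (length(b) == 1) seq_to_chars(normalize_seq(b)) else b
  if (length(ca) != length(cb)) stop("sequences differ in aligned length")
  keep <- is_unambiguous(ca) & is_unambiguous(cb)
  n <- sum(keep)
  if (n == 0) stop("no overlap: zero compared sites")
  x <- ca[keep]; y <- cb[keep]
  diff <- x != y
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transitions <- diff & (purine[x] == purine[y])
  P <- sum(transitions) / n
  Q <- (sum(diff) - sum(transitions)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    list(distance = Inf, sites = n, defined = FALSE)
  } else {
    list(distance = -0.5 * log(w1) - 0.25 * log(w2), sites = n, defined = TRUE)
  }
}

#' Pairwise K2P distance matrix with pairwise deletion
#'
#' @param aln A `locus_alignment` with >= 2 sequences.
#' @return A `k2p_dist` object: list with `ids`, `d` (symmetric matrix of
#'   proportions; saturated pairs hold `Inf`), and `sites` (compared-site
#'   counts). Undefined entries are recorded, never silently zeroed.
#' @export
k2p_matrix <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  if (n < 2) stop("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  sites <- matrix(NA_integer_, n, n, dimnames = list(aln$ids, aln$ids))
  diag(sites) <- ncol(mat)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      res <- tryCatch(k2p_distance(mat[i, ], mat[j, ]),
                      error = function(e)
                        stop("pair (", aln$ids[i], ", ", aln$ids[j], "): ",
                             conditionMessage(e)))
      d[i, j] <- d[j, i] <- res$distance
      sites[i, j] <- sites[j, i] <- res$sites
    }
  }
  structure(list(ids = aln$ids, d = d, sites = sites), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("<k2p_dist> ", length(x$ids), " individuals; ",
      sum(!is.finite(x$d[upper.tri(x$d)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a K2P distance matrix into one row per pair
#'
#' @param x A `k2p_dist`.
#' @param species_map Optional named species vector; adds species columns and
#'   an `intra` flag.
#' @param ... Unused.
#' @return Tibble with `id1`, `id2`, `distance`, `sites` (and optionally
#'   `species1`, `species2`, `intra`).
#' @export
tidy.k2p_dist <- function(x, species_map = NULL, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  out <- tibble::tibble(
    id1 = x$ids[idx[, 1]],
    id2 = x$ids[idx[, 2]],
    distance = x$d[idx],
    sites = x$sites[idx]
  )
  if (!is.null(species_map)) {
    out$species1 <- unname(species_map[out$id1])
    out$species2 <- unname(species_map[out$id2])
    out$intra <- out$species1 == out$species2
  }
  out
}

#' Per-species barcode-gap summary
#'
#' For each species: the maximum and mean intra-specific K2P distance, the
#' nearest-neighbour (NN) species and distance (minimum distance from any
#' member to any non-conspecific individual), and whether a local barcode gap
#' is present (`max_intra < nn_distance`). Distances are reported in percent.
#' Saturated (undefined) pairs are excluded from means and never qualify as
#' nearest neighbours. NN ties are resolved by reporting all tied species
#' alphabetically, the first as primary.
#'
#' @param dm A `k2p_dist`.
#' @param species_map Named character vector individual -> species covering
#'   all ids in `dm`.
#' @return Tibble: `species`, `n`, `mean_intra`, `max_intra`, `nn_species`,
#'   `nn_species_all`, `nn_distance`, `gap_present`. Distance columns in %.
#' @export
species_summaries <- function(dm, species_map) {
  sp <- unname(species_map[dm$ids])
  if (anyNA(sp)) stop("species_map does not cover all individuals")
  if (length(unique(sp)) < 2) stop("need at least two species")
  purrr::map_dfr(sort(unique(sp)), function(s) {
    members <- which(sp == s)
    others <- which(sp != s)
    intra <- dm$d[members, members, drop = FALSE][upper.tri(diag(length(members)))]
    intra_def <- intra[is.finite(intra)]
    max_intra <- if (length(intra_def)) max(intra_def) else 0
    mean_intra <- if (length(intra_def)) mean(intra_def) else 0
    inter <- dm$d[members, others, drop = FALSE]
    if (!any(is.finite(inter))) stop("all inter-specific distances undefined for ", s)
    nn_d <- min(inter[is.finite(inter)])
    hit <- which(inter <= nn_d + 1e-12 & is.finite(inter), arr.ind = TRUE)
    nn_sp <- sort(unique(sp[others][hit[, 2]]))
    gap <- max_intra < nn_d
    tibble::tibble(
      species = s, n = length(members),
      mean_intra = 100 * mean_intra, max_intra = 100 * max_intra,
      nn_species = nn_sp[1], nn_species_all = list(nn_sp),
      nn_distance = 100 * nn_d,
      gap_present = gap
    )
  })
}

#' Frequency distribution of intra- and inter-specific distances
#'
#' Each unordered pair is counted once, in exactly one of the two series, in
#' half-open bins `[k*w, (k+1)*w)`. Undefined (saturated) pairs are reported
#' in a separate `undefined` count attribute.
#'
#' @param dm A `k2p_dist`.
#' @param species_map Named species vector.
#' @param bin_width Bin width on the proportion scale (default 0.005).
#' @return Tibble: `bin_start`, `bin_end`, `series` (`"intra"`/`"inter"`),
#'   `count`.
#' @export
distance_histogram <- function(dm, species_map, bin_width = 0.005) {
  if (bin_width <= 0) stop("bin width must be positive")
  pairs <- tidy(dm, species_map = species_map)
  def <- pairs[is.finite(pairs$distance), ]
  if (nrow(def) == 0) stop("no defined distances")
  bin <- floor(def$distance / bin_width)
  out <- dplyr::count(
    tibble::tibble(
      bin_start = bin * bin_width,
      bin_end = (bin + 1) * bin_width,
      series = ifelse(def$intra, "intra", "inter")
    ),
    .data$bin_start, .data$bin_end, .data$series, name = "count"
  )
  attr(out, "undefined") <- sum(!is.finite(pairs$distance))
  out
}

#' Barcode-gap scatter data for plotting
#'
#' Per species, the maximum intra-specific distance against the NN distance;
#' points above the 1:1 line indicate a barcode gap.
#'
#' @inheritParams species_summaries
#' @return Tibble: `species`, `nn_distance`, `max_intra`, `gap_present` (%).
#' @export
barcode_gap_data <- function(dm, species_map) {
  dplyr::select(species_summaries(dm, species_map),
                "species", "nn_distance", "max_intra", "gap_present")
}
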