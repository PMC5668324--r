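# Distance-based species identification: Best Match (BM), Best Close Match
# (BCM) and All Species Barcodes (ASB), with leave-one-out identification
# rates.

match_partition <- function(best_species, query_species) {
  if (all(best_species == query_species)) "correct"
  else if (all(best_species != query_species)) "incorrect"
  else "ambiguous"
}

classify_one <- function(query_id, dm, species_map, method,
                         threshold = NULL, epsilon = 1e-9,
                         asb_strict = TRUE) {
  qi <- match(query_id, dm$ids)
  if (is.na(qi)) stop("query '", query_id, "' absent from distance matrix")
  refs <- setdiff(seq_along(dm$ids), qi)
  if (!length(refs)) stop("no reference sequences")
  dq <- dm$d[qi, refs]
  ref_sp <- unname(species_map[dm$ids[refs]])
  q_sp <- unname(species_map[query_id])
  finite <- is.finite(dq)
  if (!any(finite)) stop("all distances from query '", query_id, "' undefined")
  dmin <- min(dq[finite])
  best <- refs[finite & dq <= dmin + epsilon]
  best_sp <- unname(species_map[dm$ids[best]])

  outcome <- match_partition(best_sp, q_sp)
  if (method %in% c("bcm", "asb") && dmin > threshold + epsilon)
    return(list(outcome = "no_match", best_ids = character(0),
                best_distance = dmin))
  if (method == "asb") {
    within <- refs[finite & dq <= threshold + epsilon]
    within_sp <- unname(species_map[dm$ids[within]])
    consp <- refs[ref_sp == q_sp]
    all_consp_in <- length(within) > 0 && all(consp %in% within)
    if (asb_strict) {
      ok <- all_consp_in && all(within_sp == q_sp)
    } else {
      # lenient variant: allospecifics inside the threshold tolerated when
      # strictly farther than every conspecific
      allo <- within[within_sp != q_sp]
      ok <- all_consp_in &&
        (length(allo) == 0 ||
           (length(consp) > 0 && min(dq[match(allo, refs)]) >
              max(dq[match(consp, refs)]) + epsilon))
    }
    outcome <- if (ok) "correct"
    else if (length(within) == 0) "no_match"
    else if (all(within_sp != q_sp)) "incorrect"
    else "ambiguous"
    best <- within
  }
  list(outcome = outcome, best_ids = dm$ids[best], best_distance = dmin)
}

#' Distance-based identification of queries
#'
#' Runs one of the three classification criteria for every individual (or a
#' chosen subset) in leave-one-out fashion: the query is removed from the
#' reference set, while the BCM/ASB threshold is computed once on the full
#' dataset.
#'
#' * `"bm"` (Best Match): the query is assigned from the set of references at
#'   minimum distance (ties within `epsilon`); all conspecific = correct, all
#'   allospecific = incorrect, mixed = ambiguous.
#' * `"bcm"` (Best Close Match): as BM, but a best match farther than the
#'   threshold yields `no_match`.
#' * `"asb"` (All Species Barcodes): correct only when the within-threshold
#'   match set consists of every conspecific reference and (by default) no
#'   allospecific one.
#'
#' @param dm A `k2p_dist`.
#' @param species_map Named species vector covering all ids.
#' @param method `"bm"`, `"bcm"` or `"asb"`.
#' @param threshold Distance threshold (proportion) for BCM/ASB; default the
#'   95th percentile of intra-specific distances, via [bcm_threshold()].
#' @param query_ids Queries to classify (default: all individuals).
#' @param epsilon Tie tolerance on proportion distances.
#' @param asb_strict If `FALSE`, use the lenient ASB variant that tolerates
#'   allospecifics inside the threshold when strictly farther than all
#'   conspecifics.
#' @return Tibble: `query_id`, `species`, `method`, `outcome`, `best_ids`
#'   (list-column), `best_distance` (%), `threshold` (%; `NA` for BM).
#' @export
classify_queries <- function(dm, species_map, method = c("bm", "bcm", "asb"),
                             threshold = NULL, query_ids = dm$ids,
                             epsilon = 1e-9, asb_strict = TRUE) {
  method <- match.arg(method)
  if (method %in% c("bcm", "asb") && is.null(threshold))
    threshold <- bcm_threshold(dm, species_map)
  threshold_pct <- if (method == "bm") NA_real_ else 100 * threshold
  purrr::map_dfr(query_ids, function(q) {
    res <- classify_one(q, dm, species_map, method, threshold, epsilon, asb_strict)
    tibble::tibble(
      query_id = q,
      species = unname(species_map[q]),
      method = toupper(method),
      outcome = res$outcome,
      best_ids = list(res$best_ids),
      best_distance = 100 * res$best_distance,
      threshold = threshold_pct
    )
  })
}

#' Intra-specific distance threshold for BCM/ASB
#'
#' The given percentile of all defined intra-specific pairwise distances,
#' with linear interpolation (the `type = 7` quantile convention).
#'
#' @param dm A `k2p_dist`.
#' @param species_map Named species vector.
#' @param percentile Percentile in (0, 100]; default 95.
#' @return Threshold as a proportion.
#' @export
bcm_threshold <- function(dm, species_map, percentile = 95) {
  pairs <- tidy(dm, species_map = species_map)
  intra <- pairs$distance[pairs$intra & is.finite(pairs$distance)]
  if (!length(intra)) stop("no conspecific pairs: cannot set a threshold")
  unname(stats::quantile(intra, percentile / 100, type = 7))
}

#' Leave-one-out identification rates
#'
#' Queries every individual of the chosen loci (concatenated when several)
#' against the remaining references and aggregates outcomes into the
#' conventional correctly identified / misidentified / not identified
#' percentages; ambiguous and no-match outcomes are pooled as not identified.
#'
#' @param dataset A `barcode_dataset`.
#' @param loci Locus subset to evaluate (concatenated in the given order).
#' @param methods Subset of `c("bm", "bcm", "asb")`.
#' @param threshold BCM/ASB threshold (proportion); default computed from the
#'   data via [bcm_threshold()].
#' @inheritParams classify_queries
#' @return Tibble: `loci`, `method`, `n`, `correct_pct`, `misidentified_pct`,
#'   `not_identified_pct` (the three percentages sum to 100 up to rounding).
#' @export
identification_rates <- function(dataset, loci = names(dataset$loci),
                                 methods = c("bm", "bcm", "asb"),
                                 threshold = NULL, epsilon = 1e-9,
                                 asb_strict = TRUE) {
  aln <- concat_loci(dataset, loci)
  dm <- k2p_matrix(aln)
  sm <- dataset$species_map
  purrr::map_dfr(methods, function(m) {
    res <- classify_queries(dm, sm, m, threshold = threshold,
                            epsilon = epsilon, asb_strict = asb_strict)
    n <- nrow(res)
    tibble::tibble(
      loci = paste(loci, collapse = "+"),
      method = toupper(m),
      n = n,
      correct_pct = 100 * sum(res$outcome == "correct") / n,
      misidentified_pct = 100 * sum(res$outcome == "incorrect") / n,
      not_identified_pct =
        100 * sum(res$outcome %in% c("ambiguous", "no_match")) / n
    )
  })
}
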