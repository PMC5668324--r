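# Orchestration of the full barcode-evaluation workflow over all loci and
# their multi-locus combinations.

#' Run the full barcode evaluation report
#'
#' Computes, for a multi-locus dataset: the per-locus characteristics table,
#' per-locus and per-combination barcode-gap summaries, leave-one-out
#' identification-rate rows for every single locus and every multi-locus
#' combination (five loci yield 5 + 26 = 31 rows per method), diagnostic
#' characters and induced rules, CAPS assays, and NJ / MP trees with
#' bootstrap supports and species-monophyly flags for a focal combination.
#'
#' @param dataset A `barcode_dataset`.
#' @param methods Identification methods to run (`"bm"`, `"bcm"`, `"asb"`).
#' @param focal_loci Locus combination used for trees, rule induction and
#'   CAPS design; default all loci.
#' @param caps_locus Locus scanned for CAPS assays; default the first locus
#'   with a diagnostic SNP preference (`"matK"` when present, else the first).
#' @param outgroup Optional outgroup individual ids (used to root trees and
#'   test monophyly).
#' @param threshold BCM/ASB threshold (proportion); default data-driven per
#'   combination via [bcm_threshold()].
#' @param bootstrap_replicates Bootstrap pseudo-replicates for the focal NJ
#'   tree (0 disables).
#' @param seed Integer seed governing rule-induction slicing, MP search and
#'   bootstrap.
#' @return A `barcode_report` list: `stats`, `gap_summaries`, `rates`,
#'   `diagnostic_characters`, `rules`, `caps`, `trees` (list: `nj`, `mp`
#'   glance, `monophyly` tibble), `seed`.
#' @export
barcode_report <- function(dataset, methods = c("bm", "bcm", "asb"),
                           focal_loci = names(dataset$loci),
                           caps_locus = NULL, outgroup = NULL,
                           threshold = NULL, bootstrap_replicates = 100,
                           seed = 1) {
  loci <- names(dataset$loci)
  combos <- c(as.list(loci),
              if (length(loci) >= 2) locus_combinations(loci) else list())
  sm <- dataset$species_map

  stats <- dataset_stats(dataset)

  gap_summaries <- purrr::map_dfr(combos, function(cc) {
    aln <- concat_loci(dataset, cc)
    dm <- k2p_matrix(aln)
    dplyr::mutate(species_summaries(dm, sm),
                  loci = paste(cc, collapse = "+"), .before = 1)
  })

  rates <- purrr::map_dfr(combos, function(cc)
    identification_rates(dataset, cc, methods = methods,
                         threshold = threshold))

  focal <- concat_loci(dataset, focal_loci)
  diag_chars <- find_diagnostic_characters(focal)
  rules <- induce_rules(focal, seed = seed)
  caps_locus <- caps_locus %||%
    (if ("matK" %in% loci) "matK" else loci[1])
  caps <- design_caps(dataset$loci[[caps_locus]])

  dm_focal <- k2p_matrix(focal)
  nj <- if (all(is.finite(dm_focal$d))) {
    if (bootstrap_replicates > 0)
      bootstrap_support(focal, builder = "nj",
                        n_replicates = bootstrap_replicates, seed = seed,
                        outgroup = outgroup)
    else nj_tree(dm_focal, outgroup = outgroup)
  } else NULL
  mp <- mp_search(focal, strategy = "auto", seed = seed)
  mono_tree <- if (!is.null(outgroup)) {
    ape::root(mp$trees[[1]], outgroup = outgroup, resolve.root = TRUE)
  } else mp$trees[[1]]
  monophyly <- tibble::tibble(
    species = sort(unique(sm)),
    monophyletic = vapply(sort(unique(sm)), function(s)
      is_species_monophyletic(mono_tree, sm, s), logical(1))
  )

  structure(list(
    stats = stats, gap_summaries = gap_summaries, rates = rates,
    diagnostic_characters = diag_chars, rules = rules, caps = caps,
    trees = list(nj = nj, mp = glance(mp), mp_result = mp,
                 monophyly = monophyly),
    seed = seed
  ), class = "barcode_report")
}

#' @export
print.barcode_report <- function(x, ...) {
  cat("<barcode_report>\n  loci: ", paste(x$stats$locus, collapse = ", "),
      "\n  rate rows: ", nrow(x$rates), " (",
      length(unique(x$rates$loci)), " locus sets x ",
      length(unique(x$rates$method)), " methods)\n  diagnostic characters: ",
      nrow(x$diagnostic_characters), "; CAPS assays: ", nrow(x$caps),
      "\n  MP: length ", x$trees$mp$length, ", CI ",
      round(x$trees$mp$ci, 4), ", RI ", round(x$trees$mp$ri, 4), "\n",
      sep = "")
  invisible(x)
}

#' Write a barcode report to disk
#'
#' Emits TSV tables (stats, gap summaries, rates, diagnostic characters,
#' CAPS), Newick trees, and a machine-readable JSON bundle of all numbers.
#'
#' @param report A `barcode_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.list),
      ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), character(1))))
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$stats, "locus_stats")
  wt(report$gap_summaries, "gap_summaries")
  wt(report$rates, "identification_rates")
  wt(report$diagnostic_characters, "diagnostic_characters")
  wt(report$caps, "caps_assays")
  wt(tidy(report$rules), "rules")
  if (!is.null(report$trees$nj))
    ape::write.tree(report$trees$nj, file.path(dir, "nj.nwk"))
  ape::write.tree(report$trees$mp_result$consensus,
                  file.path(dir, "mp_consensus.nwk"))
  bundle <- list(
    seed = report$seed,
    stats = report$stats,
    gap_summaries = dplyr::select(report$gap_summaries, -"nn_species_all"),
    rates = report$rates,
    mp = report$trees$mp,
    monophyly = report$trees$monophyly
  )
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
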