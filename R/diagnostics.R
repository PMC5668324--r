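# Character-based identification: species-diagnostic nucleotides, conjunctive
# rule induction with stratified train/test slicing, and CAPS assay design.

#' Find pure species-diagnostic characters
#'
#' A column is pure-diagnostic for a species when every member carries the
#' same unambiguous base there and no non-member can carry it: a member gap or
#' ambiguity code disqualifies the column, and a non-member whose (possibly
#' ambiguous) state could include the diagnostic base also disqualifies it.
#'
#' Positions are 1-based alignment columns; `position_ungapped` gives the
#' coordinate in the species' own gap-free consensus (identical for
#' indel-free loci).
#'
#' @param aln A `locus_alignment`.
#' @param species Species to scan (default: all species in the alignment).
#' @return Tibble: `locus`, `species`, `position`, `position_ungapped`,
#'   `state`, `other_states` (list-column of states seen in non-members).
#' @export
find_diagnostic_characters <- function(aln, species = NULL) {
  sp <- aln$species
  targets <- species %||% sort(unique(sp))
  unknown <- setdiff(targets, sp)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  mat <- aln$mat
  purrr::map_dfr(targets, function(s) {
    members <- mat[sp == s, , drop = FALSE]
    others <- mat[sp != s, , drop = FALSE]
    if (nrow(others) == 0) stop("species '", s, "' has no non-members")
    cons <- species_consensus_chars(members)
    ungapped_pos <- cumsum(cons != "-" & !is.na(cons))
    hits <- list()
    for (j in seq_len(ncol(mat))) {
      mc <- members[, j]
      if (!all(is_unambiguous(mc)) || length(unique(mc)) != 1) next
      state <- unname(mc[1])
      oc <- others[, j]
      could_match <- vapply(oc, function(ch) {
        ch != "-" && state %in% (IUPAC_SETS[[ch]] %||% character(0))
      }, logical(1))
      if (any(could_match)) next
      hits[[length(hits) + 1]] <- tibble::tibble(
        locus = aln$locus, species = s, position = j,
        position_ungapped = ungapped_pos[j], state = state,
        other_states = list(sort(unique(oc)))
      )
    }
    dplyr::bind_rows(c(list(empty_diagnostics()), hits))
  })
}

empty_diagnostics <- function() {
  tibble::tibble(locus = character(), species = character(),
                 position = integer(), position_ungapped = integer(),
                 state = character(), other_states = list())
}

# majority base per column; ties or no unambiguous bases -> NA; gap-majority -> "-"
species_consensus_chars <- function(mat) {
  apply(mat, 2, function(chars) {
    tab <- sort(table(chars), decreasing = TRUE)
    if (sum(tab == tab[1]) > 1) return(NA_character_)
    top <- names(tab)[1]
    if (top == "-" || is_unambiguous(top)) top else NA_character_
  })
}

rule_matches <- function(mat, conjuncts) {
  ok <- rep(TRUE, nrow(mat))
  for (k in seq_len(nrow(conjuncts)))
    ok <- ok & mat[, conjuncts$position[k]] == conjuncts$state[k]
  ok
}

# candidate (position, state) pairs with full coverage of the member rows
rule_candidates <- function(members) {
  keep <- which(apply(members, 2, function(ch)
    all(is_unambiguous(ch)) && length(unique(ch)) == 1))
  tibble::tibble(position = keep,
                 state = vapply(keep, function(j) members[1, j], character(1)))
}

induce_rule_for_species <- function(train_mat, train_sp, s, exhaustive_limit = 12) {
  members <- train_mat[train_sp == s, , drop = FALSE]
  others <- train_mat[train_sp != s, , drop = FALSE]
  cand <- rule_candidates(members)
  if (nrow(cand) == 0) return(NULL)
  fp_of <- function(idx) sum(rule_matches(others, cand[idx, , drop = FALSE]))
  # single pure diagnostic characters first
  singles <- which(vapply(seq_len(nrow(cand)), function(i) fp_of(i) == 0, logical(1)))
  if (length(singles)) return(cand[singles[1], , drop = FALSE])
  if (nrow(cand) < 2) return(NULL)
  if (nrow(cand) <= exhaustive_limit) {
    for (k in 2:nrow(cand)) {
      subsets <- utils::combn(seq_len(nrow(cand)), k, simplify = FALSE)
      for (idx in subsets) if (fp_of(idx) == 0)
        return(cand[idx, , drop = FALSE])
    }
    return(NULL)
  }
  # greedy forward selection: maximise non-member exclusion, ties lowest position
  chosen <- integer(0)
  alive <- rep(TRUE, nrow(others))
  while (any(alive)) {
    best_i <- NA_integer_; best_excl <- -1L
    for (i in setdiff(seq_len(nrow(cand)), chosen)) {
      excl <- sum(alive & others[, cand$position[i]] != cand$state[i])
      if (excl > best_excl) { best_excl <- excl; best_i <- i }
    }
    if (is.na(best_i) || best_excl == 0) return(NULL)
    chosen <- c(chosen, best_i)
    alive <- alive & others[, cand$position[best_i]] == cand$state[best_i]
  }
  cand[chosen[order(cand$position[chosen])], , drop = FALSE]
}

#' Induce conjunctive diagnostic rules with train/test slicing
#'
#' Individuals are split per species into a training slice (default 90%) and
#' a test slice. For each species a conjunction of (position, state) pairs is
#' induced on the training slice so that every member matches (coverage 1)
#' and no non-member does (zero false positives): a single pure diagnostic
#' character when one exists, otherwise the smallest conjunction found by
#' exhaustive search over candidate pairs (when at most `exhaustive_limit`
#' candidates) or greedy forward selection. Test individuals are classified
#' by the rules they satisfy and aggregated into identification rates.
#'
#' @param aln A `locus_alignment` (single locus or a concatenation).
#' @param slice_fraction Training fraction within each species (default 0.9).
#' @param seed Integer seed for the stratified split.
#' @param exhaustive_limit Candidate-count bound below which the minimal
#'   conjunction is found exhaustively.
#' @return A `diagnostic_rules` object: list with `rules` (tibble: `species`,
#'   `conjuncts` list-column, `n_conjuncts`, `train_coverage`, `train_fpr`),
#'   `assignments` (per test individual), `rates` (correct/mis/not-identified
#'   %, as in the distance-based methods) and `split` (train/test ids).
#' @export
induce_rules <- function(aln, slice_fraction = 0.9, seed = 1,
                         exhaustive_limit = 12) {
  sp <- aln$species
  counts <- table(sp)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warning("species with a single member excluded from slicing: ",
            paste(singletons, collapse = ", "))
  }
  usable <- !(sp %in% singletons)
  mat <- aln$mat[usable, , drop = FALSE]
  sp <- sp[usable]
  ids <- aln$ids[usable]
  if (length(unique(sp)) < 2) stop("need at least two species with >= 2 members")

  set.seed(seed)
  train_idx <- integer(0)
  for (s in sort(unique(sp))) {
    m <- which(sp == s)
    n_train <- min(length(m) - 1L, max(1L, ceiling(slice_fraction * length(m))))
    train_idx <- c(train_idx, sort(sample(m, n_train)))
  }
  test_idx <- setdiff(seq_along(sp), train_idx)
  train_mat <- mat[train_idx, , drop = FALSE]
  train_sp <- sp[train_idx]

  rules <- purrr::map_dfr(sort(unique(sp)), function(s) {
    conj <- induce_rule_for_species(train_mat, train_sp, s, exhaustive_limit)
    if (is.null(conj)) return(tibble::tibble())
    members <- train_mat[train_sp == s, , drop = FALSE]
    others <- train_mat[train_sp != s, , drop = FALSE]
    tibble::tibble(
      species = s,
      conjuncts = list(conj),
      n_conjuncts = nrow(conj),
      train_coverage = mean(rule_matches(members, conj)),
      train_fpr = mean(rule_matches(others, conj))
    )
  })

  assignments <- purrr::map_dfr(test_idx, function(i) {
    hit <- if (nrow(rules)) rules$species[vapply(rules$conjuncts, function(cj)
      rule_matches(mat[i, , drop = FALSE], cj), logical(1))] else character(0)
    outcome <- if (length(hit) == 1 && hit == sp[i]) "correct"
    else if (length(hit) == 1) "incorrect"
    else if (length(hit) > 1) "ambiguous"
    else "no_match"
    tibble::tibble(query_id = ids[i], species = sp[i],
                   assigned = list(hit), outcome = outcome)
  })
  n <- nrow(assignments)
  rates <- tibble::tibble(
    loci = aln$locus, method = "RULES", n = n,
    correct_pct = 100 * sum(assignments$outcome == "correct") / n,
    misidentified_pct = 100 * sum(assignments$outcome == "incorrect") / n,
    not_identified_pct =
      100 * sum(assignments$outcome %in% c("ambiguous", "no_match")) / n
  )
  structure(list(rules = rules, assignments = assignments, rates = rates,
                 split = list(train = ids[train_idx], test = ids[test_idx])),
            class = "diagnostic_rules")
}

#' @export
print.diagnostic_rules <- function(x, ...) {
  cat("<diagnostic_rules> ", nrow(x$rules), " rule(s); test rates: ",
      sprintf("%.1f/%.1f/%.1f", x$rates$correct_pct, x$rates$misidentified_pct,
              x$rates$not_identified_pct),
      " (correct/mis/not identified %)\n", sep = "")
  for (i in seq_len(nrow(x$rules))) {
    cj <- x$rules$conjuncts[[i]]
    cat("  ", x$rules$species[i], ": ",
        paste(sprintf("pos %d = %s", cj$position, cj$state), collapse = " and "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.diagnostic_rules <- function(x, ...) {
  tidyr::unnest(dplyr::select(x$rules, "species", "conjuncts"), "conjuncts")
}

#' Built-in restriction enzyme panel
#'
#' The default panel used for CAPS design: BstXI, MnlI, HphI and AlwI.
#'
#' @return Tibble: `enzyme`, `site` (IUPAC-degenerate recognition sequence).
#' @export
restriction_enzymes <- function() {
  tibble::tibble(
    enzyme = c("BstXI", "MnlI", "HphI", "AlwI"),
    site = c("CCANNNNNNTGG", "CCTC", "GGTGA", "GGATC")
  )
}

#' Read a restriction enzyme panel from TSV
#'
#' Expects columns `enzyme` and `site`.
#'
#' @param path TSV file path.
#' @return Tibble with the same shape as [restriction_enzymes()].
#' @export
read_enzyme_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("enzyme", "site") %in% names(df)))
    stop("panel must have 'enzyme' and 'site' columns")
  validate_sites(df$site)
  tibble::as_tibble(df[, c("enzyme", "site")])
}

validate_sites <- function(sites) {
  chars <- unlist(strsplit(toupper(sites), "", fixed = TRUE))
  if (!all(chars %in% names(IUPAC_SETS)))
    stop("recognition sites must be IUPAC nucleotide codes")
  if (any(nchar(sites) < 4)) stop("recognition sites must be >= 4 bp")
  invisible(TRUE)
}

#' Scan a sequence for restriction sites
#'
#' IUPAC-degenerate matching of the recognition sequence on both strands;
#' hits on the reverse strand are reported on forward coordinates (start of
#' the matched window). Overlapping matches are all reported.
#'
#' @param seq Ungapped DNA string.
#' @param site IUPAC-degenerate recognition sequence (>= 4 bp).
#' @return Tibble: `position` (1-based start on the forward strand), `strand`
#'   (`"+"`/`"-"`).
#' @export
scan_restriction_sites <- function(seq, site) {
  seq <- normalize_seq(seq)
  if (grepl("-", seq, fixed = TRUE)) stop("sequence contains gap characters")
  site <- toupper(site)
  validate_sites(site)
  subject <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(site), subject,
                                  fixed = FALSE)
  rc <- revcomp(site)
  rev <- Biostrings::matchPattern(Biostrings::DNAString(rc), subject,
                                  fixed = FALSE)
  out <- dplyr::bind_rows(
    tibble::tibble(position = BiocGenerics::start(fwd), strand = "+"),
    tibble::tibble(position = BiocGenerics::start(rev), strand = "-")
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Design CAPS assays from species-specific SNPs
#'
#' For every pure diagnostic SNP, the gap-free per-species consensus around
#' the SNP (a window of site length - 1 on each side) is scanned for
#' recognition sites overlapping the SNP. An assay is emitted when site
#' presence at the SNP differs between the target species and every other
#' species, i.e. the diagnostic substitution creates or destroys the site.
#'
#' @param aln A `locus_alignment`.
#' @param enzymes Enzyme panel tibble (`enzyme`, `site`); default
#'   [restriction_enzymes()].
#' @param species Restrict to these target species (default all).
#' @return Tibble: `locus`, `species`, `position` (alignment column),
#'   `position_ungapped`, `target_state`, `other_state`, `enzyme`, `site`,
#'   `cuts_target` (site present in target), `digest` (list-column of
#'   per-species cut/no-cut flags). Empty when no SNP overlaps a usable site.
#' @export
design_caps <- function(aln, enzymes = restriction_enzymes(), species = NULL) {
  snps <- find_diagnostic_characters(aln, species)
  if (nrow(snps) == 0) return(empty_caps())
  sp <- aln$species
  all_sp <- sort(unique(sp))
  cons <- lapply(stats::setNames(all_sp, all_sp), function(s)
    species_consensus_chars(aln$mat[sp == s, , drop = FALSE]))

  assays <- list()
  for (r in seq_len(nrow(snps))) {
    s <- snps$species[r]; p <- snps$position[r]; state <- snps$state[r]
    others_chars <- aln$mat[sp != s, p]
    other_tab <- sort(table(others_chars[is_unambiguous(others_chars)]),
                      decreasing = TRUE)
    other_state <- if (length(other_tab)) names(other_tab)[1] else NA_character_
    for (e in seq_len(nrow(enzymes))) {
      m <- nchar(enzymes$site[e])
      presence <- vapply(all_sp, function(t)
        site_overlaps_snp(cons[[t]], p, m, enzymes$site[e]), logical(1))
      if (anyNA(presence)) next
      if (all(presence[all_sp != s] != presence[[s]])) {
        assays[[length(assays) + 1]] <- tibble::tibble(
          locus = aln$locus, species = s, position = p,
          position_ungapped = snps$position_ungapped[r],
          target_state = state, other_state = other_state,
          enzyme = enzymes$enzyme[e], site = enzymes$site[e],
          cuts_target = presence[[s]],
          digest = list(presence)
        )
      }
    }
  }
  if (!length(assays)) return(empty_caps())
  dplyr::bind_rows(assays)
}

empty_caps <- function() {
  tibble::tibble(locus = character(), species = character(),
                 position = integer(), position_ungapped = integer(),
                 target_state = character(), other_state = character(),
                 enzyme = character(), site = character(),
                 cuts_target = logical(), digest = list())
}

# does any recognition site overlap the SNP column p on this species'
# gap-free consensus? NA when the window is not a clean unambiguous stretch.
site_overlaps_snp <- function(cons_chars, p, site_len, site) {
  if (is.na(cons_chars[p]) || cons_chars[p] == "-") return(NA)
  # drop gap columns only; tied (NA) columns stay and poison windows they touch
  keep <- is.na(cons_chars) | cons_chars != "-"
  q <- sum(keep[seq_len(p)])
  degapped <- cons_chars[keep]
  lo <- max(1L, q - (site_len - 1L))
  hi <- min(length(degapped), q + (site_len - 1L))
  window <- degapped[lo:hi]
  if (anyNA(window)) return(NA)
  hits <- scan_restriction_sites(paste(window, collapse = ""), site)
  snp_rel <- q - lo + 1L
  any(hits$position <= snp_rel & hits$position + site_len - 1L >= snp_rel)
}
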