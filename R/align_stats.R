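#' Tally the states observed in one alignment column
#'
#' @param aln A `locus_alignment`.
#' @param col 1-based column index.
#' @return List with `bases` (named counts of unambiguous A/C/G/T), `gaps`
#'   (gap count) and `ambiguous` (count of IUPAC ambiguity codes).
#' @export
column_states <- function(aln, col) {
  if (col < 1 || col > ncol(aln$mat)) stop("column ", col, " out of range")
  chars <- aln$mat[, col]
  base <- chars[is_unambiguous(chars)]
  counts <- table(factor(base, levels = BASES))
  counts <- counts[counts > 0]
  list(
    bases = stats::setNames(as.integer(counts), names(counts)),
    gaps = sum(chars == "-"),
    ambiguous = sum(chars != "-" & !is_unambiguous(chars))
  )
}

#' Sequence characteristics of an alignment
#'
#' Computes the per-locus characteristics conventionally reported when
#' evaluating barcode loci: variable sites (columns with at least two distinct
#' unambiguous bases), parsimony-informative sites (at least two bases each
#' present in at least two sequences), conserved sites (a single base state
#' and no gaps), indel events (maximal gap runs, runs with an identical
#' (start, end) span across sequences counted once), and mean pairwise
#' identity.
#'
#' Ambiguity codes never contribute to variability; a column varying only by
#' gaps is counted in the indel tally, not as variable.
#'
#' @param aln A `locus_alignment` with >= 2 sequences.
#' @param gap_mode How pairwise identity treats a gap aligned to a base:
#'   `"mismatch"` (counted as a compared, non-identical site; default) or
#'   `"exclude"` (site dropped from the comparison). Gap-vs-gap sites are
#'   always excluded.
#' @return One-row tibble: `locus`, `n_seqs`, `aligned_length`,
#'   `variable_sites`, `informative_sites`, `conserved_sites`, `indel_events`,
#'   `pairwise_identity` (percent).
#' @export
alignment_stats <- function(aln, gap_mode = c("mismatch", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  mat <- aln$mat
  if (nrow(mat) < 2) stop("need at least two sequences")
  L <- ncol(mat)

  variable <- informative <- conserved <- 0L
  for (j in seq_len(L)) {
    chars <- mat[, j]
    base <- chars[is_unambiguous(chars)]
    tab <- table(base)
    if (length(tab) >= 2) {
      variable <- variable + 1L
      if (sum(tab >= 2) >= 2) informative <- informative + 1L
    } else if (length(tab) == 1 && !any(chars == "-")) {
      conserved <- conserved + 1L
    }
  }

  spans <- character(0)
  for (i in seq_len(nrow(mat))) {
    r <- rle(mat[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap_runs <- which(r$values)
    if (length(gap_runs))
      spans <- c(spans, paste(starts[gap_runs], ends[gap_runs], sep = "-"))
  }
  indel_events <- length(unique(spans))

  n <- nrow(mat)
  idents <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (k in seq(i + 1, n)) {
      a <- mat[i, ]; b <- mat[k, ]
      both_gap <- a == "-" & b == "-"
      cmp <- !both_gap
      if (gap_mode == "exclude") cmp <- cmp & a != "-" & b != "-"
      nc <- sum(cmp)
      idents <- c(idents, if (nc == 0) NA_real_ else 100 * sum(a[cmp] == b[cmp]) / nc)
    }
  }

  tibble::tibble(
    locus = aln$locus,
    n_seqs = n,
    aligned_length = L,
    variable_sites = variable,
    informative_sites = informative,
    conserved_sites = conserved,
    indel_events = indel_events,
    pairwise_identity = mean(idents, na.rm = TRUE)
  )
}

#' Per-locus characteristics table for a dataset
#'
#' One row per locus, mirroring the standard barcode-evaluation summary table.
#'
#' @param dataset A `barcode_dataset`.
#' @inheritParams alignment_stats
#' @return Tibble with one row per locus (see [alignment_stats()]).
#' @export
dataset_stats <- function(dataset, gap_mode = "mismatch") {
  dplyr::bind_rows(lapply(dataset$loci, alignment_stats, gap_mode = gap_mode))
}
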