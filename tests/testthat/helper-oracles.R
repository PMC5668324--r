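# Shared fixtures and independent brute-force oracles.

make_aln <- function(seqs, species, ids = NULL, locus = "locA") {
  ids <- ids %||% paste0("ind", seq_along(seqs))
  locus_alignment(seqs, ids, species, locus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_alignment <- function(n, L, n_species = 2, gap_prob = 0,
                             locus = "locA") {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (gap_prob > 0) {
    gaps <- matrix(runif(n * L) < gap_prob, n, L)
    mat[gaps] <- "-"
  }
  make_aln(apply(mat, 1, paste, collapse = ""),
           species = paste0("sp", rep_len(seq_len(n_species), n)),
           locus = locus)
}

# --- K2P closed form, written directly from the distance definition --------
oracle_k2p <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  x <- ca[keep]; y <- cb[keep]
  is_ts <- (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  P <- sum(is_ts) / sum(keep)
  Q <- sum(x != y & !is_ts) / sum(keep)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(Inf)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[keep] != cb[keep]) / sum(keep)
}

aln_seqs <- function(aln) apply(aln$mat, 1, paste, collapse = "")

# alignments of related sequences (bounded divergence, so K2P stays defined)
related_alignment <- function(n, L, n_species = 2, mut_prob = 0.08,
                              gap_prob = 0, locus = "locA") {
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- t(vapply(seq_len(n), function(i) {
    s <- root
    mut <- runif(L) < mut_prob
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    if (gap_prob > 0) s[runif(L) < gap_prob] <- "-"
    s
  }, character(L)))
  make_aln(apply(mat, 1, paste, collapse = ""),
           species = paste0("sp", rep_len(seq_len(n_species), n)),
           locus = locus)
}

species_of <- function(aln) stats::setNames(aln$species, aln$ids)

# --- exhaustive Fitch: enumerate every internal-state assignment -----------
# valid for small binary trees over unambiguous bases and gaps (gap = any base)
oracle_fitch <- function(tree, aln) {
  tr <- stats::reorder(ape::multi2di(tree), "postorder")
  bases <- c("A", "C", "G", "T")
  nt <- length(tr$tip.label)
  total <- 0L
  for (j in seq_len(ncol(aln$mat))) {
    tip_chars <- aln$mat[match(tr$tip.label, aln$ids), j]
    tip_sets <- lapply(tip_chars, function(ch)
      if (ch %in% bases) ch else bases)
    best <- Inf
    grids <- c(tip_sets, rep(list(bases), tr$Nnode))
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      states <- unlist(combos[r, ])
      cost <- sum(states[tr$edge[, 1]] != states[tr$edge[, 2]])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# --- naive sliding-window degenerate matcher --------------------------------
iupac_match_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_scan <- function(seq, site) {
  sc <- strsplit(toupper(seq), "")[[1]]
  revcomp_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  hits <- function(pattern) {
    pc <- strsplit(toupper(pattern), "")[[1]]
    m <- length(pc)
    out <- integer(0)
    if (length(sc) < m) return(out)
    for (i in seq_len(length(sc) - m + 1)) {
      ok <- TRUE
      for (k in seq_len(m)) {
        if (!(sc[i + k - 1] %in% iupac_match_table[[pc[k]]])) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, i)
    }
    out
  }
  list(fwd = hits(site), rev = hits(revcomp_chr(site)))
}

# --- direct ASB evaluation from the definition ------------------------------
oracle_asb <- function(query_id, dm, species_map, threshold) {
  others <- setdiff(dm$ids, query_id)
  d <- dm$d[query_id, others]
  within <- others[is.finite(d) & d <= threshold + 1e-9]
  consp <- others[species_map[others] == species_map[query_id]]
  if (min(d[is.finite(d)]) > threshold + 1e-9) return("no_match")
  if (length(within) > 0 && setequal(within, consp) && all(consp %in% within))
    return("correct")
  if (length(within) == 0) return("no_match")
  sp_in <- species_map[within]
  if (all(sp_in != species_map[query_id])) return("incorrect")
  "ambiguous"
}

# --- unrooted bipartition set of a tree, from scratch -----------------------
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  nt <- length(tips)
  res <- character(0)
  if (tree$Nnode < 2) return(res)
  for (node in (nt + 2):(nt + tree$Nnode)) {
    below <- ape::extract.clade(tree, node)$tip.label
    side <- sort(below)
    other <- sort(setdiff(tips, side))
    key <- if (length(side) <= length(other)) side else other
    if (length(key) >= 2 && length(key) <= nt - 2)
      res <- c(res, paste(key, collapse = "|"))
  }
  unique(res)
}

# alignment with exact variable / informative site counts (17 sequences);
# informative columns carry an 8/9 split, singleton-variant columns one G
constructed_alignment <- function(length, n_informative, n_singleton,
                                  locus, n_seq = 17) {
  mat <- matrix("A", n_seq, length)
  stopifnot(n_informative + n_singleton <= length)
  cols <- seq_len(n_informative + n_singleton)
  for (k in seq_len(n_informative)) mat[1:8, cols[k]] <- "C"
  if (n_singleton > 0)
    for (k in seq_len(n_singleton)) mat[1, cols[n_informative + k]] <- "G"
  make_aln(apply(mat, 1, paste, collapse = ""),
           species = paste0("sp", rep_len(1:4, n_seq)),
           ids = paste0("i", seq_len(n_seq)), locus = locus)
}

outgroup_ids <- function(ds) names(ds$species_map)[
  ds$species_map == tail(sort(unique(ds$species_map)), 1)]
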