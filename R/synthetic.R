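# Forward simulation of multi-locus barcode datasets under the K2P model:
# species ancestors evolve along a species tree, individuals radiate from
# their ancestor on short within-species branches (star phylogeny), optional
# small indels and injected species-specific SNPs complete the dataset.

k2p_transition_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    transition = 0.25 + 0.25 * e1 - 0.5 * e2,
    transversion = 0.25 - 0.25 * e1)  # each of two transversion targets
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence along a branch under the K2P model
#'
#' Exact per-site substitution using the K2P transition probabilities for the
#' branch length (expected substitutions per site) and transition/transversion
#' rate ratio `kappa`; sequence length is preserved. Uses the current RNG
#' state.
#'
#' @param seq Character vector of bases (or a single string).
#' @param branch_length Expected substitutions per site, >= 0.
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return Character vector of bases of the same length.
#' @export
evolve_k2p <- function(seq, branch_length, kappa = 2) {
  if (branch_length < 0) stop("branch length must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  chars <- if (length(seq) == 1 && nchar(seq[1]) > 1) seq_to_chars(seq) else seq
  if (branch_length == 0) return(chars)
  pr <- k2p_transition_probs(branch_length, kappa)
  out <- chars
  u <- stats::runif(length(chars))
  ts <- u >= pr["same"] & u < pr["same"] + pr["transition"]
  tv1 <- u >= pr["same"] + pr["transition"] &
    u < pr["same"] + pr["transition"] + pr["transversion"]
  tv2 <- u >= pr["same"] + pr["transition"] + pr["transversion"]
  out[ts] <- TRANSITION_PARTNER[chars[ts]]
  for (b in BASES) {
    out[tv1 & chars == b] <- TRANSVERSION_PARTNERS[[b]][1]
    out[tv2 & chars == b] <- TRANSVERSION_PARTNERS[[b]][2]
  }
  out
}

#' Simulation configuration for synthetic barcode datasets
#'
#' Defaults emulate a small plant-barcoding study: four species (three close
#' congeners plus one distant outgroup-like taxon) sampled 5/5/5/2 for 17
#' individuals, five loci with realistic aligned lengths, low intra-specific
#' divergence and moderate sister-species divergence, indels confined to the
#' nuclear spacers.
#'
#' @param n_species Number of species.
#' @param individuals_per_species Integer scalar or vector (recycled).
#' @param loci Tibble/data frame with columns `name`, `length`,
#'   `indel_events` (expected indel-event count per locus alignment).
#' @param species_tree Newick string for the species tree (edge lengths, if
#'   present, are expected substitutions per site), or `NULL` for a ladder
#'   tree calibrated from `inter_divergence`.
#' @param kappa Transition/transversion rate ratio.
#' @param inter_divergence Expected K2P distance between sister species
#'   (proportion).
#' @param intra_divergence Expected K2P distance between conspecific
#'   individuals (proportion); must be < `inter_divergence`.
#' @param injected_snps Tibble/data frame with columns `locus`, `position`,
#'   `species`, `state`: species-specific SNPs forced into the data after
#'   evolution.
#' @param species_names Optional species names (default `species1..K`).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 4,
                       individuals_per_species = c(5, 5, 5, 2),
                       loci = default_sim_loci(),
                       species_tree = NULL,
                       kappa = 2,
                       inter_divergence = 0.03,
                       intra_divergence = 0.002,
                       injected_snps = NULL,
                       species_names = NULL,
                       seed = 1) {
  if (intra_divergence < 0 || intra_divergence >= inter_divergence)
    stop("need 0 <= intra_divergence < inter_divergence")
  if (kappa <= 0) stop("kappa must be > 0")
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("name", "length", "indel_events") %in% names(loci)))
  n_ind <- rep_len(individuals_per_species, n_species)
  if (any(n_ind < 1)) stop("each species needs >= 1 individual")
  species_names <- species_names %||% paste0("species", seq_len(n_species))
  if (!is.null(injected_snps)) {
    injected_snps <- tibble::as_tibble(injected_snps)
    stopifnot(all(c("locus", "position", "species", "state") %in%
                    names(injected_snps)))
    for (r in seq_len(nrow(injected_snps))) {
      L <- loci$length[loci$name == injected_snps$locus[r]]
      if (!length(L) || injected_snps$position[r] < 1 ||
          injected_snps$position[r] > L)
        stop("injected SNP outside locus bounds")
    }
  }
  structure(list(
    n_species = n_species, individuals_per_species = n_ind, loci = loci,
    species_tree = species_tree, kappa = kappa,
    inter_divergence = inter_divergence, intra_divergence = intra_divergence,
    injected_snps = injected_snps, species_names = species_names, seed = seed
  ), class = "sim_config")
}

#' Default locus set for the simulator
#'
#' Five loci with the aligned lengths typical of the plant barcoding core and
#' supplementary regions; indel events confined to the nuclear spacers.
#'
#' @return Tibble: `name`, `length`, `indel_events`.
#' @export
default_sim_loci <- function() {
  tibble::tibble(
    name = c("rbcL", "matK", "psbA-trnH", "ITS", "ITS2"),
    length = c(676L, 751L, 380L, 679L, 406L),
    indel_events = c(0, 0, 0, 19, 6)
  )
}

# ladder species tree with all edges inter/2, so sister species are at the
# configured expected divergence and deeper pairs farther
ladder_species_tree <- function(names, inter) {
  if (length(names) == 1)
    return(ape::read.tree(text = paste0("(", names, ":0);")))
  nwk <- names[1]
  for (i in seq(2, length(names)))
    nwk <- paste0("(", nwk, ",", names[i], ")")
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$edge.length <- rep(inter / 2, nrow(tr$edge))
  tr
}

#' Simulate a multi-locus barcode dataset
#'
#' The root sequence of each locus is drawn uniformly over A/C/G/T; species
#' ancestors evolve along the species tree under K2P; individuals branch off
#' their species ancestor on independent branches of length
#' `intra_divergence / 2` (star phylogeny within species). Indels are then
#' applied as maximal gap runs of length 1-3 (truncated-geometric lengths) in
#' randomly chosen individuals, and injected SNPs are forced to be fixed in
#' the target species and absent elsewhere. Fully seeded: the same
#' configuration reproduces byte-identical data.
#'
#' @param config A [sim_config()].
#' @return List: `dataset` (a [barcode_dataset()]) and `truth` (species tree,
#'   configured divergences, injected SNPs, species map).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sp_names <- config$species_names
  tr <- if (is.null(config$species_tree)) {
    ladder_species_tree(sp_names, config$inter_divergence)
  } else {
    t0 <- ape::read.tree(text = config$species_tree)
    if (is.null(t0$edge.length))
      t0$edge.length <- rep(config$inter_divergence / 2, nrow(t0$edge))
    t0
  }
  if (!setequal(tr$tip.label, sp_names))
    sp_names <- tr$tip.label
  n_ind <- rep_len(config$individuals_per_species, length(sp_names))
  ids <- unlist(lapply(seq_along(sp_names), function(i)
    paste0(sp_names[i], "_", seq_len(n_ind[i]))))
  species_map <- stats::setNames(
    rep(sp_names, n_ind), ids)

  alns <- list()
  for (li in seq_len(nrow(config$loci))) {
    L <- config$loci$length[li]
    root <- sample(BASES, L, replace = TRUE)
    ancestors <- evolve_along_tree(tr, root, config$kappa)
    mat <- matrix("", length(ids), L, dimnames = list(ids, NULL))
    for (i in seq_along(sp_names)) {
      anc <- ancestors[[sp_names[i]]]
      for (k in seq_len(n_ind[i])) {
        mat[paste0(sp_names[i], "_", k), ] <-
          evolve_k2p(anc, config$intra_divergence / 2, config$kappa)
      }
    }
    mat <- apply_indels(mat, config$loci$indel_events[li])
    mat <- apply_injected_snps(mat, species_map, config$injected_snps,
                               config$loci$name[li])
    alns[[config$loci$name[li]]] <- locus_alignment(
      seqs = apply(mat, 1, paste, collapse = ""),
      ids = ids, species = unname(species_map[ids]),
      locus = config$loci$name[li]
    )
  }
  list(
    dataset = barcode_dataset(alns),
    truth = list(species_tree = tr, species_map = species_map,
                 intra_divergence = config$intra_divergence,
                 inter_divergence = config$inter_divergence,
                 injected_snps = config$injected_snps, seed = config$seed)
  )
}

evolve_along_tree <- function(tr, root_seq, kappa) {
  tr <- stats::reorder(tr, "cladewise")
  nt <- length(tr$tip.label)
  seqs <- vector("list", nt + tr$Nnode)
  seqs[[nt + 1L]] <- root_seq
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    seqs[[child]] <- evolve_k2p(seqs[[parent]], tr$edge.length[e], kappa)
  }
  stats::setNames(seqs[seq_len(nt)], tr$tip.label)
}

apply_indels <- function(mat, expected_events) {
  if (expected_events <= 0) return(mat)
  n_events <- stats::rpois(1, expected_events)
  if (n_events == 0) return(mat)
  L <- ncol(mat)
  for (k in seq_len(n_events)) {
    len <- sample(1:3, 1, prob = c(4, 2, 1) / 7)
    start <- sample.int(L - len + 1L, 1)
    row <- sample.int(nrow(mat), 1)
    mat[row, start:(start + len - 1L)] <- "-"
  }
  mat
}

apply_injected_snps <- function(mat, species_map, snps, locus) {
  if (is.null(snps)) return(mat)
  snps <- snps[snps$locus == locus, , drop = FALSE]
  for (r in seq_len(nrow(snps))) {
    p <- snps$position[r]; s <- snps$species[r]; state <- snps$state[r]
    members <- names(species_map)[species_map == s]
    others <- setdiff(rownames(mat), members)
    if (any(mat[members, p] == "-"))
      stop("injected SNP position overlaps a gap in the target species")
    other_bases <- mat[others, p][is_unambiguous(mat[others, p])]
    majority <- names(sort(table(other_bases), decreasing = TRUE))
    if (length(majority) && majority[1] == state)
      stop("injected SNP state equals the non-target consensus at position ", p)
    mat[members, p] <- state
    clash <- others[mat[others, p] == state]
    if (length(clash)) mat[clash, p] <- majority[1]
  }
  mat
}
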