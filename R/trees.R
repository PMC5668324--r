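# Tree inference and parsimony diagnostics: neighbour joining on K2P
# distances, Fitch parsimony with branch-and-bound or heuristic search,
# consistency/retention indices, strict consensus, bootstrap, monophyly.

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbour joining with negative branch lengths clamped to zero,
#' optionally rooted on an outgroup.
#'
#' @param dm A `k2p_dist` with all entries defined.
#' @param outgroup Optional character vector of outgroup tip ids.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  if (any(!is.finite(dm$d)))
    stop("distance matrix has undefined (saturated) entries")
  tr <- ape::nj(dm$d)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% tr$tip.label)) stop("outgroup tips absent from tree")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

# alignment columns as bitmask matrix (tips x columns); gaps and N are
# missing data (all four states), ambiguity codes are partial state sets
alignment_bits <- function(aln) {
  bits <- apply(aln$mat, c(1, 2), function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (is.null(s)) 15L else sum(BASE_BITS[s])
  })
  rownames(bits) <- aln$ids
  bits
}

#' Fitch parsimony length of a tree
#'
#' Small-parsimony score summed over columns; gaps and ambiguity codes carry
#' no cost (missing data / partial state sets). Multifurcating trees are
#' scored on an arbitrary binary resolution (valid for binary search trees;
#' consensus polytomies get an upper-bound score).
#'
#' @param tree A `phylo` whose tip labels match the alignment ids.
#' @param aln A `locus_alignment`.
#' @param per_column If `TRUE`, return the per-column step vector.
#' @return Total steps (or integer vector when `per_column`).
#' @export
fitch_length <- function(tree, aln, per_column = FALSE) {
  if (!setequal(tree$tip.label, aln$ids))
    stop("tree tips do not match alignment ids")
  tr <- tree
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
  tr <- stats::reorder(tr, "postorder")
  bits <- alignment_bits(aln)
  nt <- length(tr$tip.label)
  C <- ncol(bits)
  S <- matrix(0L, nt + tr$Nnode, C)
  S[seq_len(nt), ] <- bits[tr$tip.label, , drop = FALSE]
  steps <- integer(C)
  parents <- unique(tr$edge[, 1])
  for (p in parents) {
    ch <- tr$edge[tr$edge[, 1] == p, 2]
    acc <- S[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(acc, S[c2, ])
      empty <- inter == 0L
      steps[empty] <- steps[empty] + 1L
      acc <- ifelse(empty, bitwOr(acc, S[c2, ]), inter)
    }
    S[p, ] <- acc
  }
  if (per_column) steps else sum(steps)
}

#' Consistency, retention and rescaled consistency indices
#'
#' Per column, the minimum steps `m = (distinct unambiguous states) - 1`, the
#' maximum steps on a star tree `g = (taxa with data) - (frequency of the
#' most common state)`, and the observed Fitch steps `l` are accumulated into
#' `CI = M/L`, `RI = (G - L)/(G - M)` and `RC = CI * RI`. Both conventions
#' are reported: over all (equivalently all variable) characters, and over
#' parsimony-informative characters only.
#'
#' @param tree A `phylo`.
#' @param aln A `locus_alignment`.
#' @return Tibble with rows `scope = c("all", "informative")` and columns
#'   `ci`, `ri`, `rc`, `min_steps`, `max_steps`, `length`. Indices are `NA`
#'   (flagged undefined) when `G = M`.
#' @export
consistency_indices <- function(tree, aln) {
  l <- fitch_length(tree, aln, per_column = TRUE)
  C <- ncol(aln$mat)
  m <- g <- integer(C)
  informative <- logical(C)
  for (j in seq_len(C)) {
    chars <- aln$mat[, j]
    base <- chars[is_unambiguous(chars)]
    tab <- table(base)
    m[j] <- max(0L, length(tab) - 1L)
    g[j] <- if (length(tab)) length(base) - max(tab) else 0L
    informative[j] <- length(tab) >= 2 && sum(tab >= 2) >= 2
  }
  one_scope <- function(keep, label) {
    M <- sum(m[keep]); G <- sum(g[keep]); L <- sum(l[keep])
    if (G == M) {
      ci <- if (L == 0) NA_real_ else M / L
      ri <- NA_real_
    } else {
      ci <- M / L
      ri <- (G - L) / (G - M)
    }
    tibble::tibble(scope = label, ci = ci, ri = ri, rc = ci * ri,
                   min_steps = M, max_steps = G, length = L)
  }
  dplyr::bind_rows(one_scope(rep(TRUE, C), "all"),
                   one_scope(informative, "informative"))
}

aln_phyDat <- function(aln) {
  phangorn::phyDat(aln$mat, type = "DNA")
}

#' Maximum-parsimony tree search
#'
#' Equal-weights Fitch parsimony with gaps as missing data. `"bnb"` is exact
#' branch and bound (default up to 12 taxa; refused above 16 unless
#' `force = TRUE`); `"hillclimb"` runs seeded random-addition starting trees
#' with SPR branch swapping to a local optimum, over `replicates` starts.
#' All equally-best trees are retained up to `max_trees`.
#'
#' @param aln A `locus_alignment` with >= 4 taxa.
#' @param strategy `"auto"`, `"bnb"` or `"hillclimb"`.
#' @param seed Integer seed for random-addition order and tie-breaking.
#' @param replicates Hill-climb restarts.
#' @param max_trees Cap on retained equally-best trees.
#' @param force Allow branch and bound beyond 16 taxa.
#' @return A `parsimony_result`: `trees` (multiPhylo of best trees),
#'   `consensus` (their strict consensus), `length` (steps), `ci`, `ri`, `rc`
#'   (all-characters convention), `indices` (both conventions, see
#'   [consistency_indices()]), `n_characters`, `n_informative`, `strategy`.
#' @export
mp_search <- function(aln, strategy = c("auto", "bnb", "hillclimb"),
                      seed = 1, replicates = 10, max_trees = 100,
                      force = FALSE) {
  strategy <- match.arg(strategy)
  n <- n_seq(aln)
  if (n < 4) stop("need at least four taxa")
  if (strategy == "auto") strategy <- if (n <= 12) "bnb" else "hillclimb"
  if (strategy == "bnb" && n > 16 && !force)
    stop("branch and bound refused for > 16 taxa; use force = TRUE or hillclimb")
  pd <- aln_phyDat(aln)
  set.seed(seed)
  if (strategy == "bnb") {
    trees <- phangorn::bab(pd, trace = 0)
  } else {
    found <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      start <- phangorn::random.addition(pd)
      found[[r]] <- phangorn::optim.parsimony(
        start, pd, method = "fitch", rearrangements = "SPR", trace = 0)
    }
    lens <- vapply(found, fitch_length, numeric(1), aln = aln)
    trees <- found[lens == min(lens)]
    class(trees) <- "multiPhylo"
    trees <- unique(trees)
  }
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) > max_trees) trees <- trees[seq_len(max_trees)]
  best <- trees[[1]]
  len <- fitch_length(best, aln)
  idx <- consistency_indices(best, aln)
  stats <- alignment_stats(aln)
  structure(list(
    trees = trees,
    consensus = if (length(trees) > 1) strict_consensus(trees) else best,
    length = len,
    ci = idx$ci[idx$scope == "all"],
    ri = idx$ri[idx$scope == "all"],
    rc = idx$rc[idx$scope == "all"],
    indices = idx,
    n_characters = ncol(aln$mat),
    n_informative = stats$informative_sites,
    strategy = strategy
  ), class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> ", length(x$trees), " best tree(s), length = ",
      x$length, " steps\n  CI = ", round(x$ci, 4), ", RI = ", round(x$ri, 4),
      ", RC = ", round(x$rc, 4), " (", x$n_informative, "/", x$n_characters,
      " informative characters; ", x$strategy, " search)\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a parsimony search
#' @param x A `parsimony_result`.
#' @param ... Unused.
#' @return Tibble: `n_trees`, `length`, `ci`, `ri`, `rc`, `n_characters`,
#'   `n_informative`, `strategy`.
#' @export
glance.parsimony_result <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees), length = x$length,
                 ci = x$ci, ri = x$ri, rc = x$rc,
                 n_characters = x$n_characters,
                 n_informative = x$n_informative, strategy = x$strategy)
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) on identical leaf sets.
#' @return A `phylo`, possibly with polytomies.
#' @export
strict_consensus <- function(trees) {
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  tips <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tips, identical, logical(1), tips[[1]])))
    stop("trees have different leaf sets")
  class(trees) <- "multiPhylo"
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1)
}

#' Bootstrap support for a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' pseudo-replicate with the chosen builder, and reports for each internal
#' edge of the original tree the percentage of replicates containing that
#' bipartition (stored in `node.label`).
#'
#' @param aln A `locus_alignment`.
#' @param builder `"nj"` (K2P + neighbour joining) or `"mp"` (one seeded
#'   random-addition + SPR parsimony search per replicate).
#' @param n_replicates Number of pseudo-replicates (>= 1).
#' @param seed Integer seed.
#' @param tree Optional original tree; default built from the full alignment
#'   with the same builder.
#' @param outgroup Optional outgroup for the returned tree.
#' @return The original tree with `node.label` holding support percentages.
#' @export
bootstrap_support <- function(aln, builder = c("nj", "mp"),
                              n_replicates = 1000, seed = 1, tree = NULL,
                              outgroup = NULL) {
  builder <- match.arg(builder)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  build <- function(a) {
    if (builder == "nj") nj_tree(k2p_matrix(a))
    else {
      pd <- aln_phyDat(a)
      phangorn::optim.parsimony(phangorn::random.addition(pd), pd,
                                method = "fitch", rearrangements = "SPR",
                                trace = 0)
    }
  }
  set.seed(seed)
  if (is.null(tree)) tree <- build(aln)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(aln$mat), replace = TRUE)
    ra <- aln
    ra$mat <- aln$mat[, cols, drop = FALSE]
    reps[[r]] <- build(ra)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- round(100 * counts / n_replicates, 1)
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tree
}

#' Is a species monophyletic on a tree?
#'
#' Tests whether the species' individuals form a clade on the
#' outgroup-rooted tree. Singleton species are monophyletic by definition.
#'
#' @param tree A `phylo`.
#' @param species_map Named species vector over tip ids.
#' @param species Species name to test.
#' @param outgroup Optional outgroup tips used to root the tree first.
#' @return Logical flag.
#' @export
is_species_monophyletic <- function(tree, species_map, species,
                                    outgroup = NULL) {
  tips <- names(species_map)[species_map == species]
  tips <- intersect(tips, tree$tip.label)
  if (!length(tips)) stop("species '", species, "' absent from tree")
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% tree$tip.label)) stop("outgroup absent from tree")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (length(tips) == 1) return(TRUE)
  ape::is.monophyletic(tree, tips)
}
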