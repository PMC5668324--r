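additive_dm <- function() {
  # quartet ((a:1,b:2):1,(c:3,d:4)) scaled to proportions (x 0.01)
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  d <- ape::cophenetic.phylo(tr) * 0.01
  structure(list(ids = rownames(d), d = d,
                 sites = matrix(100L, 4, 4, dimnames = dimnames(d))),
            class = "k2p_dist")
}

test_that("NJ recovers an additive tree exactly, with clamped branches", {
  dm <- additive_dm()
  tr <- nj_tree(dm)
  want <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want)), 0,
               ignore_attr = TRUE)
  # total length of an additive tree is preserved
  expect_equal(sum(tr$edge.length), 0.01 * (1 + 2 + 1 + 3 + 4))
  expect_true(all(tr$edge.length >= 0))

  # perturbed matrix never yields negative output lengths
  withr::local_seed(5)
  dm$d <- dm$d + matrix(runif(16, 0, 0.002), 4, 4)
  dm$d <- (dm$d + t(dm$d)) / 2; diag(dm$d) <- 0
  expect_true(all(nj_tree(dm)$edge.length >= 0))

  dm$d[1, 2] <- dm$d[2, 1] <- Inf
  expect_error(nj_tree(dm), "undefined")

  expect_error(nj_tree(additive_dm(), outgroup = "zz"), "outgroup")
  rooted <- nj_tree(additive_dm(), outgroup = "d")
  expect_true(ape::is.rooted(rooted))
})

test_that("Fitch length matches hand values and is rooting-invariant", {
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  aln <- make_aln(c("A", "A", "G", "G"), c("s1", "s1", "s2", "s2"),
                  ids = paste0("t", 1:4))
  expect_equal(fitch_length(tr, aln), 1)
  # invariant column adds nothing
  aln2 <- make_aln(c("AC", "AC", "GC", "GC"), c("s1", "s1", "s2", "s2"),
                   ids = paste0("t", 1:4))
  expect_equal(fitch_length(tr, aln2), 1)
  # alternating pattern on the comb costs 2
  aln3 <- make_aln(c("A", "G", "A", "G"), c("s1", "s1", "s2", "s2"),
                   ids = paste0("t", 1:4))
  expect_equal(fitch_length(tr, aln3), 2)
  # rooting invariance
  expect_equal(fitch_length(ape::root(tr, "t3", resolve.root = TRUE), aln3),
               fitch_length(tr, aln3))
  expect_error(fitch_length(tr, make_aln(c("A", "A"), c("s1", "s2"))),
               "match")
})

test_that("Fitch length equals exhaustive state enumeration on 5 taxa", {
  withr::local_seed(41)
  for (rep in 1:6) {
    aln <- random_alignment(5, 6, gap_prob = 0.1)
    aln$ids <- paste0("t", 1:5)
    rownames(aln$mat) <- aln$ids
    tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
    expect_equal(fitch_length(tr, aln), oracle_fitch(tr, aln),
                 info = paste("rep", rep))
  }
})

test_that("branch and bound equals all-topology enumeration on 6 taxa", {
  withr::local_seed(19)
  sim <- simulate_dataset(sim_config(
    n_species = 6, individuals_per_species = 1,
    loci = data.frame(name = "l1", length = 40, indel_events = 0),
    inter_divergence = 0.2, intra_divergence = 0.01, seed = 77))
  aln <- sim$dataset$loci$l1
  res <- mp_search(aln, strategy = "bnb")
  all_tr <- phangorn::allTrees(6, rooted = FALSE, tip.label = aln$ids)
  lens <- vapply(all_tr, fitch_length, numeric(1), aln = aln)
  expect_equal(res$length, min(lens))
  # every retained tree attains the optimum
  for (i in seq_along(res$trees))
    expect_equal(fitch_length(res$trees[[i]], aln), min(lens))
  # hill climbing reaches the same optimum
  res2 <- mp_search(aln, strategy = "hillclimb", seed = 3, replicates = 5)
  expect_equal(res2$length, res$length)
})

test_that("alignments without variable sites have zero-length MP trees", {
  aln <- make_aln(rep("ACGTAC", 4), paste0("s", 1:4))
  res <- mp_search(aln, strategy = "bnb")
  expect_equal(res$length, 0)
  expect_error(mp_search(random_alignment(17, 10), strategy = "bnb"),
               "refused")
})

test_that("consistency indices follow the M/L and (G-L)/(G-M) conventions", {
  # 5-taxon hand example, one homoplastic column
  # col1: A A G G G on ((t1,t2),(t3,(t4,t5))): m=1, g=2, fitch=1
  # col2: A G A G A: m=1, g=2, fitch=2 (homoplasy)
  tr <- ape::read.tree(text = "((t1,t2),(t3,(t4,t5)));")
  aln <- make_aln(c("AA", "AG", "GA", "GG", "GA"), paste0("s", 1:5),
                  ids = paste0("t", 1:5))
  idx <- consistency_indices(tr, aln)
  all_row <- idx[idx$scope == "all", ]
  expect_equal(all_row$min_steps, 2L)
  expect_equal(all_row$max_steps, 4L)
  expect_equal(all_row$length, 3L)
  expect_equal(all_row$ci, 2 / 3)
  expect_equal(all_row$ri, (4 - 3) / (4 - 2))
  expect_equal(all_row$rc, all_row$ci * all_row$ri)

  # no homoplasy: CI = 1
  aln2 <- make_aln(c("A", "A", "G", "G", "G"), paste0("s", 1:5),
                   ids = paste0("t", 1:5))
  expect_equal(consistency_indices(tr, aln2)$ci[1], 1)

  # agreement with an established implementation on random data
  withr::local_seed(29)
  aln3 <- random_alignment(6, 30)
  aln3$ids <- paste0("t", 1:6); rownames(aln3$mat) <- aln3$ids
  tr3 <- ape::rtree(6, tip.label = paste0("t", 1:6))
  got <- consistency_indices(tr3, aln3)[1, ]
  pd <- phangorn::phyDat(aln3$mat, type = "DNA")
  expect_equal(got$ci, phangorn::CI(tr3, pd), tolerance = 1e-12)
  expect_equal(got$ri, phangorn::RI(tr3, pd), tolerance = 1e-12)
})

test_that("tree length is bounded by the character min and max step sums", {
  withr::local_seed(37)
  for (rep in 1:5) {
    aln <- random_alignment(6, 25)
    aln$ids <- paste0("t", 1:6); rownames(aln$mat) <- aln$ids
    tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
    idx <- consistency_indices(tr, aln)[1, ]
    expect_gte(idx$length, idx$min_steps)
    expect_lte(idx$length, idx$max_steps)
    expect_true(idx$ci > 0 && idx$ci <= 1)
    expect_true(idx$ri >= 0 && idx$ri <= 1)
    expect_equal(idx$rc, idx$ci * idx$ri)
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_equal(ape::dist.topo(strict_consensus(c(t1, t1)), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  # no shared internal bipartition: star
  t2 <- ape::read.tree(text = "((a,c),(b,(d,e)));")
  t3 <- ape::read.tree(text = "((a,d),(c,(b,e)));")
  star <- strict_consensus(c(t2, t3))
  expect_equal(length(oracle_bipartitions(star)), 0)
  # oracle: intersection of bipartition sets
  withr::local_seed(47)
  trees <- lapply(1:3, function(i) ape::rtree(7, tip.label = letters[1:7]))
  class(trees) <- "multiPhylo"
  cons <- strict_consensus(trees)
  shared <- Reduce(intersect, lapply(trees, oracle_bipartitions))
  expect_setequal(oracle_bipartitions(cons), shared)
  expect_error(strict_consensus(list(t1, ape::rtree(4))), "leaf sets")
})

test_that("bootstrap supports are seeded, bounded and degenerate at n = 1", {
  sim <- simulate_dataset(sim_config(
    n_species = 4, individuals_per_species = 2,
    loci = data.frame(name = "l1", length = 300, indel_events = 0),
    inter_divergence = 0.08, intra_divergence = 0.004, seed = 12))
  aln <- sim$dataset$loci$l1
  b1 <- bootstrap_support(aln, "nj", n_replicates = 25, seed = 6)
  b2 <- bootstrap_support(aln, "nj", n_replicates = 25, seed = 6)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))
  b3 <- bootstrap_support(aln, "nj", n_replicates = 1, seed = 2)
  expect_true(all(b3$node.label %in% c(0, 100)))
  expect_error(bootstrap_support(aln, "nj", n_replicates = 0), ">= 1")
})

test_that("species monophyly is read off the outgroup-rooted tree", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),o1);")
  sm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", o1 = "O")
  expect_true(is_species_monophyletic(tr, sm, "A", outgroup = "o1"))
  expect_true(is_species_monophyletic(tr, sm, "O", outgroup = "o1"))
  # interleaved species on a comb
  tr2 <- ape::read.tree(text = "(a1,(b1,(a2,(b2,o1))));")
  expect_false(is_species_monophyletic(tr2, sm, "A", outgroup = "o1"))
  expect_error(is_species_monophyletic(tr2, sm, "Z"), "absent")
})
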