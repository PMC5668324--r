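test_that("pure diagnostic characters are found and verified by recount", {
  aln <- make_aln(c("ACGTA", "ACGTA", "ACCTA", "ACCTG"),
                  species = c("X", "X", "Y", "Y"))
  dc <- find_diagnostic_characters(aln, "X")
  # column 3 G fixed in X, C in Y; column 5 not diagnostic (Y varies A/G,
  # one Y shares A with X)
  expect_true(any(dc$position == 3 & dc$state == "G"))
  expect_false(any(dc$position == 5))
  # direct recount oracle for every emitted character
  for (r in seq_len(nrow(dc))) {
    members <- aln$mat[aln$species == "X", dc$position[r]]
    others <- aln$mat[aln$species != "X", dc$position[r]]
    expect_true(all(members == dc$state[r]))
    expect_false(any(others == dc$state[r]))
  }
  # identical columns everywhere: no diagnostics
  expect_equal(nrow(find_diagnostic_characters(
    make_aln(rep("AAAA", 4), c("X", "X", "Y", "Y")))), 0)
  expect_error(find_diagnostic_characters(aln, "Z"), "unknown species")
})

test_that("member gaps or shareable ambiguity codes disqualify a column", {
  aln <- make_aln(c("A-G", "AAG", "AAR", "AAC"),
                  species = c("X", "X", "Y", "Y"))
  dc <- find_diagnostic_characters(aln, "X")
  expect_false(any(dc$position == 1))  # member gap
  expect_false(any(dc$position == 3))  # R = A/G could include the G state
})

test_that("diagnostic scan agrees with an exhaustive column loop", {
  withr::local_seed(23)
  for (rep in 1:8) {
    aln <- random_alignment(7, 40, n_species = 3, gap_prob = 0.05)
    sp <- aln$species
    for (s in unique(sp)) {
      got <- find_diagnostic_characters(aln, s)
      want <- integer(0)
      for (j in seq_len(ncol(aln$mat))) {
        mc <- aln$mat[sp == s, j]
        oc <- aln$mat[sp != s, j]
        if (all(mc %in% c("A", "C", "G", "T")) && length(unique(mc)) == 1 &&
            !any(oc == mc[1]) &&
            !any(vapply(oc, function(ch)
              ch != "-" && mc[1] %in% (iupac_match_table[[ch]] %||% ""),
              logical(1))))
          want <- c(want, j)
      }
      expect_equal(got$position, want, info = paste("rep", rep, s))
    }
  }
})

test_that("simulator-injected SNPs are recovered exactly", {
  snp <- data.frame(locus = "m", position = 230, species = "species2",
                    state = "C")
  sim <- simulate_dataset(sim_config(
    n_species = 3, individuals_per_species = 4,
    loci = data.frame(name = "m", length = 500, indel_events = 0),
    inter_divergence = 0.04, intra_divergence = 0.002,
    injected_snps = snp, seed = 99))
  dc <- find_diagnostic_characters(sim$dataset$loci$m, "species2")
  expect_true(any(dc$position == 230 & dc$state == "C"))
})

test_that("rule induction finds single-character rules and perfect test rates", {
  # species differ at exactly one fixed column
  seqs <- c(rep("ACGTACGTAA", 3), rep("ACGTACGTCA", 3))
  aln <- make_aln(seqs, rep(c("X", "Y"), each = 3))
  r <- induce_rules(aln, seed = 4)
  expect_equal(nrow(r$rules), 2)
  expect_equal(r$rules$n_conjuncts, c(1L, 1L))
  expect_equal(sort(unique(tidy(r)$position)), 9L)
  expect_true(all(r$rules$train_coverage == 1))
  expect_true(all(r$rules$train_fpr == 0))
  expect_equal(r$rates$correct_pct, 100)
})

test_that("induced conjunctions are minimal on small column sets", {
  withr::local_seed(53)
  for (rep in 1:10) {
    # 6-column alignments over two states per column
    mat <- matrix(sample(c("A", "G"), 8 * 6, replace = TRUE), 8, 6)
    sp <- rep(c("X", "Y"), each = 4)
    aln <- make_aln(apply(mat, 1, paste, collapse = ""), sp)
    for (s in c("X", "Y")) {
      members <- mat[sp == s, , drop = FALSE]
      others <- mat[sp != s, , drop = FALSE]
      cand <- which(apply(members, 2, function(x) length(unique(x)) == 1))
      # brute force: smallest conjunction subset with zero false positives
      best <- Inf
      if (length(cand)) {
        for (k in seq_along(cand)) {
          for (idx in utils::combn(cand, k, simplify = FALSE)) {
            fp <- sum(apply(others, 1, function(row)
              all(row[idx] == members[1, idx])))
            if (fp == 0) { best <- min(best, k); break }
          }
          if (is.finite(best)) break
        }
      }
      got <- barcodeval:::induce_rule_for_species(mat, sp, s)
      if (is.infinite(best)) {
        expect_null(got)
      } else {
        expect_equal(nrow(got), best, info = paste("rep", rep, s))
        fp <- sum(apply(others, 1, function(row)
          all(row[got$position] == got$state)))
        expect_equal(fp, 0)
      }
    }
  }
})

test_that("singleton species are excluded from slicing with a warning", {
  seqs <- c(rep("AAAA", 3), rep("CCCC", 3), "GGGG")
  aln <- make_aln(seqs, c("X", "X", "X", "Y", "Y", "Y", "Z"))
  expect_warning(r <- induce_rules(aln, seed = 2), "single member.*Z")
  expect_false("Z" %in% r$rules$species)
})

test_that("restriction scanning matches hand and naive oracles", {
  # BstXI CCANNNNNNTGG inside padding
  hits <- scan_restriction_sites("TTCCATTTTTTTGGAA", "CCANNNNNNTGG")
  expect_true(all(hits$position == 3))
  # palindromic site is found at the same position on both strands
  expect_setequal(hits$strand, c("+", "-"))
  # poly-A sequence has no site for any enzyme lacking an A-only site
  for (s in restriction_enzymes()$site)
    expect_equal(nrow(scan_restriction_sites(strrep("A", 30), s)), 0)
  expect_error(scan_restriction_sites("AC-GT", "CCTC"), "gap")

  withr::local_seed(61)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
    for (k in seq_len(nrow(restriction_enzymes()))) {
      site <- restriction_enzymes()$site[k]
      got <- scan_restriction_sites(seq, site)
      want <- oracle_scan(seq, site)
      expect_equal(got$position[got$strand == "+"], want$fwd)
      expect_equal(got$position[got$strand == "-"], want$rev)
    }
  }
})

test_that("overlapping sites are all reported", {
  got <- scan_restriction_sites("CCTCCTCC", "CCTC")
  expect_equal(got$position[got$strand == "+"], c(1L, 4L))
})

test_that("CAPS design emits assays only where digestion differs", {
  # diagnostic C at column 7 completes an MnlI site (CCTC) in X only
  x <- "AAAACCTCAAAA"; y <- "AAAACATCAAAA"
  aln <- make_aln(c(x, x, y, y), c("X", "X", "Y", "Y"))
  caps <- design_caps(aln, restriction_enzymes())
  mnl <- caps[caps$enzyme == "MnlI", ]
  expect_true(any(mnl$species == "X" & mnl$cuts_target))
  # the paired diagnostic state in Y must show the opposite digest
  yrow <- caps[caps$species == "Y" & caps$enzyme == "MnlI", ]
  if (nrow(yrow)) expect_false(any(yrow$cuts_target))

  # SNP far from any recognition site: no assay
  a2 <- make_aln(c("AAAAAAAAGAAA", "AAAAAAAAGAAA",
                   "AAAAAAAATAAA", "AAAAAAAATAAA"),
                 c("X", "X", "Y", "Y"))
  expect_equal(nrow(design_caps(a2, restriction_enzymes())), 0)
})

test_that("enzyme panels round-trip through TSV and are validated", {
  f <- withr::local_tempfile()
  utils::write.table(restriction_enzymes(), f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_equal(read_enzyme_panel(f), restriction_enzymes())
  f2 <- withr::local_tempfile(lines = c("enzyme\tsite", "Bad\tCCX"))
  expect_error(read_enzyme_panel(f2), "IUPAC")
})
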