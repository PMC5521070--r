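tree4 <- ape::read.tree(text = "((ref:0.2,sp2:0.2):0.1,(sp3:0.2,sp4:0.2):0.1);")

test_that("alignment preprocessing splices reference gaps and masks stops", {
  aln <- preprocess_alignment(
    c(ref = "ATG-AAACCC", oth = "ATGCAAACCC"), "ref"
  )
  expect_equal(unname(aln$rows["ref"]), "ATGAAACCC")
  expect_equal(unname(aln$rows["oth"]), "ATGAAACCC")

  aln2 <- preprocess_alignment(
    c(ref = "ATGAAACCC", oth = "ATGTAACCC"), "ref"
  )
  expect_equal(unname(aln2$rows["oth"]), "ATG---CCC")

  clean <- c(ref = "ATGAAA", oth = "ATGGGG")
  expect_equal(preprocess_alignment(clean, "ref")$rows, clean)
  expect_error(preprocess_alignment(c(ref = "AT", oth = "AT"), "ref"),
               "complete reference codon")
})

test_that("tree pruning removes one of the closest pair and preserves distances", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.06):0.4,(C:0.3,D:0.31):0.2);")
  seen <- character(0)
  for (s in 1:30) {
    pruned <- prune_tree(tr, max_leaves = 3, seed = s)
    expect_equal(length(pruned$tip.label), 3L)
    gone <- setdiff(tr$tip.label, pruned$tip.label)
    expect_true(gone %in% c("A", "B"))  # the closest pair
    seen <- union(seen, gone)
    d0 <- ape::cophenetic.phylo(tr)
    d1 <- ape::cophenetic.phylo(pruned)
    keep <- pruned$tip.label
    expect_equal(d1[keep, keep], d0[keep, keep], tolerance = 1e-10)
  }
  expect_setequal(seen, c("A", "B"))  # both outcomes occur across seeds

  expect_identical(prune_tree(tr, max_leaves = 10), tr)
  protected <- prune_tree(tr, max_leaves = 3, keep = "A", seed = 1)
  expect_true("A" %in% protected$tip.label)
})

test_that("identical rows give a zero log-likelihood difference", {
  cds <- paste(rep("GCT", 30), collapse = "")
  aln <- structure(list(reference_id = "ref",
                        rows = c(ref = cds, sp2 = cds, sp3 = cds, sp4 = cds)),
                   class = "codon_alignment")
  res <- dnds_loglik_test(aln, tree4)
  expect_lt(res$loglik_diff, 0.01)
})

test_that("synonymous-only divergence drives omega down, matching a grid scan", {
  # two species differing at a handful of synonymous third positions
  set.seed(40)
  ref_cod <- rep(c("CTA", "GGA", "CCA", "TCA", "GTA", "AAA"), 5)
  oth_cod <- ref_cod
  # third-position transitions only: GGA->GGG (Gly), CTA->CTG (Leu),
  # TCA->TCG (Ser)
  oth_cod[c(2, 7, 13, 19, 25, 28)] <- c("GGG", "CTG", "CTG", "CTG", "CTG", "TCG")
  aln <- structure(list(reference_id = "ref",
                        rows = c(ref = paste(ref_cod, collapse = ""),
                                 oth = paste(oth_cod, collapse = ""))),
                   class = "codon_alignment")
  tr2 <- ape::read.tree(text = "(ref:0.3,oth:0.3);")
  res <- dnds_loglik_test(aln, tr2)
  expect_lt(res$omega_hat, 0.1)
  expect_gt(res$loglik_diff, 1)
  # fine-grid profile over omega (scale profiled per grid point) cannot beat
  # the reported free-model likelihood by more than the search tolerance
  grid <- exp(seq(log(1e-3), log(5), length.out = 60))
  prof <- vapply(grid, function(w) {
    max(vapply(exp(seq(log(0.01), log(5), length.out = 40)), function(s) {
      smorfselect:::codon_loglik(aln, tr2, omega = w, scale = s)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(prof) - res$lnl_free, 0.1)
  expect_lt(grid[which.max(prof)], 0.1)
})

test_that("pruning likelihood equals direct summation over ancestral states", {
  set.seed(41)
  tr3 <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  codons <- smorfselect:::SENSE_CODONS
  rows <- c(A = paste(sample(codons, 4, TRUE), collapse = ""),
            B = paste(sample(codons, 4, TRUE), collapse = ""),
            C = paste(sample(codons, 4, TRUE), collapse = ""))
  aln <- structure(list(reference_id = "A", rows = rows),
                   class = "codon_alignment")
  for (omega in c(0.3, 1, 2.5)) {
    got <- smorfselect:::codon_loglik(aln, tr3, omega = omega, scale = 1)
    # independent route: unrooted 3-leaf tree has one internal node; sum
    # P(anc) * prod_tips P(anc -> tip) per site
    pi <- smorfselect:::f1x4_frequencies(rows)
    P <- lapply(c(A = 0.2, B = 0.3, C = 0.4 + 0.1), function(t) {
      smorfselect:::codon_pmat(pi, kappa = 2, omega = omega, t = t)
    })
    want <- 0
    idx <- lapply(rows, function(r) {
      match(substring(r, c(1, 4, 7, 10), c(3, 6, 9, 12)), codons)
    })
    for (site in 1:4) {
      like <- sum(pi * P[["A"]][, idx$A[site]] * P[["B"]][, idx$B[site]] *
                    P[["C"]][, idx$C[site]])
      want <- want + log(like)
    }
    expect_equal(got, want, tolerance = 1e-8, info = paste("omega", omega))
  }
})

test_that("the statistic ignores row order and all-gap species", {
  set.seed(42)
  cds <- paste(sample(smorfselect:::SENSE_CODONS, 20, TRUE), collapse = "")
  aln <- simulate_ortholog_alignment(cds, tree4, "ref", omega = 0.5, seed = 9)
  base <- dnds_loglik_test(aln, tree4)
  shuffled <- aln
  shuffled$rows <- aln$rows[c(3, 1, 4, 2)]
  expect_equal(dnds_loglik_test(shuffled, tree4)$loglik_diff,
               base$loglik_diff, tolerance = 1e-6)

  tree5 <- ape::read.tree(
    text = "(((ref:0.2,sp2:0.2):0.1,(sp3:0.2,sp4:0.2):0.1):0.05,sp5:0.3);")
  gappy <- aln
  gappy$rows <- c(aln$rows, sp5 = strrep("-", nchar(cds)))
  expect_equal(dnds_loglik_test(gappy, tree5)$loglik_diff,
               base$loglik_diff, tolerance = 0.05)
})

test_that("omega is recovered from data simulated under purifying selection", {
  tree8 <- ape::read.tree(text = paste0(
    "(((ref:0.15,s2:0.15):0.1,(s3:0.15,s4:0.15):0.1):0.05,",
    "((s5:0.15,s6:0.15):0.1,(s7:0.15,s8:0.15):0.1):0.05);"))
  set.seed(43)
  cds <- paste(sample(smorfselect:::SENSE_CODONS, 60, TRUE), collapse = "")
  om <- vapply(1:25, function(i) {
    aln <- simulate_ortholog_alignment(cds, tree8, "ref", omega = 0.2,
                                       seed = 1000 + i)
    dnds_loglik_test(aln, tree8)$omega_hat
  }, numeric(1))
  expect_gt(median(om), 0.1)
  expect_lt(median(om), 0.35)
})

test_that("degenerate alignments return the missing-value marker", {
  aln <- structure(list(reference_id = "ref",
                        rows = c(ref = "ATGAAA")), class = "codon_alignment")
  res <- dnds_loglik_test(aln, tree4)
  expect_true(is.na(res$loglik_diff))
})
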