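test_that("sequence shuffles preserve composition and are seed-reproducible", {
  expect_equal(shuffle_sequence("AAAA", 3), rep("AAAA", 3))
  s <- "ACGTACGGTTAC"
  sh <- shuffle_sequence(s, 10, seed = 4)
  for (x in sh) {
    expect_equal(sort(strsplit(x, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  expect_identical(sh, shuffle_sequence(s, 10, seed = 4))
})

test_that("shuffled sRNAs without stop/start potential yield zero expected ORFs", {
  g <- mk_genome(strrep("AC", 100))  # no G or T: no ATG, no stop
  srna <- mk_feature(10, 110, "+", "srna", "s1")
  out <- expected_orf_count(srna, g, n_shuffles = 10, seed = 2)
  expect_true(all(out$expected == 0))
  expect_true(all(out$hi - out$lo == 0))
  expect_true(all(out$observed == 0))
})

test_that("observed ORF counts of random sRNAs fall inside the shuffle CI", {
  set.seed(12)
  g <- mk_genome(random_seq(4000))
  srnas <- dplyr::bind_rows(lapply(0:11, function(i) {
    mk_feature(i * 320, i * 320 + 300, "+", "srna", paste0("s", i))
  }))
  out <- expected_orf_count(srnas, g, n_shuffles = 60,
                            bins = c(10, 20, 35, 51), seed = 5)
  # random sequence is its own null: totals agree within the summed CI
  expect_lt(abs(sum(out$observed) - sum(out$expected)),
            1.96 * sqrt(sum(((out$hi - out$expected) / 1.96)^2)) + 3)
})

test_that("positive subsets match target lengths exactly and keep the frame", {
  sim <- simulate_genome(length = 30000, n_cds = 12, seed = 3)
  targets <- c(12L, 12L, 40L)
  sets <- sample_positive_subsets(sim$features, sim$genome, targets,
                                  n_sets = 4, seed = 9)
  expect_length(sets, 4)
  for (s in sets) {
    expect_equal(s$aa_length, targets)
    expect_equal(nchar(s$nt_seq), 3L * targets)
    expect_equal(s$provenance, rep("annotated_subset", 3))
    # in-frame: window offset from the parent CDS start is a codon multiple
    for (j in seq_len(nrow(s))) {
      parent <- sim$features[sim$features$id == s$parent_id[j], ]
      off <- if (s$strand[j] == "+") s$start[j] - parent$start else
        parent$end - s$end[j]
      expect_equal(off %% 3, 0)
    }
  }
  expect_error(
    sample_positive_subsets(sim$features, sim$genome, 5000L, n_sets = 1),
    "no CDS long enough.*5000"
  )
})

test_that("in-frame windows are drawn uniformly across the parent CDS", {
  sim <- simulate_genome(length = 20000, n_cds = 1, cds_len_range = c(150, 150),
                         seed = 13)
  sets <- sample_positive_subsets(sim$features, sim$genome,
                                  rep(20L, 400), n_sets = 1, seed = 21)
  parent <- sim$features[1, ]
  offs <- vapply(seq_len(400), function(j) {
    s <- sets[[1]][j, ]
    if (s$strand == "+") (s$start - parent$start) / 3 else (parent$end - s$end) / 3
  }, numeric(1))
  # codon offsets 0..130 are equally likely: chi-squared over 10 bins,
  # with expected probabilities proportional to the integers per bin
  breaks <- seq(-0.5, 130.5, length.out = 11)
  obs <- table(cut(offs, breaks))
  expected_p <- table(cut(0:130, breaks)) / 131
  p <- stats::chisq.test(obs, p = as.numeric(expected_p))$p.value
  expect_gt(p, 0.01)
})

test_that("mock ORFs obey every constraint and match the length multiset", {
  sim <- simulate_genome(length = 40000, n_cds = 15, seed = 6)
  srna_orfs <- tibble::tibble(start = c(1000L, 2000L), end = c(1060L, 2090L))
  targets <- c(10L, 15L, 25L, 25L, 40L)
  sets <- sample_mock_orfs(sim$genome, sim$features, srna_orfs, targets,
                           n_sets = 6, seed = 8)
  blocked <- dplyr::bind_rows(sim$features[, c("start", "end")], srna_orfs)
  for (s in sets) {
    expect_equal(s$aa_length, targets)
    for (j in seq_len(nrow(s))) {
      cods <- smorfselect:::split_codons(s$nt_seq[j])
      expect_false(cods[1] == "ATG")
      expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
      expect_true(all(pmin(s$end[j], blocked$end) -
                        pmax(s$start[j], blocked$start) <= 0))
    }
  }
  # per-set mean length equals the target mean exactly
  expect_equal(mean(sets[[1]]$aa_length), mean(targets))
})

test_that("a stop-dense genome makes mock sampling fail loudly", {
  set.seed(9)
  # A/T-only sequence: every ~8th codon is a TAA stop on either strand, so
  # a long stop-free window is (7/8)^151-rare and the retry cap trips
  g <- mk_genome(paste(sample(c("A", "T"), 3000, replace = TRUE), collapse = ""))
  expect_error(
    sample_mock_orfs(g, empty_cds(), empty_cds()[, c("start", "end")],
                     150L, n_sets = 1, max_retry = 200, seed = 1),
    "mock sampling failed"
  )
})

test_that("overlap-matched mocks reproduce the template geometry", {
  sim <- simulate_genome(length = 60000, n_cds = 25, seed = 14)
  cds <- sim$features
  # template: ORF whose genomic right end pokes 10 nt into a CDS
  c1 <- cds[cds$strand == "+", ][1, ]
  orf <- tibble::tibble(
    orf_id = "t1", seqid = sim$genome$id, start = c1$start - 50L,
    end = c1$start + 10L, strand = "-", parent_id = "s",
    aa_length = 19L, nt_seq = "x", overlap_class = "antisense",
    extended_3prime = FALSE, provenance = "srna"
  )
  mocks <- sample_overlap_matched_mocks(orf, cds, sim$genome, n = 12, seed = 3)
  expect_equal(nrow(mocks), 12L)
  for (j in seq_len(nrow(mocks))) {
    ovl <- pmin(mocks$end[j], cds$end) - pmax(mocks$start[j], cds$start)
    expect_equal(max(ovl), 10L)  # overlap length preserved
    hit <- cds[which.max(ovl), ]
    expect_false(mocks$strand[j] == hit$strand)  # antisense preserved
    expect_equal(mocks$end[j] - mocks$start[j], 60L)  # span preserved
    cods <- smorfselect:::split_codons(mocks$nt_seq[j])
    expect_false(cods[1] == "ATG")
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("overlap-matched mocks refuse a non-overlapping template", {
  sim <- simulate_genome(length = 20000, n_cds = 5, seed = 4)
  orf <- tibble::tibble(
    orf_id = "t", seqid = "g", start = 0L, end = 60L, strand = "+",
    parent_id = "s", aa_length = 19L, nt_seq = "x", overlap_class = "none",
    extended_3prime = FALSE, provenance = "srna"
  )
  expect_error(
    sample_overlap_matched_mocks(orf, sim$features, sim$genome, n = 2),
    "overlap"
  )
})

test_that("upstream shuffles preserve per-string composition deterministically", {
  ups <- c(strrep("A", 20), random_seq(20, seed = 2))
  sets <- shuffle_upstream_backgrounds(ups, n = 5, seed = 11)
  expect_length(sets, 5)
  expect_equal(sets[[1]][1], strrep("A", 20))
  for (s in sets) {
    expect_equal(sort(strsplit(s[2], "")[[1]]), sort(strsplit(ups[2], "")[[1]]))
  }
  expect_identical(sets, shuffle_upstream_backgrounds(ups, n = 5, seed = 11))
})
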