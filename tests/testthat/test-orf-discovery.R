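test_that("a constructed 31-aa ORF is found with the stop codon included", {
  body <- paste0("ATG", strrep("GCA", 30), "TAA")
  g <- mk_genome(paste0(strrep("C", 30), body, strrep("C", 30)))
  srna <- mk_feature(25, 135, "+", "srna", "s1")
  orfs <- find_orfs_in_srna(srna, g, empty_cds())
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_length, 31L)
  expect_equal(orfs$end - orfs$start, 96L)  # (31 + 1) codons
  expect_equal(orfs$nt_seq, body)
  expect_false(orfs$extended_3prime)
})

test_that("an immediate stop yields no candidate and extension is flagged", {
  g <- mk_genome(paste0(strrep("C", 12), "ATGTAA", strrep("C", 20)))
  srna <- mk_feature(10, 30, "+", "srna", "s1")
  expect_equal(nrow(find_orfs_in_srna(srna, g, empty_cds())), 0L)

  # ORF whose stop lies past the annotated 3' end
  body <- paste0("ATG", strrep("GGA", 12), "TGA")
  g2 <- mk_genome(paste0(strrep("C", 10), body, strrep("C", 10)))
  srna2 <- mk_feature(5, 30, "+", "srna", "s2")  # ends mid-ORF
  orfs2 <- find_orfs_in_srna(srna2, g2, empty_cds())
  expect_equal(nrow(orfs2), 1L)
  expect_true(orfs2$extended_3prime)
  expect_equal(orfs2$aa_length, 13L)
})

test_that("sRNA candidates match a regex brute-force oracle on random sequences", {
  set.seed(71)
  for (rep in 1:60) {
    glen <- 400L
    g <- mk_genome(random_seq(glen))
    start <- sample(20:80, 1)
    srna <- mk_feature(start, start + 300L, "+", "srna", "s")
    got <- find_orfs_in_srna(srna, g, empty_cds(), min_aa = 10, max_aa = 50)
    want <- oracle_orfs_plus(g$seq, start, start + 300L, 10, 50, extend = TRUE)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
    expect_equal(got$aa_length, as.integer(want$aa))
  }
})

test_that("minus-strand discovery mirrors plus-strand discovery", {
  set.seed(72)
  for (rep in 1:20) {
    seqf <- random_seq(350)
    g <- mk_genome(seqf)
    grc <- mk_genome(smorfselect:::revcomp(seqf))
    srna_m <- mk_feature(40, 320, "-", "srna", "s")
    srna_p <- mk_feature(350 - 320, 350 - 40, "+", "srna", "s")
    om <- find_orfs_in_srna(srna_m, g, empty_cds(), min_aa = 5, max_aa = 60)
    op <- find_orfs_in_srna(srna_p, grc, empty_cds(), min_aa = 5, max_aa = 60)
    expect_equal(sort(350 - om$end), sort(op$start))
    expect_setequal(om$nt_seq, op$nt_seq)
  }
})

test_that("overlap classification follows precedence and matches the oracle", {
  cds <- mk_feature(30, 90, "+", "cds", "c1")
  inside <- tibble::tibble(start = 33L, end = 63L, strand = "+")
  expect_equal(classify_overlap(inside, cds), "sense_inframe")
  shifted <- tibble::tibble(start = 34L, end = 64L, strand = "+")
  expect_equal(classify_overlap(shifted, cds), "sense_outframe")
  anti <- tibble::tibble(start = 89L, end = 120L, strand = "-")
  expect_equal(classify_overlap(anti, cds), "antisense")
  clear <- tibble::tibble(start = 90L, end = 120L, strand = "+")
  expect_equal(classify_overlap(clear, cds), "none")

  set.seed(31)
  cds2 <- dplyr::bind_rows(lapply(1:4, function(i) {
    s <- sample(0:400, 1)
    mk_feature(s, s + 3 * sample(10:40, 1), sample(c("+", "-"), 1), "cds",
               paste0("c", i))
  }))
  for (rep in 1:500) {
    os <- sample(0:450, 1)
    oe <- os + 3 * sample(4:30, 1)
    ostrand <- sample(c("+", "-"), 1)
    got <- classify_overlap(tibble::tibble(start = os, end = oe,
                                           strand = ostrand), cds2)
    expect_equal(got, oracle_overlap(os, oe, ostrand, cds2))
  }
})

test_that("in-frame merge keeps the longest ORF and the best score", {
  orfs <- tibble::tibble(
    orf_id = c("a", "b", "c"), seqid = "g", strand = "+",
    start = c(10L, 55L, 200L), end = c(118L, 118L, 260L),
    aa_length = c(35L, 20L, 19L), nt_seq = "x",
    parent_id = "s", overlap_class = "none", extended_3prime = FALSE,
    provenance = "srna"
  )
  merged <- merge_inframe_overlaps(orfs, scores = c(a = 0.3, b = 0.9, c = 0.5))
  expect_equal(nrow(merged), 2L)
  kept <- merged[merged$end == 118L, ]
  expect_equal(kept$aa_length, 35L)      # longest representative survives
  expect_equal(kept$coding_score, 0.9)   # but carries the best score
  expect_equal(merged$coding_score[merged$orf_id == "c"], 0.5)

  # idempotence and identity without shared stops
  again <- merge_inframe_overlaps(merged[, names(orfs)])
  expect_equal(again$orf_id, merged$orf_id)
})

test_that("intergenic discovery removes every CDS overlap and matches the oracle", {
  g_allcds <- mk_genome(paste0("ATG", strrep("GCA", 40), "TAA"))
  cds_all <- mk_feature(0, nchar(g_allcds$seq), "+", "cds", "c")
  expect_equal(nrow(find_intergenic_orfs(g_allcds, cds_all)), 0L)

  set.seed(55)
  g <- mk_genome(random_seq(600))
  got <- find_intergenic_orfs(g, empty_cds(), min_aa = 10, max_aa = 50)
  fwd <- oracle_orfs_plus(g$seq, 0, 600, 10, 50, extend = FALSE)
  rc <- smorfselect:::revcomp(g$seq)
  rev <- oracle_orfs_plus(rc, 0, 600, 10, 50, extend = FALSE)
  expect_equal(sum(got$strand == "+"), nrow(fwd))
  expect_equal(sum(got$strand == "-"), nrow(rev))
  expect_equal(sort(got$start[got$strand == "+"]), sort(as.integer(fwd$start)))
  expect_equal(sort(600 - got$end[got$strand == "-"]), sort(as.integer(rev$start)))
})

test_that("emitted candidates satisfy the ORF invariants on random inputs", {
  set.seed(91)
  for (rep in 1:15) {
    g <- mk_genome(random_seq(500))
    srna <- mk_feature(50, 450, sample(c("+", "-"), 1), "srna", "s")
    orfs <- find_orfs_in_srna(srna, g, empty_cds())
    if (nrow(orfs) == 0) next
    expect_true(all((orfs$end - orfs$start) %% 3 == 0))
    expect_true(all(substr(orfs$nt_seq, 1, 3) == "ATG"))
    lastcod <- substr(orfs$nt_seq, nchar(orfs$nt_seq) - 2, nchar(orfs$nt_seq))
    expect_true(all(lastcod %in% c("TAA", "TAG", "TGA")))
    internal <- vapply(orfs$nt_seq, function(nt) {
      cods <- substring(nt, seq(1, nchar(nt) - 3, 3), seq(3, nchar(nt) - 3, 3))
      any(cods[-1] %in% c("TAA", "TAG", "TGA"))
    }, logical(1))
    expect_false(any(internal))
    expect_true(all(orfs$aa_length >= 10 & orfs$aa_length <= 50))
    # relaxing the length cap yields a superset
    all_orfs <- find_orfs_in_srna(srna, g, empty_cds(), min_aa = 10,
                                  max_aa = 10000)
    expect_true(all(orfs$orf_id %in% all_orfs$orf_id))
  }
})
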