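# Synthetic test-bed generator: genomes with planted CDS, sRNA annotations
# with planted coding ORFs (SD motif upstream, codon-usage-biased body),
# ortholog codon alignments evolved under a chosen omega with the same rate
# matrix the LRT uses, and strand-specific coverage tracks. The generator's
# defaults define the study conditions for all recovery tests.

# A biased bacterial-style codon usage: uniform amino-acid choice, strongly
# preferred synonymous codon per amino acid. Returned as sampling weights
# over the 61 sense codons.
default_codon_usage <- function(bias = 0.8) {
  aas <- unique(GENETIC_CODE_DNA[SENSE_CODONS])
  w <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in aas) {
    syn <- SENSE_CODONS[GENETIC_CODE_DNA[SENSE_CODONS] == aa]
    ws <- rep((1 - bias) / max(length(syn) - 1, 1), length(syn))
    ws[1] <- if (length(syn) == 1) 1 else bias
    w[syn] <- ws / length(aas)
  }
  w / sum(w)
}

sample_codons <- function(n, usage) {
  sample(names(usage), n, replace = TRUE, prob = usage)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Write a DNA fragment into a genome string at 0-based position `at` on the
# given strand (the fragment is given 5'->3' on `strand`).
plant_fragment <- function(seq, frag, at, strand = "+") {
  if (strand == "-") frag <- revcomp(frag)
  paste0(substr(seq, 1, at), frag, substr(seq, at + nchar(frag) + 1, nchar(seq)))
}

#' Simulate a genome with planted CDS
#'
#' Background bases are iid with the requested GC content; `n_cds`
#' non-overlapping CDS (ATG + codon-usage-biased body + stop) are planted at
#' random positions and strands, each preceded by a Shine-Dalgarno core in
#' its upstream region.
#'
#' @param length Genome length (nt).
#' @param gc Background GC content.
#' @param n_cds Number of CDS to plant.
#' @param cds_len_range Range of CDS peptide lengths (aa).
#' @param codon_usage Named sampling weights over the 61 sense codons.
#' @param sd_core DNA motif planted upstream of each CDS start (the SD
#'   sequence; pairs with the anti-SD tail).
#' @param seed Optional seed.
#' @return List with `genome` (one-row tibble) and `features` (CDS tibble).
#' @export
simulate_genome <- function(length = 50000, gc = 0.5, n_cds = 40,
                            cds_len_range = c(60, 200),
                            codon_usage = default_codon_usage(),
                            sd_core = "AGGAGG", seed = NULL) {
  local_seed(seed)
  seq <- random_dna(length, gc)
  margin <- 30L
  placed <- tibble::tibble(start = integer(), end = integer())
  rows <- vector("list", n_cds)
  for (i in seq_len(n_cds)) {
    aa <- sample_range(cds_len_range[1], cds_len_range[2])
    span <- 3L * (aa + 1L)
    for (try in 1:2000) {
      s <- sample.int(length - span - 2L * margin, 1) + margin
      if (interval_clear(s - margin, s + span + margin, placed)) break
      s <- NA_integer_
    }
    if (is.na(s)) stop("could not place all CDS; genome too small", call. = FALSE)
    strand <- sample(c("+", "-"), 1)
    body <- paste(sample_codons(aa - 1L, codon_usage), collapse = "")
    frag <- paste0("ATG", body, sample(STOP_CODONS, 1))
    seq <- plant_fragment(seq, frag, s, strand)
    # SD core ending 7 nt upstream of the start codon
    sd_at <- if (strand == "+") s - 7L - nchar(sd_core) else s + span + 7L
    seq <- plant_fragment(seq, sd_core, sd_at, strand)
    placed <- dplyr::bind_rows(placed,
                               tibble::tibble(start = s - margin,
                                              end = s + span + margin))
    rows[[i]] <- tibble::tibble(
      seqid = "synthetic1", start = s, end = s + span, strand = strand,
      ftype = "cds", id = sprintf("cds%03d", i)
    )
  }
  list(
    genome = tibble::tibble(id = "synthetic1", seq = seq, circular = FALSE),
    features = dplyr::bind_rows(rows)
  )
}

#' Simulate sRNA annotations with planted coding ORFs
#'
#' Places `n_srna` sRNAs in intergenic space. `n_coding` of them contain a
#' planted ORF (10-50 aa) with a Shine-Dalgarno core upstream of its ATG and
#' a codon-usage-biased body; the rest are background sequence. The
#' `SyntheticTruth` record lists the planted ORF ids.
#'
#' @param sim List from [simulate_genome()] (modified genome is returned).
#' @param n_srna Number of sRNAs.
#' @param n_coding Number of sRNAs that receive a planted coding ORF.
#' @param srna_len sRNA length (nt).
#' @param orf_aa_range Planted ORF peptide-length range.
#' @param codon_usage Codon usage for planted ORF bodies.
#' @param sd_core SD motif planted upstream of each planted ATG.
#' @param seed Optional seed.
#' @return List with `genome`, `features` (CDS + sRNA), `srnas`, and
#'   `truth` (tibble: `orf_id`, `srna_id`, `start`, `end`, `strand`).
#' @export
simulate_srnas <- function(sim, n_srna = 300, n_coding = 30, srna_len = 160L,
                           orf_aa_range = c(10, 40),
                           codon_usage = default_codon_usage(),
                           sd_core = "AGGAGG", seed = NULL) {
  local_seed(seed)
  srna_len <- as.integer(srna_len)
  genome <- sim$genome
  seq <- genome$seq
  glen <- nchar(seq)
  blocked <- sim$features[, c("start", "end")]
  srna_rows <- vector("list", n_srna)
  truth_rows <- list()
  coding_idx <- seq_len(n_coding)
  for (i in seq_len(n_srna)) {
    for (try in 1:5000) {
      s <- sample.int(glen - srna_len - 60L, 1) + 30L
      if (interval_clear(s - 25L, s + srna_len + 25L, blocked)) break
      s <- NA_integer_
    }
    if (is.na(s)) stop("could not place all sRNAs", call. = FALSE)
    strand <- sample(c("+", "-"), 1)
    srna_id <- sprintf("srna%04d", i)
    if (i %in% coding_idx) {
      aa <- sample_range(orf_aa_range[1], orf_aa_range[2])
      body <- paste(sample_codons(aa - 1L, codon_usage), collapse = "")
      orf <- paste0("ATG", body, sample(STOP_CODONS, 1))
      # lay out on the sRNA strand: SD core, 7-nt spacer, then the ORF
      pre <- nchar(sd_core) + 7L
      frag <- paste0(sd_core, random_dna(7L), orf)
      off <- 25L  # ORF starts 25 + pre into the sRNA window
      frag_at <- if (strand == "+") s + off else
        s + srna_len - off - nchar(frag)
      seq <- plant_fragment(seq, frag, frag_at, strand)
      orf_s <- if (strand == "+") frag_at + pre else frag_at
      orf_e <- orf_s + nchar(orf)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        orf_id = orf_uid(genome$id, orf_s, orf_e, strand),
        srna_id = srna_id, start = orf_s, end = orf_e, strand = strand
      )
    }
    srna_rows[[i]] <- tibble::tibble(
      seqid = genome$id, start = s, end = s + srna_len, strand = strand,
      ftype = "srna", id = srna_id
    )
    blocked <- dplyr::bind_rows(blocked,
                                tibble::tibble(start = s - 25L,
                                               end = s + srna_len + 25L))
  }
  genome$seq <- seq
  srnas <- dplyr::bind_rows(srna_rows)
  list(
    genome = genome,
    features = dplyr::bind_rows(sim$features, srnas),
    srnas = srnas,
    truth = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
      tibble::tibble(orf_id = character(), srna_id = character(),
                     start = integer(), end = integer(), strand = character())
  )
}

#' Simulate an ortholog codon alignment under the analysis codon model
#'
#' The reference sequence is fixed at the reference leaf and codon states
#' are evolved outward over the (unrooted) tree by sampling from the
#' transition matrices of the same GY94-style rate matrix the
#' likelihood-ratio test uses (valid under reversibility). Gapless output.
#'
#' @param cds_nt Reference DNA sequence (length divisible by 3, stop codons
#'   are dropped from the evolved portion if present internally -- the
#'   sequence is truncated to its sense codons).
#' @param tree `phylo` tree with branch lengths; `reference_id` must be a
#'   leaf.
#' @param reference_id Leaf carrying the reference sequence.
#' @param omega dN/dS used for the simulation.
#' @param kappa Transition/transversion ratio.
#' @param scale Multiplier applied to branch lengths.
#' @param seed Optional seed.
#' @return A `codon_alignment`.
#' @export
simulate_ortholog_alignment <- function(cds_nt, tree, reference_id, omega,
                                        kappa = 2, scale = 1, seed = NULL) {
  local_seed(seed)
  codons <- split_codons(toupper(cds_nt))
  codons <- codons[!codons %in% STOP_CODONS]
  idx <- codon_index(codons)
  assert_that(!anyNA(idx), "reference contains non-ACGT codons")
  assert_that(reference_id %in% tree$tip.label, "reference not in tree")
  pi <- f1x4_frequencies(paste(codons, collapse = ""))
  ntip <- length(tree$tip.label)
  # adjacency over the unrooted topology
  nedge <- nrow(tree$edge)
  adj <- vector("list", max(tree$edge))
  for (e in seq_len(nedge)) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  ref_node <- match(reference_id, tree$tip.label)
  # one eigendecomposition serves every branch
  uniq_t <- unique(scale * tree$edge.length)
  pmats <- cpp_codon_pmats(pi, codon_change_type(), kappa, omega, uniq_t)
  states <- matrix(NA_integer_, nrow = max(tree$edge), ncol = length(idx))
  states[ref_node, ] <- idx
  # BFS out from the reference tip
  queue <- ref_node
  visited <- logical(max(tree$edge))
  visited[ref_node] <- TRUE
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    nb <- adj[[node]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      child <- nb[r, 1]
      if (visited[child]) next
      t <- scale * tree$edge.length[nb[r, 2]]
      P <- pmats[[which(uniq_t == t)[1]]]
      parent_states <- states[node, ]
      child_states <- integer(length(parent_states))
      for (st in unique(parent_states)) {
        at <- which(parent_states == st)
        child_states[at] <- sample.int(61L, length(at), replace = TRUE,
                                       prob = P[st, ])
      }
      states[child, ] <- child_states
      visited[child] <- TRUE
      queue <- c(queue, child)
    }
  }
  rows <- vapply(seq_len(ntip), function(tip) {
    paste(SENSE_CODONS[states[tip, ]], collapse = "")
  }, character(1))
  names(rows) <- tree$tip.label
  structure(list(reference_id = reference_id, rows = rows),
            class = "codon_alignment")
}

#' Simulate strand-specific ribosome-profiling coverage
#'
#' Translated ORFs receive reads at their start/stop anchor windows on
#' their own strand; every other position receives iid Poisson background.
#'
#' @param orfs ORF-candidate tibble.
#' @param translated_ids `orf_id`s that are translated.
#' @param genome_length Genome length.
#' @param background_rate Poisson rate per position per strand.
#' @param window_codons Anchor window half-width (codons).
#' @param seed Optional seed.
#' @return List with `plus` and `minus` `coverage_track`s.
#' @export
simulate_ribo_coverage <- function(orfs, translated_ids, genome_length,
                                   background_rate = 0.001,
                                   window_codons = 3, seed = NULL) {
  local_seed(seed)
  vp <- stats::rpois(genome_length, background_rate)
  vm <- stats::rpois(genome_length, background_rate)
  wnt <- 3L * window_codons
  for (i in which(orfs$orf_id %in% translated_ids)) {
    pos <- ribo_window_positions(orfs$start[i], orfs$end[i], orfs$strand[i],
                                 wnt, genome_length)
    hit <- sample(pos, max(1L, length(pos) %/% 6L))
    if (orfs$strand[i] == "+") vp[hit] <- vp[hit] + sample(1:5, length(hit), TRUE)
    else vm[hit] <- vm[hit] + sample(1:5, length(hit), TRUE)
  }
  list(
    plus = structure(list(seqid = orfs$seqid[1] %||% NA_character_,
                          strand = "+", values = as.numeric(vp)),
                     class = "coverage_track"),
    minus = structure(list(seqid = orfs$seqid[1] %||% NA_character_,
                           strand = "-", values = as.numeric(vm)),
                      class = "coverage_track")
  )
}

#' dN/dS provider backed by the ortholog-alignment simulator
#'
#' Returns a `dnds_provider` function for [analyze_srna_coding()] that, for
#' every ORF row it is handed, simulates an ortholog codon alignment on the
#' given tree (under `omega_coding` for planted coding ORFs and annotated
#' subsets, `omega_null` otherwise) and runs the likelihood-ratio test on
#' it. This is the test bed for end-to-end parameter recovery: the
#' conservation feature is generated under the same codon model the test
#' assumes.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param reference_id Reference leaf label.
#' @param coding_ids `orf_id`s of planted coding ORFs.
#' @param omega_coding,omega_null dN/dS for coding and background rows.
#' @param kappa Transition/transversion ratio.
#' @param tol Likelihood-optimization tolerance passed to the test.
#' @param omega_bounds,scale_bounds Search intervals passed to the test.
#' @param seed Base seed; each ORF derives its own stream.
#' @return Function of an ORF tibble returning a tibble with `orf_id`,
#'   `omega_hat`, `loglik_diff`.
#' @export
simulated_dnds_provider <- function(tree, reference_id, coding_ids,
                                    omega_coding = 0.2, omega_null = 1,
                                    kappa = 2, tol = 0.05,
                                    omega_bounds = c(1e-4, 20),
                                    scale_bounds = c(1e-4, 100), seed = 1) {
  force(tree); force(coding_ids)
  function(orfs) {
    n <- nrow(orfs)
    om_hat <- diff <- numeric(n)
    seeds <- derive_seeds(seed, n)
    for (i in seq_len(n)) {
      om <- if (orfs$orf_id[i] %in% coding_ids ||
                orfs$provenance[i] == "annotated_subset") omega_coding else omega_null
      aln <- simulate_ortholog_alignment(orfs$nt_seq[i], tree, reference_id,
                                         omega = om, kappa = kappa,
                                         seed = seeds[[i]])
      res <- dnds_loglik_test(aln, tree, kappa = kappa, tol = tol,
                              omega_bounds = omega_bounds,
                              scale_bounds = scale_bounds)
      om_hat[i] <- res$omega_hat
      diff[i] <- res$loglik_diff
    }
    tibble::tibble(orf_id = orfs$orf_id, omega_hat = om_hat,
                   loglik_diff = diff)
  }
}
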