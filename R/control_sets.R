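# Matched control sets: positive controls are in-frame windows of annotated
# CDS; negative controls ("mock ORFs") are stop-free, non-ATG-initiated
# intergenic segments length-matched to the real sRNA ORFs. Both feed the
# classifier training set and the empirical-FDR null.

#' Shuffle a sequence preserving mononucleotide composition
#'
#' Plain uniform letter permutations (not dinucleotide-preserving).
#'
#' @param seq DNA string.
#' @param n Number of shuffles.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return Character vector of `n` shuffled strings.
#' @export
shuffle_sequence <- function(seq, n, seed = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  local_seed(seed)
  letters <- strsplit(seq, "")[[1]]
  vapply(seq_len(n), function(i) paste(sample(letters), collapse = ""),
         character(1))
}

#' Expected ORF counts in shuffled sRNA sequences
#'
#' Shuffles each sRNA sequence `n_shuffles` times, applies the same ORF
#' finding rules (ATG start, nearest in-frame stop, length bounds; shuffled
#' sequences are scanned standalone, with no 3' extension), and summarises
#' the count of resulting ORFs per peptide-length bin as mean and
#' mean +/- 1.96 sd across shuffles. The observed counts in the real
#' sequences are reported alongside.
#'
#' @param srnas sRNA feature tibble.
#' @param genome One-row genome tibble.
#' @param n_shuffles Number of shuffles (>= 2).
#' @param min_aa,max_aa Peptide-length bounds.
#' @param bins Breaks of aa-length bins; defaults to one bin per length.
#' @param seed Optional seed.
#' @return Tibble with `bin_lo`, `bin_hi`, `observed`, `expected`, `lo`,
#'   `hi` (CI bounds `expected +/- 1.96 sd`).
#' @export
expected_orf_count <- function(srnas, genome, n_shuffles = 1000,
                               min_aa = 10, max_aa = 50, bins = NULL,
                               seed = NULL) {
  assert_that(n_shuffles >= 2, "n_shuffles must be >= 2")
  local_seed(seed)
  if (is.null(bins)) bins <- seq(min_aa, max_aa + 1L)
  seqs <- vapply(seq_len(nrow(srnas)), function(i) {
    extract_interval(genome$seq, srnas$start[i], srnas$end[i], srnas$strand[i])
  }, character(1))
  count_bins <- function(lens) {
    graduated <- findInterval(lens, bins, rightmost.closed = FALSE)
    tabulate(graduated[graduated >= 1 & graduated < length(bins)],
             nbins = length(bins) - 1L)
  }
  orf_lengths <- function(ss) {
    unlist(lapply(ss, function(s) {
      hits <- scan_orfs(s, 0L, nchar(s), "+", min_aa, max_aa, extend = FALSE)
      hits$aa_length
    }))
  }
  observed <- count_bins(orf_lengths(seqs))
  per_shuffle <- vapply(seq_len(n_shuffles), function(k) {
    count_bins(orf_lengths(vapply(seqs, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))))
  }, numeric(length(bins) - 1L))
  per_shuffle <- matrix(per_shuffle, nrow = length(bins) - 1L)
  mu <- rowMeans(per_shuffle)
  sdv <- apply(per_shuffle, 1, stats::sd)
  tibble::tibble(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1] - 1L,
    observed = observed, expected = mu,
    lo = mu - 1.96 * sdv, hi = mu + 1.96 * sdv
  )
}

#' Sample positive control sets from annotated CDS
#'
#' For each target peptide length, a random annotated CDS with enough codons
#' is chosen and a random in-frame window of that length is cut from its
#' body (terminal stop codon excluded), so the window retains the parent
#' reading frame. Each set's length multiset equals `target_lengths` exactly.
#'
#' @param cds CDS feature tibble.
#' @param genome One-row genome tibble.
#' @param target_lengths Integer vector of peptide lengths (aa) to match.
#' @param n_sets Number of control sets.
#' @param seed Optional seed.
#' @return List of `n_sets` ORF-candidate tibbles with
#'   `provenance = "annotated_subset"`; `parent_id` names the source CDS.
#' @export
sample_positive_subsets <- function(cds, genome, target_lengths,
                                    n_sets = 20, seed = NULL) {
  local_seed(seed)
  cds <- cds[cds$ftype == "cds", , drop = FALSE]
  assert_that(nrow(cds) > 0, "no annotated CDS available")
  n_codons <- (cds$end - cds$start) %/% 3L - 1L  # usable codons excl. stop
  nt_len <- length(target_lengths)
  lapply(seq_len(n_sets), function(set_i) {
    starts <- ends <- integer(nt_len)
    strands <- ids <- parents <- nts <- character(nt_len)
    for (j in seq_len(nt_len)) {
      m <- target_lengths[j]
      ok <- which(n_codons >= m)
      if (length(ok) == 0L) {
        stop(sprintf("no CDS long enough for target length %d aa", m),
             call. = FALSE)
      }
      ci <- ok[sample.int(length(ok), 1L)]
      off <- sample.int(n_codons[ci] - m + 1L, 1L) - 1L  # codon offset
      if (cds$strand[ci] == "+") {
        s <- cds$start[ci] + 3L * off
        e <- s + 3L * m
      } else {
        e <- cds$end[ci] - 3L * off
        s <- e - 3L * m
      }
      starts[j] <- s; ends[j] <- e; strands[j] <- cds$strand[ci]
      parents[j] <- cds$id[ci]
      ids[j] <- sprintf("pos%02d_%03d_%s", set_i, j, cds$id[ci])
      nts[j] <- extract_interval(genome$seq, s, e, cds$strand[ci])
    }
    tibble::tibble(
      orf_id = ids, seqid = genome$id, start = starts, end = ends,
      strand = strands, parent_id = parents,
      aa_length = as.integer(target_lengths), nt_seq = nts,
      overlap_class = "none", extended_3prime = FALSE,
      provenance = "annotated_subset"
    )
  })
}

# Interval fits entirely outside every interval in `blocked` (both strands)?
interval_clear <- function(s, e, blocked) {
  if (nrow(blocked) == 0L) return(TRUE)
  all(pmin(e, blocked$end) - pmax(s, blocked$start) <= 0L)
}

#' Sample mock ORF sets from intergenic space
#'
#' A mock matched to an m-aa ORF occupies the same nucleotide span as the
#' real ORF including its stop codon (3m + 3 nt). Every mock satisfies: the
#' interval lies outside all annotated CDS (either strand) and outside all
#' real sRNA ORFs of 10-50 aa; the first codon is not ATG; no codon in the
#' span is an in-frame stop. Mocks get a nominal strand uniformly at random.
#' Sampling is rejection sampling with a retry cap.
#'
#' @param genome One-row genome tibble.
#' @param cds CDS feature tibble.
#' @param srna_orfs Tibble of real sRNA ORF candidates to exclude.
#' @param target_lengths Integer vector of peptide lengths to match.
#' @param n_sets Number of mock sets.
#' @param max_retry Per-mock rejection-sampling cap.
#' @param seed Optional seed.
#' @return List of `n_sets` ORF-candidate tibbles with `provenance = "mock"`.
#' @export
sample_mock_orfs <- function(genome, cds, srna_orfs, target_lengths,
                             n_sets = 20, max_retry = 10000, seed = NULL) {
  local_seed(seed)
  glen <- nchar(genome$seq)
  cds <- cds[cds$ftype == "cds", , drop = FALSE]
  blocked <- dplyr::bind_rows(
    cds[, c("start", "end")],
    if (nrow(srna_orfs) > 0) srna_orfs[, c("start", "end")] else NULL
  )
  nt_len <- length(target_lengths)
  lapply(seq_len(n_sets), function(set_i) {
    starts <- ends <- integer(nt_len)
    strands <- nts <- character(nt_len)
    for (j in seq_len(nt_len)) {
      m <- target_lengths[j]
      span <- 3L * (m + 1L)
      placed <- FALSE
      for (try in seq_len(max_retry)) {
        s <- sample.int(glen - span + 1L, 1L) - 1L
        e <- s + span
        if (!interval_clear(s, e, blocked)) next
        strand <- sample(c("+", "-"), 1L)
        nt <- extract_interval(genome$seq, s, e, strand)
        if (grepl("N", nt, fixed = TRUE)) next
        codons <- split_codons(nt)
        if (codons[1] == "ATG") next
        if (any(codons %in% STOP_CODONS)) next
        starts[j] <- s; ends[j] <- e; strands[j] <- strand; nts[j] <- nt
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "mock sampling failed for length %d aa after %d tries; intergenic space may be too constrained",
          m, max_retry), call. = FALSE)
      }
    }
    tibble::tibble(
      orf_id = sprintf("mock%02d_%03d", set_i, seq_len(nt_len)),
      seqid = genome$id, start = starts, end = ends, strand = strands,
      parent_id = "mock", aa_length = as.integer(target_lengths),
      nt_seq = nts, overlap_class = "none", extended_3prime = FALSE,
      provenance = "mock"
    )
  })
}

# Strand-aware overlap descriptor of an ORF against the CDS it overlaps:
# which ORF end sits in the CDS, which CDS end is hit, the overlap length,
# and the relative orientation.
overlap_descriptor <- function(orf, cds_row) {
  L <- min(orf$end, cds_row$end) - max(orf$start, cds_row$start)
  assert_that(L > 0, "ORF does not overlap the CDS")
  contained <- orf$start >= cds_row$start && orf$end <= cds_row$end
  # genomic side of the ORF that pokes into the CDS
  orf_right_in <- orf$end > cds_row$start && orf$end <= cds_row$end
  orf_left_in <- orf$start >= cds_row$start && orf$start < cds_row$end
  side <- if (contained) "contained" else if (orf_right_in) "right" else if (orf_left_in) "left" else "spans"
  # which end of the CDS (in its own 5'->3' orientation) is overlapped:
  # side == "right" means the overlap sits at the CDS's genomic-left
  # boundary, which is its 5' end on "+" and its 3' end on "-"
  cds_end <- if (side == "right") {
    if (cds_row$strand == "+") "5prime" else "3prime"
  } else if (side == "left") {
    if (cds_row$strand == "+") "3prime" else "5prime"
  } else side
  list(
    len = L, side = side, cds_end = cds_end,
    orientation = if (orf$strand == cds_row$strand) "sense" else "antisense",
    frame_off = (frame_anchor(orf$start, orf$end, orf$strand) -
                   frame_anchor(cds_row$start, cds_row$end, cds_row$strand)) %% 3L
  )
}

#' Sample mock ORFs matched to an overlapping sRNA ORF
#'
#' For an sRNA ORF that overlaps an annotated CDS (sense out-of-frame or
#' antisense), each mock reproduces the template's overlap length, relative
#' orientation and overlapped side against a randomly chosen annotated CDS,
#' with the remainder of the mock in intergenic space. Because annotated CDS
#' lengths are multiples of three, anchoring the overlap at the matched CDS
#' boundary also reproduces the template's reading-frame offset. Mocks obey
#' the plain-mock constraints (first codon not ATG, no in-frame stop).
#'
#' @param orf One-row ORF-candidate tibble with
#'   `overlap_class %in% c("sense_outframe", "antisense")`.
#' @param cds CDS feature tibble.
#' @param genome One-row genome tibble.
#' @param srna_orfs Real sRNA ORFs to exclude from the intergenic remainder.
#' @param n Number of mocks.
#' @param max_retry Rejection-sampling cap.
#' @param seed Optional seed.
#' @return ORF-candidate tibble of `n` mocks (`provenance = "mock"`).
#' @export
sample_overlap_matched_mocks <- function(orf, cds, genome, srna_orfs = NULL,
                                         n = 20, max_retry = 10000,
                                         seed = NULL) {
  assert_that(nrow(orf) == 1L, "orf must be a single candidate row")
  assert_that(orf$overlap_class %in% c("sense_outframe", "antisense"),
              "overlap-matched mocks require an overlapping ORF (use sample_mock_orfs for overlap length 0)")
  local_seed(seed)
  cds <- cds[cds$ftype == "cds", , drop = FALSE]
  hit <- which(vapply(seq_len(nrow(cds)), function(i) {
    min(orf$end, cds$end[i]) - max(orf$start, cds$start[i]) > 0
  }, logical(1)))
  assert_that(length(hit) > 0, "ORF overlaps no annotated CDS")
  desc <- overlap_descriptor(orf, cds[hit[1], ])
  span <- orf$end - orf$start
  glen <- nchar(genome$seq)
  blocked <- dplyr::bind_rows(
    cds[, c("start", "end")],
    if (!is.null(srna_orfs) && nrow(srna_orfs) > 0) srna_orfs[, c("start", "end")] else NULL
  )
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      ci <- sample.int(nrow(cds), 1L)
      cs <- cds$start[ci]; ce <- cds$end[ci]
      strand <- if (desc$orientation == "sense") cds$strand[ci] else
        setdiff(c("+", "-"), cds$strand[ci])
      rem <- NULL
      if (desc$side == "contained") {
        if (ce - cs < span) next
        # in-frame-offset-preserving slots inside the CDS
        off0 <- (orf$start - cds$start[hit[1]]) %% 3L
        if (cs + off0 > ce - span) next
        slots <- seq(cs + off0, ce - span, by = 3L)
        s <- slots[sample.int(length(slots), 1L)]
        e <- s + span
      } else if (desc$side %in% c("right", "left")) {
        # anchor the overlap at the boundary matching the template's CDS
        # end in the candidate CDS's own orientation
        at_left <- (desc$cds_end == "5prime") == (cds$strand[ci] == "+")
        if (at_left) {
          e <- cs + desc$len
          s <- e - span
          if (s < 0 || e > glen || e > ce) next
          rem <- c(s, cs)
        } else {
          s <- ce - desc$len
          e <- s + span
          if (s < 0 || e > glen || s < cs) next
          rem <- c(ce, e)
        }
      } else {
        next
      }
      # the non-overlap remainder must be intergenic
      others <- blocked[!(blocked$start == cs & blocked$end == ce), , drop = FALSE]
      if (!is.null(rem) && rem[2] > rem[1] &&
          !interval_clear(rem[1], rem[2], others)) next
      nt <- extract_interval(genome$seq, s, e, strand)
      if (grepl("N", nt, fixed = TRUE)) next
      codons <- split_codons(nt)
      if (length(codons) == 0L || codons[1] == "ATG") next
      if (any(codons %in% STOP_CODONS)) next
      rows[[k]] <- tibble::tibble(
        orf_id = sprintf("ovmock_%s_%03d", orf$orf_id, k),
        seqid = genome$id, start = s, end = e, strand = strand,
        parent_id = orf$orf_id, aa_length = orf$aa_length, nt_seq = nt,
        overlap_class = orf$overlap_class, extended_3prime = FALSE,
        provenance = "mock"
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("no CDS admits the required overlap geometry for this ORF",
           call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Shuffle 20-nt upstream regions
#'
#' Per-string letter permutation repeated `n` times; composition is preserved
#' within each string.
#'
#' @param upstreams Character vector of upstream sequences (typically 20 nt).
#' @param n Number of shuffled sets.
#' @param seed Optional seed.
#' @return List of `n` character vectors, each a per-string shuffle of
#'   `upstreams`.
#' @export
shuffle_upstream_backgrounds <- function(upstreams, n = 20, seed = NULL) {
  local_seed(seed)
  lapply(seq_len(n), function(i) {
    vapply(upstreams, function(s) {
      if (is.na(s)) return(NA_character_)
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}
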