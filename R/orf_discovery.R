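# Candidate short-ORF enumeration. ATG is the only accepted start codon;
# an ORF runs from its ATG through the nearest in-frame stop (stop included
# in the interval). aa_length counts codons excluding the stop, so a 10-aa
# ORF spans 33 nt.

#' Find candidate short ORFs within one annotated sRNA
#'
#' Every ATG on the sRNA strand inside the sRNA interval opens a candidate,
#' which is extended to the nearest in-frame stop codon. If the stop lies past
#' the annotated 3' end the ORF is extended into the genome (flagged
#' `extended_3prime`); an ORF with no in-frame stop before the genome end is
#' discarded, as is any candidate whose window contains `N`. Candidates with
#' peptide length outside `[min_aa, max_aa]` are dropped, and so are
#' candidates with in-frame, same-strand overlap with an annotated CDS.
#' Remaining candidates are labelled with their overlap class against the CDS
#' annotation.
#'
#' @param srna One-row feature tibble with `ftype == "srna"`.
#' @param genome One-row genome tibble (see [read_genome()]).
#' @param cds Feature tibble of annotated CDS (may be empty).
#' @param min_aa,max_aa Peptide length bounds (codons excluding the stop).
#' @return ORF-candidate tibble (possibly empty).
#' @export
find_orfs_in_srna <- function(srna, genome, cds, min_aa = 10, max_aa = 50) {
  assert_that(nrow(srna) == 1L && srna$ftype == "srna",
              "srna must be a single feature of type 'srna'")
  glen <- nchar(genome$seq)
  assert_that(srna$start >= 0 && srna$end <= glen,
              "sRNA interval outside genome")
  cand <- scan_orfs(genome$seq, srna$start, srna$end, srna$strand,
                    min_aa = min_aa, max_aa = max_aa, extend = TRUE)
  if (nrow(cand) == 0L) return(empty_orf_tbl())
  cand$parent_id <- srna$id
  cand$seqid <- genome$id
  cand$provenance <- "srna"
  cds_here <- cds[cds$ftype == "cds", , drop = FALSE]
  cand$overlap_class <- classify_overlap(cand, cds_here)
  cand <- cand[cand$overlap_class != "sense_inframe", , drop = FALSE]
  finish_orf_tbl(cand)
}

#' Find intergenic candidate short ORFs
#'
#' Scans both strands of the genome for ATG-initiated ORFs in the length
#' range, then removes every candidate that overlaps an annotated CDS by one
#' or more nucleotides on either strand. Surviving candidates have
#' `overlap_class == "none"`.
#'
#' @inheritParams find_orfs_in_srna
#' @param srnas Optional sRNA feature tibble, recorded for provenance only;
#'   the intergenic rule filters on CDS overlap alone.
#' @return ORF-candidate tibble.
#' @export
find_intergenic_orfs <- function(genome, cds, srnas = NULL,
                                 min_aa = 10, max_aa = 50) {
  glen <- nchar(genome$seq)
  cand <- dplyr::bind_rows(
    scan_orfs(genome$seq, 0L, glen, "+", min_aa, max_aa, extend = FALSE),
    scan_orfs(genome$seq, 0L, glen, "-", min_aa, max_aa, extend = FALSE)
  )
  if (nrow(cand) == 0L) return(empty_orf_tbl())
  cand$parent_id <- "intergenic"
  cand$seqid <- genome$id
  cand$provenance <- "intergenic"
  cds_here <- cds[cds$ftype == "cds", , drop = FALSE]
  keep <- !overlaps_any(cand, cds_here)
  cand <- cand[keep, , drop = FALSE]
  cand$overlap_class <- rep("none", nrow(cand))
  finish_orf_tbl(cand)
}

# Core scanner on one strand of [region_start, region_end). ATGs must start
# within the region; stops may lie beyond it when extend = TRUE (up to the
# genome end), never when extend = FALSE.
scan_orfs <- function(seq, region_start, region_end, strand,
                      min_aa, max_aa, extend) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  glen <- nchar(seq)
  if (strand == "-") {
    # work on the reverse complement; a window [s, e) there maps back to
    # [glen - e, glen - s) on the forward strand
    res <- scan_orfs(revcomp(seq), glen - region_end, glen - region_start,
                     "+", min_aa, max_aa, extend)
    if (nrow(res) == 0L) return(res)
    new_start <- glen - res$end
    res$end <- glen - res$start
    res$start <- new_start
    res$strand <- "-"
    return(res)
  }
  # an ATG must *start* within the region; it may span the 3' boundary, so
  # scan two extra bases and filter on the start position
  region <- substr(seq, region_start + 1L, min(region_end + 2L, glen))
  atg_rel <- as.integer(stringr::str_locate_all(region, "(?=ATG)")[[1]][, "start"])
  atg0 <- region_start + atg_rel - 1L  # 0-based genomic ATG positions
  atg0 <- atg0[atg0 < region_end]
  if (length(atg0) == 0L) return(empty_orf_tbl())
  search_end <- if (extend) glen else region_end
  out <- lapply(atg0, function(s) {
    # walk codons from s until an in-frame stop
    n_cod <- (search_end - s) %/% 3L
    if (n_cod < 2L) return(NULL)
    codons <- substring(seq, s + 1L + 3L * (seq_len(n_cod) - 1L),
                        s + 3L * seq_len(n_cod))
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(stop_i) == 0L) return(NULL)
    k <- stop_i[1]
    aa_len <- k - 1L
    if (aa_len < min_aa || aa_len > max_aa) return(NULL)
    e <- s + 3L * k
    nt <- substr(seq, s + 1L, e)
    if (grepl("N", nt, fixed = TRUE)) return(NULL)
    list(start = s, end = e, aa_length = aa_len, nt_seq = nt,
         extended = e > region_end)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_orf_tbl())
  tibble::tibble(
    orf_id = NA_character_,
    seqid = NA_character_,
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    strand = "+",
    parent_id = NA_character_,
    aa_length = vapply(out, `[[`, integer(1), "aa_length"),
    nt_seq = vapply(out, `[[`, character(1), "nt_seq"),
    overlap_class = NA_character_,
    extended_3prime = vapply(out, `[[`, logical(1), "extended"),
    provenance = NA_character_
  )
}

finish_orf_tbl <- function(orfs) {
  if (nrow(orfs) == 0L) return(empty_orf_tbl())
  orfs$orf_id <- orf_uid(orfs$seqid, orfs$start, orfs$end, orfs$strand)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  tibble::as_tibble(orfs)[names(empty_orf_tbl())]
}

# Genomic reading-frame anchor of an interval: position of codon boundaries
# mod 3. For "+" ORFs codons start at `start`; for "-" ORFs they start at
# `end` and run leftwards, so the anchor is `end mod 3`.
frame_anchor <- function(start, end, strand) {
  ifelse(strand == "+", start %% 3L, end %% 3L)
}

#' Classify the overlap of candidate ORFs against annotated CDS
#'
#' Returns one of `sense_inframe` (same strand, congruent reading frame, at
#' least one fully shared in-frame codon), `sense_outframe` (same strand,
#' >= 1 nt overlap, different frame), `antisense` (opposite strand, >= 1 nt
#' overlap) or `none`. When several CDS overlap one ORF the precedence is
#' `sense_inframe > sense_outframe > antisense`.
#'
#' @param orfs ORF-candidate tibble (only `start`, `end`, `strand` are used).
#' @param cds CDS feature tibble.
#' @return Character vector of overlap classes, one per ORF.
#' @export
classify_overlap <- function(orfs, cds) {
  n <- nrow(orfs)
  if (n == 0L) return(character(0))
  if (is.null(cds) || nrow(cds) == 0L) return(rep("none", n))
  vapply(seq_len(n), function(i) {
    s <- orfs$start[i]; e <- orfs$end[i]; st <- orfs$strand[i]
    ov_len <- pmin(e, cds$end) - pmax(s, cds$start)
    hit <- ov_len > 0L
    if (!any(hit)) return("none")
    same <- hit & cds$strand == st
    if (any(same)) {
      anchor <- frame_anchor(s, e, st)
      cds_anchor <- frame_anchor(cds$start, cds$end, cds$strand)
      inframe <- same & (cds_anchor %% 3L == anchor %% 3L)
      if (any(inframe)) {
        # require a complete shared codon on the common grid
        a <- pmax(s, cds$start[inframe])
        b <- pmin(e, cds$end[inframe])
        lead <- (3L - ((a - anchor) %% 3L)) %% 3L
        if (any(b - (a + lead) >= 3L)) return("sense_inframe")
      }
      if (any(same & !(cds_anchor %% 3L == anchor %% 3L))) return("sense_outframe")
      # same strand, congruent frame but no full shared codon: treat as
      # out-of-frame-style sense overlap
      return("sense_outframe")
    }
    "antisense"
  }, character(1))
}

overlaps_any <- function(orfs, cds) {
  if (nrow(cds) == 0L) return(rep(FALSE, nrow(orfs)))
  vapply(seq_len(nrow(orfs)), function(i) {
    any(pmin(orfs$end[i], cds$end) - pmax(orfs$start[i], cds$start) > 0L)
  }, logical(1))
}

#' Merge in-frame overlapping ORF candidates
#'
#' Candidates sharing seqid, strand and stop codon (several ATGs feeding the
#' same stop) collapse to the longest representative. When per-ORF coding
#' scores are supplied the merged record carries the maximum constituent
#' score. The operation is idempotent.
#'
#' @param orfs ORF-candidate tibble.
#' @param scores Optional named numeric vector of coding scores keyed by
#'   `orf_id`, or a numeric vector aligned with `orfs` rows.
#' @return Tibble of merged candidates; if scores were supplied, with a
#'   `coding_score` column holding the group maximum.
#' @export
merge_inframe_overlaps <- function(orfs, scores = NULL) {
  if (nrow(orfs) == 0L) return(orfs)
  sc <- NULL
  if (!is.null(scores)) {
    sc <- if (!is.null(names(scores))) unname(scores[orfs$orf_id]) else scores
    assert_that(length(sc) == nrow(orfs), "scores misaligned with orfs")
  }
  stop_anchor <- ifelse(orfs$strand == "+", orfs$end, orfs$start)
  key <- paste(orfs$seqid, orfs$strand, stop_anchor)
  keep <- unlist(lapply(split(seq_len(nrow(orfs)), key), function(idx) {
    idx[which.max(orfs$aa_length[idx])]
  }), use.names = FALSE)
  out <- orfs[sort(keep), , drop = FALSE]
  if (!is.null(sc)) {
    gmax <- vapply(split(sc, key), max, numeric(1))
    out$coding_score <- unname(gmax[paste(out$seqid, out$strand,
      ifelse(out$strand == "+", out$end, out$start))])
  }
  out
}
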