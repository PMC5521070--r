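# Shine-Dalgarno strength: hybridization free energy between the 20 nt
# upstream of a start codon and the species' anti-SD sequence (the 3' tail
# of the 16S rRNA), under a nearest-neighbor duplex model at 37 C.

base_codes <- function(rna) {
  x <- match(strsplit(rna, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(x)) stop("sequence contains a non-ACGU character", call. = FALSE)
  x
}

#' Extract the 20-nt upstream region of an ORF
#'
#' Strand-aware extraction, read 5' to 3', ending immediately before the
#' start codon. ORFs closer than `width` nt to the genome edge get
#' `NA` (a missing-value marker, not an error).
#'
#' @param orfs ORF-candidate tibble.
#' @param genome One-row genome tibble.
#' @param width Upstream window width in nt.
#' @return Character vector of upstream sequences (`NA` where unavailable).
#' @export
extract_upstream <- function(orfs, genome, width = 20) {
  glen <- nchar(genome$seq)
  vapply(seq_len(nrow(orfs)), function(i) {
    if (orfs$strand[i] == "+") {
      s <- orfs$start[i] - width
      if (s < 0) return(NA_character_)
      extract_interval(genome$seq, s, orfs$start[i], "+")
    } else {
      e <- orfs$end[i] + width
      if (e > glen) return(NA_character_)
      extract_interval(genome$seq, orfs$end[i], e, "-")
    }
  }, character(1))
}

#' Duplex hybridization free energy against an anti-SD sequence
#'
#' Minimum free energy of an intermolecular duplex between the upstream
#' sequence (DNA input is transcribed T -> U) and the anti-SD RNA, under the
#' Turner nearest-neighbor stacking model (Watson-Crick and GU pairs), a
#' duplex-initiation penalty, and a linear per-unpaired-nucleotide cost for
#' interior loops and bulges. Energies are kJ/mol at 37 C; when no duplex is
#' stable the free energy is 0. The conventional reported score is the
#' negated free energy, so larger reported scores mean stronger pairing and
#' the literature threshold "stronger than -11 kJ/mol" reads directly as
#' `delta_g < -11`.
#'
#' @param upstream DNA or RNA string (or vector of strings; `NA` propagates).
#' @param anti_sd Anti-SD RNA string, 5' to 3', at least 4 nt.
#' @param loop_penalty Cost per unpaired nucleotide in loops, kJ/mol.
#' @return Tibble with columns `delta_g` (<= 0) and `reported_score`
#'   (`-delta_g`).
#' @export
duplex_free_energy <- function(upstream, anti_sd, loop_penalty = 2.1) {
  assert_that(nchar(anti_sd) >= 4, "anti-SD sequence must be >= 4 nt")
  asd <- base_codes(toupper(chartr("T", "U", anti_sd)))
  asd_rev <- rev(asd)
  dg <- vapply(upstream, function(u) {
    if (is.na(u) || nchar(u) == 0) return(NA_real_)
    up <- base_codes(toupper(chartr("T", "U", u)))
    cpp_duplex_mfe(up, asd_rev, loop_penalty)
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(delta_g = dg, reported_score = -dg)
}

#' SD scores for a table of ORF candidates
#'
#' Convenience wrapper: extracts upstream windows and scores them against the
#' anti-SD sequence. Optionally also returns `n_shuffles` per-ORF shuffled
#' upstream scores as a composition-matched background.
#'
#' @inheritParams extract_upstream
#' @inheritParams duplex_free_energy
#' @param n_shuffles Number of per-upstream shuffles for the background
#'   (0 = none).
#' @param seed Optional seed for the shuffles.
#' @return `orfs` with added columns `sd_delta_g` and, if requested, a list
#'   column `sd_shuffled` of shuffled-upstream delta-G vectors.
#' @export
sd_score_orfs <- function(orfs, genome, anti_sd, width = 20,
                          loop_penalty = 2.1, n_shuffles = 0, seed = NULL) {
  local_seed(seed)
  ups <- extract_upstream(orfs, genome, width)
  orfs$sd_delta_g <- duplex_free_energy(ups, anti_sd, loop_penalty)$delta_g
  if (n_shuffles > 0) {
    orfs$sd_shuffled <- lapply(ups, function(u) {
      if (is.na(u)) return(rep(NA_real_, n_shuffles))
      sh <- shuffle_sequence(u, n_shuffles)
      duplex_free_energy(sh, anti_sd, loop_penalty)$delta_g
    })
  }
  orfs
}
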