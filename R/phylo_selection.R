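# Reference-framed codon alignments and the dN/dS likelihood-ratio test:
# a GY94-style codon model with a single omega across sites and branches,
# fixed kappa, F1x4 codon frequencies, branch lengths from the input tree
# rescaled by one free global multiplier. The free-omega and the
# omega-fixed-at-1 fits are compared; the reported statistic is
# max(lnl_free - lnl_fixed, 0).

# 61x61 single-nucleotide-change classification, built once at load:
# 0 multi-nt, 1 syn transversion, 2 syn transition, 3 nonsyn tv, 4 nonsyn ts
codon_change_type <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- length(SENSE_CODONS)
    mat <- matrix(0L, n, n)
    is_ts <- function(a, b) paste0(a, b) %in% c("AG", "GA", "CT", "TC")
    for (i in seq_len(n)) {
      ci <- strsplit(SENSE_CODONS[i], "")[[1]]
      for (j in seq_len(n)) {
        if (i == j) next
        cj <- strsplit(SENSE_CODONS[j], "")[[1]]
        d <- which(ci != cj)
        if (length(d) != 1L) next
        ts <- is_ts(ci[d], cj[d])
        syn <- GENETIC_CODE_DNA[SENSE_CODONS[i]] == GENETIC_CODE_DNA[SENSE_CODONS[j]]
        mat[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
      }
    }
    cache <<- mat
    mat
  }
})

#' Build a reference-framed codon alignment
#'
#' Columns where the reference has a gap are spliced out; any non-reference
#' codon equal to a stop (in the reference frame) is replaced by `---`;
#' trailing partial reference codons are trimmed. The result is an object of
#' class `codon_alignment` whose reference row is gap-free with length
#' divisible by 3.
#'
#' @param rows Named character vector of aligned sequences (same length,
#'   gaps as `-`), or a path to an aligned FASTA file.
#' @param reference_id Name of the reference row.
#' @return A `codon_alignment`: list with `reference_id` and `rows`.
#' @export
preprocess_alignment <- function(rows, reference_id) {
  if (length(rows) == 1L && is.character(rows) && file.exists(rows[[1]]) &&
      is.null(names(rows))) {
    set <- Biostrings::readBStringSet(rows)
    rows <- stats::setNames(toupper(as.character(set)),
                            stringr::str_split_fixed(names(set), "\\s+", 2)[, 1])
  }
  assert_that(reference_id %in% names(rows), "reference row not present")
  rows <- toupper(rows)
  lens <- nchar(rows)
  assert_that(length(unique(lens)) == 1L, "aligned rows differ in length")
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- mat[reference_id, ] != "-"
  mat <- mat[, keep, drop = FALSE]
  ncod <- ncol(mat) %/% 3L
  assert_that(ncod >= 1L, "alignment has no complete reference codon")
  mat <- mat[, seq_len(3L * ncod), drop = FALSE]
  for (sp in setdiff(rownames(mat), reference_id)) {
    for (k in seq_len(ncod)) {
      idx <- (3L * k - 2L):(3L * k)
      if (paste(mat[sp, idx], collapse = "") %in% STOP_CODONS) {
        mat[sp, idx] <- "-"
      }
    }
  }
  out_rows <- apply(mat, 1, paste, collapse = "")
  structure(list(reference_id = reference_id, rows = out_rows),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d rows x %d codons (reference %s)\n",
              length(x$rows), nchar(x$rows[1]) / 3, x$reference_id))
  invisible(x)
}

#' Prune a tree to at most `max_leaves` leaves
#'
#' While the leaf count exceeds `max_leaves`, the pair of leaves with the
#' minimum path length is found and one of the two is removed uniformly at
#' random (a protected leaf, typically the reference species, is never
#' removed); unary nodes are collapsed with branch lengths summed, so path
#' lengths between surviving leaves are preserved.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param max_leaves Maximum number of leaves to keep.
#' @param keep Leaf label(s) never removed.
#' @param seed Optional seed.
#' @return Pruned `phylo` object.
#' @export
prune_tree <- function(tree, max_leaves = 50, keep = character(0),
                       seed = NULL) {
  assert_that(!is.null(tree$edge.length), "tree must have branch lengths")
  local_seed(seed)
  while (length(tree$tip.label) > max_leaves) {
    d <- ape::cophenetic.phylo(tree)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    pair <- rownames(d)[idx]
    removable <- setdiff(pair, keep)
    if (length(removable) == 0L) {
      # both protected: fall back to the next closest unprotected pair
      cand <- setdiff(rownames(d), keep)
      assert_that(length(cand) > 0, "cannot prune below the protected set")
      sub <- d[cand, , drop = FALSE]
      idx2 <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      removable <- cand[idx2[1]]
    }
    drop <- if (length(removable) == 1L) removable else sample(removable, 1L)
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}

codon_index <- function(codons) {
  idx <- match(codons, SENSE_CODONS)
  idx[is.na(idx)] <- NA_integer_
  idx
}

# base-index triplets of the 61 sense codons, built once
sense_codon_bases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- cbind(
        match(substr(SENSE_CODONS, 1, 1), DNA_BASES),
        match(substr(SENSE_CODONS, 2, 2), DNA_BASES),
        match(substr(SENSE_CODONS, 3, 3), DNA_BASES)
      )
    }
    cache
  }
})

# F1x4 codon frequencies from the non-gap characters of an alignment.
f1x4_frequencies <- function(rows) {
  chars <- strsplit(paste(rows, collapse = ""), "")[[1]]
  counts <- tabulate(match(chars, DNA_BASES), 4) + 1  # pseudocount
  f <- counts / sum(counts)
  cb <- sense_codon_bases()
  pi <- f[cb[, 1]] * f[cb[, 2]] * f[cb[, 3]]
  pi / sum(pi)
}

#' dN/dS likelihood-ratio test on a codon alignment
#'
#' Fits the codon substitution model twice -- once with omega fixed at 1 and
#' once with omega free -- and reports the log-likelihood difference
#' (clamped at zero when the fixed model is at least as likely). Gapped or
#' ambiguous codons are treated as missing data. ORFs that overlap annotated
#' CDS should not be passed here; the caller emits a missing value for them.
#'
#' @param aln A `codon_alignment` (see [preprocess_alignment()]).
#' @param tree `phylo` object whose leaves include the alignment species.
#' @param kappa Transition/transversion rate ratio (fixed, not estimated).
#' @param omega_bounds,scale_bounds Search intervals for the free omega and
#'   the global branch-length multiplier.
#' @param tol Golden-section search tolerance (log scale).
#' @return One-row tibble: `lnl_fixed`, `lnl_free`, `omega_hat`,
#'   `loglik_diff`, `n_species`, `n_codons`. All-`NA` statistics when no two
#'   species share an ungapped codon (missing-value marker).
#' @export
dnds_loglik_test <- function(aln, tree, kappa = 2,
                             omega_bounds = c(1e-4, 20),
                             scale_bounds = c(1e-4, 100), tol = 0.05) {
  species <- intersect(names(aln$rows), tree$tip.label)
  assert_that(all(names(aln$rows) %in% tree$tip.label),
              "tree is missing alignment species")
  na_row <- function() tibble::tibble(
    lnl_fixed = NA_real_, lnl_free = NA_real_, omega_hat = NA_real_,
    loglik_diff = NA_real_, n_species = length(species),
    n_codons = nchar(aln$rows[[1]]) %/% 3L
  )
  if (length(species) < 2L) return(na_row())
  tr <- if (length(species) == length(tree$tip.label)) tree else
    ape::keep.tip(tree, species)
  if (is.null(attr(tr, "order")) || attr(tr, "order") != "postorder") {
    tr <- ape::reorder.phylo(tr, "postorder")
  }
  ncod <- nchar(aln$rows[[1]]) %/% 3L
  states <- matrix(as.integer(unlist(lapply(tr$tip.label, function(sp) {
    codon_index(split_codons(aln$rows[[sp]]))
  }))), nrow = length(tr$tip.label), byrow = TRUE)
  # at least one codon column with >= 2 observed species
  obs <- colSums(!is.na(states))
  if (!any(obs >= 2)) return(na_row())
  cstates <- states - 1L
  cstates[is.na(cstates)] <- -1L
  pi <- f1x4_frequencies(aln$rows[species])
  res <- cpp_codon_lrt(
    cstates, pi, codon_change_type(), kappa,
    tr$edge, tr$edge.length, length(tr$tip.label),
    omega_bounds[1], omega_bounds[2], scale_bounds[1], scale_bounds[2], tol
  )
  tibble::new_tibble(list(
    lnl_fixed = res$lnl_fixed, lnl_free = res$lnl_free,
    omega_hat = res$omega_hat,
    loglik_diff = max(res$lnl_free - res$lnl_fixed, 0),
    n_species = length(species), n_codons = ncod
  ), nrow = 1L)
}

# Direct likelihood evaluation at given (omega, scale); used by tests and
# by the grid oracle.
codon_loglik <- function(aln, tree, omega, scale, kappa = 2) {
  species <- names(aln$rows)
  tr <- ape::keep.tip(tree, intersect(species, tree$tip.label))
  tr <- ape::reorder.phylo(tr, "postorder")
  ncod <- nchar(aln$rows[[1]]) %/% 3L
  states <- matrix(as.integer(unlist(lapply(tr$tip.label, function(sp) {
    codon_index(split_codons(aln$rows[[sp]]))
  }))), nrow = length(tr$tip.label), byrow = TRUE)
  cstates <- states - 1L
  cstates[is.na(cstates)] <- -1L
  pi <- f1x4_frequencies(aln$rows)
  cpp_codon_loglik(cstates, pi, codon_change_type(), kappa, omega, scale,
                   tr$edge, tr$edge.length, length(tr$tip.label))
}

# Transition probability matrix of the codon model (61 x 61), exposed for
# the simulator and for exhaustive-summation oracles.
codon_pmat <- function(pi, kappa, omega, t) {
  cpp_codon_pmat(pi, codon_change_type(), kappa, omega, t)
}
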