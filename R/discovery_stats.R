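# Headline statistics: empirical FDR and q-values of sRNA-ORF coding scores
# against the mock-ORF null, the excess-over-null coding count C with the
# truncation rule T', the fluctuation-corrected C' with a 95% CI from mock
# subsets, per-overlap-category combination, and the fraction of sRNAs with
# at least one coding ORF. Plus the intergenic pseudogene filter and the
# expression-enrichment rule.

#' Empirical FDR curve of sRNA-ORF scores against mock scores
#'
#' For every distinct observed score threshold T (score comparisons use
#' `>=`), with S sRNA ORFs of which `S_T` score at least T and M mocks of
#' which `M_T` score at least T:
#' \deqn{FDR_T = (M_T / M) / (S_T / S)}
#' and the q-value at T is the Storey running minimum over the thresholds
#' at or below T (the rejection regions that contain an ORF scoring T):
#' \deqn{q_T = \min_{T' \le T} FDR_{T'},}
#' so q is non-increasing in more stringent thresholds. FDR and q are
#' capped at 1 for reporting; the uncapped FDR is used inside the running
#' minimum. Thresholds attained only by mocks above every sRNA-ORF score
#' have `S_T = 0`; their FDR is undefined (`NA`) and skipped in the
#' minimum. Inputs should be in-frame-merged ORF scores (see
#' [merge_inframe_overlaps()]).
#'
#' @param s_scores Numeric vector of sRNA-ORF coding scores.
#' @param m_scores Numeric vector of mock-ORF coding scores.
#' @return Object of class `fdr_curve`: a tibble with columns `threshold`
#'   (descending), `s_t`, `m_t`, `fdr_raw`, `fdr`, `q`, plus attributes
#'   `S` and `M`.
#' @export
empirical_fdr <- function(s_scores, m_scores) {
  assert_that(length(s_scores) > 0 && length(m_scores) > 0,
              "both score vectors must be non-empty")
  S <- length(s_scores); M <- length(m_scores)
  thr <- sort(unique(c(s_scores, m_scores)), decreasing = TRUE)
  # counts of scores >= threshold, vectorized over descending thresholds
  s_t <- vapply(thr, function(t) sum(s_scores >= t), numeric(1))
  m_t <- vapply(thr, function(t) sum(m_scores >= t), numeric(1))
  fdr_raw <- ifelse(s_t > 0, (m_t / M) / (s_t / S), NA_real_)
  # thresholds are in descending order; the Storey minimum at row i runs
  # over rows i..n (thresholds at or below threshold i)
  safe <- ifelse(is.na(fdr_raw), Inf, fdr_raw)
  q <- pmin(rev(cummin(rev(safe))), 1)
  out <- tibble::tibble(
    threshold = thr, s_t = s_t, m_t = m_t,
    fdr_raw = fdr_raw, fdr = pmin(fdr_raw, 1), q = q
  )
  structure(out, class = c("fdr_curve", class(out)), S = S, M = M)
}

#' Raw excess-over-null coding count with truncation rule
#'
#' The truncation threshold is the largest t with
#' \eqn{S_t - (M_t / M) S \le -1} (negative coding signal above background);
#' the raw count is \eqn{C = max_{T > T'} S_T (1 - q_T)}, taken over
#' thresholds strictly greater than T' (0 when no threshold is admissible).
#'
#' @param curve An `fdr_curve`.
#' @return List with `c_raw`, `t_prime` (`-Inf` when no threshold triggers
#'   truncation) and `t_star` (the arg-max threshold, `NA` if none).
#' @export
estimate_coding_count <- function(curve) {
  S <- attr(curve, "S"); M <- attr(curve, "M")
  signal <- curve$s_t - (curve$m_t / M) * S
  trig <- which(signal <= -1)
  t_prime <- if (length(trig) > 0) max(curve$threshold[trig]) else -Inf
  adm <- curve$threshold > t_prime
  vals <- curve$s_t * (1 - curve$q)
  vals[!adm] <- -Inf
  if (all(!is.finite(vals))) {
    return(list(c_raw = 0, t_prime = t_prime, t_star = NA_real_))
  }
  best <- which.max(vals)
  c_raw <- max(vals[best], 0)
  list(c_raw = c_raw, t_prime = t_prime,
       t_star = if (c_raw > 0) curve$threshold[best] else NA_real_)
}

#' Fluctuation-corrected coding-count estimate C' with 95% CI
#'
#' Draws `n_subsets` random subsets of the mock scores, each of size
#' `length(s_scores)`, runs each subset through the same FDR / truncation /
#' maximization machinery against the remaining mocks (the false-positive
#' distribution), and subtracts the mean subset estimate:
#' \eqn{C' = C - mean_i C_i}, with the 95% CI `+/- 1.96 sd` of the subset
#' estimates.
#'
#' @inheritParams empirical_fdr
#' @param n_subsets Number of mock subsets.
#' @param seed Optional seed.
#' @return Object of class `coding_estimate`: list with `c_raw`, `t_prime`,
#'   `t_star`, `c_corrected`, `ci95`, `subset_estimates`, `curve`, `S`, `M`.
#' @export
correct_fluctuation <- function(s_scores, m_scores, n_subsets = 20,
                                seed = NULL) {
  assert_that(length(m_scores) > length(s_scores),
              "need more mock scores than sRNA-ORF scores")
  local_seed(seed)
  curve <- empirical_fdr(s_scores, m_scores)
  est <- estimate_coding_count(curve)
  n_s <- length(s_scores)
  subset_est <- vapply(seq_len(n_subsets), function(i) {
    pick <- sample.int(length(m_scores), n_s)
    sub_curve <- empirical_fdr(m_scores[pick], m_scores[-pick])
    estimate_coding_count(sub_curve)$c_raw
  }, numeric(1))
  structure(
    list(c_raw = est$c_raw, t_prime = est$t_prime, t_star = est$t_star,
         c_corrected = est$c_raw - mean(subset_est),
         ci95 = 1.96 * stats::sd(subset_est),
         subset_estimates = subset_est, curve = curve,
         S = length(s_scores), M = length(m_scores)),
    class = "coding_estimate"
  )
}

#' @export
print.coding_estimate <- function(x, ...) {
  cat(sprintf(
    "Coding-ORF estimate: C' = %.1f +/- %.1f (C = %.1f, S = %d, M = %d)\n",
    x$c_corrected, x$ci95, x$c_raw, x$S, x$M))
  invisible(x)
}

#' @method tidy coding_estimate
#' @export
tidy.coding_estimate <- function(x, ...) {
  tibble::tibble(
    c_raw = x$c_raw, c_corrected = x$c_corrected, ci95 = x$ci95,
    t_prime = x$t_prime, t_star = x$t_star, S = x$S, M = x$M
  )
}

#' @method glance coding_estimate
#' @export
glance.coding_estimate <- function(x, ...) tidy(x)

#' Combine per-overlap-category coding estimates
#'
#' The total is the sum of the per-category corrected counts; the CI comes
#' from the standard deviation of the *summed* per-subset estimates, so the
#' per-category `coding_estimate`s must have been computed with the same
#' number of mock subsets.
#'
#' @param estimates Named list of `coding_estimate` objects (names are
#'   overlap categories).
#' @return Tibble with one row per category plus a `total` row
#'   (`c_corrected`, `ci95`).
#' @export
combine_categories <- function(estimates) {
  if (length(estimates) == 0L) {
    return(tibble::tibble(category = "total", c_corrected = 0, ci95 = 0))
  }
  per <- purrr::imap(estimates, function(e, nm) {
    tibble::tibble(category = nm, c_corrected = e$c_corrected, ci95 = e$ci95)
  })
  ns <- vapply(estimates, function(e) length(e$subset_estimates), numeric(1))
  assert_that(length(unique(ns)) == 1L,
              "per-category subset counts must align")
  sums <- rowSums(vapply(estimates, function(e) e$subset_estimates,
                         numeric(ns[1])))
  total <- tibble::tibble(
    category = "total",
    c_corrected = sum(vapply(estimates, function(e) e$c_corrected, numeric(1))),
    ci95 = if (length(estimates) > 1L) 1.96 * stats::sd(sums) else estimates[[1]]$ci95
  )
  dplyr::bind_rows(dplyr::bind_rows(per), total)
}

#' Fraction of sRNAs containing at least one coding ORF
#'
#' Repeatedly samples which particular ORFs are the coding ones: each draw
#' picks `round(C)` ORFs per category from that category's eligible pool
#' (ORFs scoring at or above the category's optimal threshold `t_star`,
#' extended down the score ranking when fewer than `C` qualify), takes the
#' union across categories, and counts the sRNAs containing at least one
#' drawn ORF.
#'
#' @param orfs ORF tibble with `orf_id`, `parent_id`, `coding_score`,
#'   `overlap_class`.
#' @param n_srnas Total number of annotated sRNAs.
#' @param estimates Named list of `coding_estimate`s keyed by overlap
#'   category (as in [combine_categories()]).
#' @param n_draws Number of random draws.
#' @param seed Optional seed.
#' @return Tibble with `fraction`, `ci95`, `mean_srnas`, `n_draws`.
#' @export
fraction_srnas_coding <- function(orfs, n_srnas, estimates, n_draws = 100,
                                  seed = NULL) {
  local_seed(seed)
  assert_that(n_srnas > 0, "n_srnas must be positive")
  pools <- purrr::imap(estimates, function(e, cat) {
    sub <- orfs[orfs$overlap_class == cat, , drop = FALSE]
    sub <- sub[order(-sub$coding_score), , drop = FALSE]
    c_i <- max(0, min(round(e$c_corrected), nrow(sub)))
    if (c_i == 0) return(NULL)
    n_pool <- if (is.na(e$t_star)) c_i else
      max(sum(sub$coding_score >= e$t_star), c_i)
    list(ids = sub$orf_id[seq_len(n_pool)],
         parents = sub$parent_id[seq_len(n_pool)], draw = c_i)
  })
  pools <- pools[!vapply(pools, is.null, logical(1))]
  if (length(pools) == 0L) {
    return(tibble::tibble(fraction = 0, ci95 = 0, mean_srnas = 0,
                          n_draws = n_draws))
  }
  counts <- vapply(seq_len(n_draws), function(d) {
    hit <- unlist(lapply(pools, function(p) {
      p$parents[sample.int(length(p$ids), p$draw)]
    }))
    length(unique(hit))
  }, numeric(1))
  frac <- counts / n_srnas
  tibble::tibble(fraction = mean(frac), ci95 = 1.96 * stats::sd(frac),
                 mean_srnas = mean(counts), n_draws = n_draws)
}

#' Remove likely pseudogene ORFs (positive-selection filter)
#'
#' Intergenic ORFs with \eqn{\hat\omega > 1} and a log-likelihood difference
#' of at least `min_loglik` show signal for positive selection and are
#' removed as likely out-of-frame ORFs in unannotated pseudogenes. A column
#' `blast_filter_pending` flags that the homology-based (>100 aa BLAST hit)
#' pseudogene rule is a separate, external screen not applied here.
#'
#' @param orfs ORF tibble with columns `omega_hat` and `loglik_diff`
#'   (`NA`s are kept).
#' @param min_loglik Log-likelihood-difference cutoff.
#' @return Filtered tibble with the flag column added.
#' @export
pseudogene_filter <- function(orfs, min_loglik = 3) {
  drop <- !is.na(orfs$omega_hat) & !is.na(orfs$loglik_diff) &
    orfs$omega_hat > 1 & orfs$loglik_diff >= min_loglik
  out <- orfs[!drop, , drop = FALSE]
  out$blast_filter_pending <- TRUE
  out
}

#' Expression-condition enrichment of coding sRNA ORFs
#'
#' A condition is called enriched when the number of coding ORFs highly
#' expressed in it is at least `fold` times the expectation under *every*
#' supplied control-set type and at least `min_count`. The expectation per
#' control type is the mean count over its control sets; a normal-based 95%
#' CI (`+/- 1.96 sd`) is reported.
#'
#' @param coding_features Character vector of expression-feature ids that
#'   contain a predicted coding ORF.
#' @param control_sets List of control types; each a list of character
#'   vectors of feature ids (one per control set).
#' @param condition_table Tibble with columns `feature_id`, `condition`
#'   (features annotated as highly expressed per condition).
#' @param fold Fold-enrichment threshold.
#' @param min_count Minimum observed coding count.
#' @return Tibble per condition: `observed`, one `expected_*`/`ci95_*` pair
#'   per control type, `enriched`.
#' @export
expression_enrichment <- function(coding_features, control_sets,
                                  condition_table, fold = 1.5,
                                  min_count = 5) {
  conds <- unique(condition_table$condition)
  if (is.null(names(control_sets))) {
    names(control_sets) <- paste0("control", seq_along(control_sets))
  }
  rows <- lapply(conds, function(cn) {
    feats <- condition_table$feature_id[condition_table$condition == cn]
    obs <- sum(coding_features %in% feats)
    stats_per <- lapply(control_sets, function(sets) {
      cnt <- vapply(sets, function(ids) sum(ids %in% feats), numeric(1))
      c(mean = mean(cnt), ci = 1.96 * stats::sd(cnt))
    })
    ok <- all(vapply(stats_per, function(s) obs >= fold * s[["mean"]],
                     logical(1))) && obs >= min_count
    out <- tibble::tibble(condition = cn, observed = obs, enriched = ok)
    for (nm in names(stats_per)) {
      out[[paste0("expected_", nm)]] <- stats_per[[nm]][["mean"]]
      out[[paste0("ci95_", nm)]] <- stats_per[[nm]][["ci"]]
    }
    out
  })
  dplyr::bind_rows(rows)
}
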