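test_that("the FDR curve reproduces the worked example", {
  cv <- empirical_fdr(c(0.9, 0.8, 0.2), c(0.5, 0.4, 0.3))
  at <- function(t) cv[cv$threshold == t, ]
  expect_equal(at(0.8)$s_t, 2)
  expect_equal(at(0.8)$m_t, 0)
  expect_equal(at(0.8)$fdr, 0)
  expect_equal(at(0.8)$q, 0)
  expect_equal(at(0.5)$fdr, 0.5)
  expect_equal(at(0.2)$q, 1)
  est <- estimate_coding_count(cv)
  expect_equal(est$c_raw, 2)
  expect_equal(est$t_star, 0.8)
  # truncation by the printed rule: S_t - (M_t/M) S = -1 at t = 0.3
  expect_equal(est$t_prime, 0.3)
})

test_that("identical score multisets give FDR 1 and a zero coding count", {
  s <- c(0.1, 0.4, 0.4, 0.9)
  cv <- empirical_fdr(s, s)
  expect_true(all(cv$fdr == 1))
  expect_equal(estimate_coding_count(cv)$c_raw, 0)
})

test_that("q-values are monotone and the scan matches the brute-force oracle", {
  set.seed(51)
  for (rep in 1:200) {
    ns <- sample(5:80, 1)
    nm <- sample(5:160, 1)
    digits <- sample(1:3, 1)  # coarse scores exercise ties
    s <- round(runif(ns), digits)
    m <- round(runif(nm), digits)
    cv <- empirical_fdr(s, m)
    # q_T non-increasing as the threshold T increases
    expect_true(all(diff(cv$q) >= -1e-12))  # thresholds stored descending
    oracle <- oracle_fdr_scan(s, m)
    expect_equal(cv$s_t, oracle$st)
    expect_equal(cv$m_t, oracle$mt)
    expect_equal(cv$q, oracle$q)
    est <- estimate_coding_count(cv)
    want <- oracle_coding_count(s, m)
    expect_equal(est$c_raw, want$c_raw)
    expect_equal(est$t_prime, want$t_prime)
  }
})

test_that("the fluctuation correction is seed-stable and translation-invariant", {
  set.seed(52)
  s <- runif(60)
  m <- runif(400)
  e1 <- correct_fluctuation(s, m, n_subsets = 10, seed = 4)
  e2 <- correct_fluctuation(s, m, n_subsets = 10, seed = 4)
  expect_equal(e1$c_corrected, e2$c_corrected)
  expect_equal(e1$subset_estimates, e2$subset_estimates)
  e3 <- correct_fluctuation(s + 5, m + 5, n_subsets = 10, seed = 4)
  expect_equal(e3$c_corrected, e1$c_corrected)
  expect_equal(e3$ci95, e1$ci95)
  expect_error(correct_fluctuation(runif(10), runif(5)), "more mock")
})

test_that("null draws from the mock distribution center C' near zero", {
  set.seed(53)
  cover <- vapply(1:40, function(i) {
    m <- rbeta(800, 1, 4)
    s <- sample(m, 120)
    e <- correct_fluctuation(s, m, n_subsets = 15, seed = 1000 + i)
    c(e$c_corrected, e$ci95)
  }, numeric(2))
  expect_lt(abs(mean(cover[1, ])), 3)
  expect_gt(mean(abs(cover[1, ]) <= pmax(cover[2, ], 1e-9) + 1e-9), 0.8)
})

test_that("category combination sums estimates and pools subset variance", {
  set.seed(54)
  mk_est <- function(seed) {
    m <- runif(300)
    correct_fluctuation(sample(m, 50), m, n_subsets = 12, seed = seed)
  }
  ests <- list(none = mk_est(1), antisense = mk_est(2))
  comb <- combine_categories(ests)
  tot <- comb[comb$category == "total", ]
  expect_equal(tot$c_corrected,
               ests$none$c_corrected + ests$antisense$c_corrected)
  sums <- ests$none$subset_estimates + ests$antisense$subset_estimates
  expect_equal(tot$ci95, 1.96 * sd(sums))
  one <- combine_categories(ests["none"])
  expect_equal(one$c_corrected[one$category == "total"],
               ests$none$c_corrected)
  empty <- combine_categories(list())
  expect_equal(empty$c_corrected, 0)
  expect_equal(empty$ci95, 0)
})

test_that("the sRNA coding fraction behaves on degenerate inputs", {
  orfs <- tibble::tibble(
    orf_id = sprintf("o%d", 1:10), parent_id = sprintf("s%d", 1:10),
    coding_score = seq(1, 0.1, length.out = 10), overlap_class = "none"
  )
  est0 <- list(none = structure(list(c_corrected = 0, t_star = 0.9,
                                     subset_estimates = rep(0, 5)),
                                class = "coding_estimate"))
  f0 <- fraction_srnas_coding(orfs, 20, est0, n_draws = 10, seed = 1)
  expect_equal(f0$fraction, 0)

  # one ORF per sRNA: the fraction is exactly C / n_srnas
  est4 <- list(none = structure(list(c_corrected = 4, t_star = 0.7,
                                     subset_estimates = rep(0, 5)),
                                class = "coding_estimate"))
  f4 <- fraction_srnas_coding(orfs, 10, est4, n_draws = 25, seed = 2)
  expect_equal(f4$fraction, 0.4)
  expect_equal(f4$ci95, 0)

  # multi-ORF sRNAs: mean unique parents matches a hypergeometric-style
  # expectation within the reported CI
  orfs2 <- orfs
  orfs2$parent_id <- rep(c("sA", "sB", "sC", "sD", "sE"), each = 2)
  est_all <- list(none = structure(list(c_corrected = 4, t_star = 0,
                                        subset_estimates = rep(0, 5)),
                                   class = "coding_estimate"))
  f2 <- fraction_srnas_coding(orfs2, 5, est_all, n_draws = 400, seed = 3)
  # E[unique parents of 4 draws from 5 pairs] = 5 (1 - choose(8,4)/choose(10,4))
  expected <- 5 * (1 - choose(8, 4) / choose(10, 4)) / 5
  expect_lt(abs(f2$fraction - expected), 0.05)
})

test_that("the pseudogene filter removes only positive-selection ORFs", {
  orfs <- tibble::tibble(
    orf_id = c("a", "b", "c", "d"),
    omega_hat = c(1.5, 1.5, 0.3, NA),
    loglik_diff = c(3.2, 2.0, 10, NA)
  )
  out <- pseudogene_filter(orfs)
  expect_setequal(out$orf_id, c("b", "c", "d"))
  expect_true(all(out$blast_filter_pending))
})

test_that("expression enrichment applies the fold and count rules", {
  cond <- tibble::tibble(
    feature_id = c(paste0("f", 1:8), paste0("g", 1:8)),
    condition = rep(c("biofilm", "exponential"), each = 8)
  )
  controls <- list(
    mock = list(paste0("f", 1:2), paste0("f", 1:4)),      # mean 3 in biofilm
    noncoding = list(paste0("f", 1:3), paste0("f", 1:4))  # mean 3.5
  )
  coding <- paste0("f", 1:6)  # 6 observed in biofilm, 0 in exponential
  out <- expression_enrichment(coding, controls, cond)
  bio <- out[out$condition == "biofilm", ]
  expect_true(bio$enriched)  # 6 >= 1.5 * 3 and 6 >= 1.5 * 3.5 and 6 >= 5
  expect_equal(bio$expected_mock, 3)
  expect_false(out$enriched[out$condition == "exponential"])

  # minimum-count rule: 4 observed never enriches
  out4 <- expression_enrichment(paste0("f", 1:4),
                                list(mock = list(character(0))), cond)
  expect_false(out4$enriched[out4$condition == "biofilm"])
  # fold rule: 6 observed vs expectation 5 fails 1.5x
  out5 <- expression_enrichment(paste0("f", 1:6),
                                list(mock = list(paste0("f", 1:5))), cond)
  expect_false(out5$enriched[out5$condition == "biofilm"])
})
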