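# Toy feature worlds for the bagged-tree classifier.
toy_rows <- function(n, sep = 3, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    orf_id = sprintf("r%04d", 1:(2 * n)),
    sd_score = c(rnorm(n, -sep), rnorm(n, 0)),
    dnds_loglik = c(rnorm(n, sep), rnorm(n, 0)),
    comp_score = plogis(c(rnorm(n, sep), rnorm(n, -sep))),
    category = "none",
    label = rep(c("coding", "noncoding"), each = n)
  )
}

test_that("the training table wires SD scores and missing dN/dS correctly", {
  sim <- simulate_genome(length = 40000, n_cds = 15, seed = 31)
  pos <- sample_positive_subsets(sim$features, sim$genome, c(12L, 20L),
                                 n_sets = 2, seed = 1)
  neg <- sample_mock_orfs(sim$genome, sim$features,
                          tibble::tibble(start = integer(), end = integer()),
                          c(12L, 20L), n_sets = 2, seed = 2)
  # mark one mock as an overlap-category row
  neg[[1]]$overlap_class[1] <- "antisense"
  cds_sd <- stats::setNames(runif(nrow(sim$features), -30, 0),
                            sim$features$id)
  comp <- train_composition_model(pos[[1]]$nt_seq, neg[[1]]$nt_seq)
  dnds <- tibble::tibble(
    orf_id = c(pos[[1]]$orf_id, neg[[1]]$orf_id),
    loglik_diff = seq_along(c(pos[[1]]$orf_id, neg[[1]]$orf_id))
  )
  rows <- build_training_table(pos, neg, cds_sd, shuffled_sd_pool = c(-5, -1),
                               comp_model = comp, dnds = dnds, seed = 3)
  prow <- rows[rows$label == "coding", ]
  expect_equal(prow$sd_score[1],
               unname(cds_sd[pos[[1]]$parent_id[1]]))
  expect_true(all(rows$sd_score[rows$label == "noncoding"] %in% c(-5, -1)))
  expect_true(all(is.na(rows$dnds_loglik[rows$category != "none"])))
  expect_false(anyNA(rows$dnds_loglik[rows$category == "none" &
                                        rows$orf_id %in% dnds$orf_id]))
})

test_that("separable classes are learned with high out-of-bag accuracy", {
  rows <- toy_rows(150, sep = 3, seed = 32)
  model <- train_bagged_trees(rows, n_bags = 30, seed = 5)
  sc <- coding_scores(model, rows)
  expect_true(all(sc >= 0 & sc <= 1))
  train_acc <- mean((sc > 0.5) == (rows$label == "coding"))
  expect_gte(train_acc, 0.99)
  fresh <- toy_rows(150, sep = 3, seed = 33)
  oob_acc <- mean((coding_scores(model, fresh) > 0.5) ==
                    (fresh$label == "coding"))
  expect_gt(oob_acc, 0.95)
})

test_that("shuffled labels carry no signal", {
  rows <- toy_rows(120, sep = 3, seed = 34)
  set.seed(6)
  rows$label <- sample(rows$label)
  model <- train_bagged_trees(rows, n_bags = 20, seed = 7)
  fresh <- toy_rows(120, sep = 3, seed = 35)
  set.seed(8)
  fresh$label <- sample(fresh$label)
  acc <- mean((coding_scores(model, fresh) > 0.5) == (fresh$label == "coding"))
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("training and scoring are deterministic given the seed", {
  rows <- toy_rows(80, seed = 36)
  m1 <- train_bagged_trees(rows, n_bags = 10, seed = 11)
  m2 <- train_bagged_trees(rows, n_bags = 10, seed = 11)
  expect_identical(coding_scores(m1, rows), coding_scores(m2, rows))
})

test_that("the ensemble score is the mean of individual tree outputs", {
  rows <- toy_rows(100, sep = 1.5, seed = 37)
  model <- train_bagged_trees(rows, n_bags = 15, seed = 12)
  df <- as.data.frame(rows[model$feature_cols])
  manual <- rowMeans(vapply(model$trees, function(tr) {
    unname(predict(tr, df, type = "prob")[, "coding"])
  }, numeric(nrow(df))))
  expect_equal(unname(coding_scores(model, rows)), unname(manual))
})

test_that("missing features are routed, not dropped, at prediction time", {
  rows <- toy_rows(120, sep = 3, seed = 38)
  rows$dnds_loglik[rows$category == "none"][1:40] <- NA
  model <- train_bagged_trees(rows, n_bags = 15, seed = 13)
  probe <- toy_rows(10, sep = 3, seed = 39)
  probe$dnds_loglik <- NA_real_
  sc <- coding_scores(model, probe)
  expect_length(sc, 20)
  expect_false(anyNA(sc))
  expect_gt(mean(sc[probe$label == "coding"]),
            mean(sc[probe$label == "noncoding"]))
})

test_that("cross-validated background scoring scores every mock exactly once", {
  mocks <- toy_rows(60, seed = 40)
  mocks <- mocks[mocks$label == "noncoding", ]
  pos <- toy_rows(60, seed = 41)
  pos <- pos[pos$label == "coding", ]
  sc <- background_scores_cv(mocks, pos, k = 10, n_bags = 8, seed = 14)
  expect_length(sc, nrow(mocks))
  expect_false(anyNA(sc))
  expect_equal(names(sc), mocks$orf_id)
  # leave-one-out also runs
  small_m <- mocks[1:12, ]
  loo <- background_scores_cv(small_m, pos, k = 12, n_bags = 5, seed = 15)
  expect_length(loo, 12)
  # mocks sit stochastically below positives on separable data
  expect_lt(mean(sc), 0.5)
})

test_that("bagging does not do worse than a single tree out of bag", {
  errs <- vapply(1:8, function(s) {
    rows <- toy_rows(100, sep = 1, seed = 100 + s)
    fresh <- toy_rows(100, sep = 1, seed = 200 + s)
    bag <- train_bagged_trees(rows, n_bags = 20, seed = s)
    single <- train_bagged_trees(rows, n_bags = 1, seed = s)
    c(bag = mean((coding_scores(bag, fresh) > 0.5) !=
                   (fresh$label == "coding")),
      single = mean((coding_scores(single, fresh) > 0.5) !=
                      (fresh$label == "coding")))
  }, numeric(2))
  expect_lte(mean(errs["bag", ]), mean(errs["single", ]) + 0.01)
})
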