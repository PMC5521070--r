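# The coding-score classifier: a cost-sensitive bagged decision-tree
# ensemble over the three sequence features (SD score, dN/dS log-likelihood
# difference, composition score). Base learners are CART trees (rpart) grown
# on bootstrap resamples with class weights balancing the two labels;
# each tree is pruned by selecting the cost-complexity level with minimum
# out-of-bag error (a reduced-error pruning analogue). Missing feature
# values (dN/dS for overlap categories, SD at genome edges) are routed by
# CART surrogate splits at training and prediction time.

FEATURE_COLS <- c("sd_score", "dnds_loglik", "comp_score")

#' Assemble the three-feature training table from control sets
#'
#' Positive rows are the annotated-ORF subsets; each carries the *real* SD
#' score of the annotated ORF containing the subset. Negative rows are the
#' mock ORFs; each is matched to a randomly drawn shuffled-upstream SD score
#' from the supplied background pool. Composition scores are computed from
#' each row's nucleotide sequence with `comp_model`. dN/dS statistics are
#' looked up by `orf_id` in `dnds` and are `NA` for every row whose
#' `overlap_class != "none"` (and for ids absent from the table).
#'
#' @param positive_sets,negative_sets Lists of ORF-candidate tibbles
#'   (provenance `annotated_subset` / `mock`).
#' @param cds_sd Named numeric vector: real SD `delta_g` per CDS id.
#' @param shuffled_sd_pool Numeric vector of shuffled-upstream SD `delta_g`
#'   values (the composition-matched background).
#' @param comp_model A `composition_model`.
#' @param dnds Optional tibble with columns `orf_id`, `loglik_diff`.
#' @param seed Optional seed (for the random shuffled-SD matching).
#' @return Tibble of feature rows: `orf_id`, `set`, `sd_score`,
#'   `dnds_loglik`, `comp_score`, `category`, `label`.
#' @export
build_training_table <- function(positive_sets, negative_sets, cds_sd,
                                 shuffled_sd_pool, comp_model, dnds = NULL,
                                 seed = NULL) {
  local_seed(seed)
  assert_that(length(positive_sets) == length(negative_sets),
              "positive and negative set lists must be the same length")
  one_set <- function(orfs, set_i, label) {
    if (label == "coding") {
      sd <- unname(cds_sd[orfs$parent_id])
      if (anyNA(sd)) stop("positive subset parent CDS without SD score",
                          call. = FALSE)
    } else {
      sd <- sample(shuffled_sd_pool, nrow(orfs), replace = TRUE)
    }
    tibble::tibble(
      orf_id = orfs$orf_id, set = set_i, sd_score = sd,
      dnds_loglik = NA_real_,
      comp_score = score_composition(comp_model, comp_sequence(orfs)),
      category = orfs$overlap_class, label = label
    )
  }
  rows <- dplyr::bind_rows(
    purrr::imap(positive_sets, ~ one_set(.x, .y, "coding")),
    purrr::imap(negative_sets, ~ one_set(.x, .y, "noncoding"))
  )
  if (!is.null(dnds)) {
    lut <- stats::setNames(dnds$loglik_diff, dnds$orf_id)
    hit <- rows$category == "none" & rows$orf_id %in% names(lut)
    rows$dnds_loglik[hit] <- unname(lut[rows$orf_id[hit]])
  }
  rows$dnds_loglik[rows$category != "none"] <- NA_real_
  rows
}

#' Train the cost-sensitive bagged decision-tree classifier
#'
#' @param rows Feature tibble with columns `sd_score`, `dnds_loglik`,
#'   `comp_score` and `label` (`coding` / `noncoding`); both labels must be
#'   present. Rows with every feature missing are dropped.
#' @param n_bags Number of bootstrap trees.
#' @param min_bucket Minimum observations in a leaf.
#' @param seed Optional seed.
#' @return Object of class `bagged_trees`.
#' @export
train_bagged_trees <- function(rows, n_bags = 100, min_bucket = 2,
                               seed = NULL) {
  local_seed(seed)
  rows <- rows[rowSums(!is.na(rows[FEATURE_COLS])) > 0, , drop = FALSE]
  lab <- factor(rows$label, levels = c("noncoding", "coding"))
  assert_that(nlevels(droplevels(lab)) == 2L,
              "both labels must be present in the training data")
  df <- as.data.frame(rows[FEATURE_COLS])
  df$label <- lab
  n <- nrow(df)
  class_w <- n / (2 * table(lab))
  w_all <- as.numeric(class_w[lab])
  trees <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    fit <- rpart::rpart(
      label ~ sd_score + dnds_loglik + comp_score,
      data = df[idx, , drop = FALSE], weights = w_all[idx],
      method = "class",
      control = rpart::rpart.control(cp = 0, minsplit = 2 * min_bucket,
                                     minbucket = min_bucket, xval = 0,
                                     maxsurrogate = 3, usesurrogate = 2)
    )
    trees[[b]] <- prune_by_oob(fit, df[oob, , drop = FALSE], w_all[oob])
  }
  structure(
    list(trees = trees, n_bags = n_bags,
         class_weights = as.numeric(class_w),
         n_train = n, feature_cols = FEATURE_COLS),
    class = "bagged_trees"
  )
}

# Reduced-error pruning against held-out (out-of-bag) rows: pick the
# cost-complexity level of the rpart sequence with minimum weighted OOB
# misclassification error (ties -> smaller tree).
prune_by_oob <- function(fit, oob_df, oob_w) {
  cps <- fit$cptable[, "CP"]
  if (length(cps) <= 1L || nrow(oob_df) == 0L) return(fit)
  errs <- vapply(seq_along(cps), function(i) {
    pr <- rpart::prune(fit, cp = cps[i] * 1.0000001)
    pred <- predict(pr, oob_df, type = "class")
    sum(oob_w * (pred != oob_df$label))
  }, numeric(1))
  best <- rev(which(errs == min(errs)))[1]  # prefer the most pruned tree
  rpart::prune(fit, cp = cps[best] * 1.0000001)
}

#' Coding scores from a bagged-tree model
#'
#' The score of a row is the mean over trees of the `coding`-class leaf
#' frequency, so it always lies in `[0, 1]`.
#'
#' @param model A `bagged_trees` object.
#' @param rows Feature tibble (columns `sd_score`, `dnds_loglik`,
#'   `comp_score`; `orf_id` optional).
#' @return Numeric vector of scores, named by `orf_id` when present.
#' @export
coding_scores <- function(model, rows) {
  df <- as.data.frame(rows[model$feature_cols])
  preds <- vapply(model$trees, function(tr) {
    predict(tr, df, type = "prob")[, "coding"]
  }, numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  out <- rowMeans(preds)
  if ("orf_id" %in% names(rows)) names(out) <- rows$orf_id
  out
}

#' Cross-validated background scores for mock ORFs
#'
#' Mocks are partitioned into `k` folds; for each fold a bagged model is
#' trained on the remaining folds' mocks plus all positive rows, and scores
#' the held-out fold, so every mock is scored exactly once by a model that
#' never saw it.
#'
#' @param mock_rows Feature tibble of mock (noncoding) rows.
#' @param positive_rows Feature tibble of positive (coding) rows.
#' @param k Number of folds.
#' @param n_bags Trees per fold model.
#' @param seed Optional seed.
#' @return Numeric vector of scores aligned with `mock_rows` (named by
#'   `orf_id` when present).
#' @export
background_scores_cv <- function(mock_rows, positive_rows, k = 10,
                                 n_bags = 100, seed = NULL) {
  local_seed(seed)
  n <- nrow(mock_rows)
  assert_that(n >= k, "need at least k mock rows")
  fold <- sample(rep(seq_len(k), length.out = n))
  out <- numeric(n)
  seeds <- derive_seeds(stats::runif(1, 1, 2^30), k)
  for (f in seq_len(k)) {
    train <- dplyr::bind_rows(mock_rows[fold != f, , drop = FALSE],
                              positive_rows)
    m <- train_bagged_trees(train, n_bags = n_bags, seed = seeds[[f]])
    out[fold == f] <- coding_scores(m, mock_rows[fold == f, , drop = FALSE])
  }
  if ("orf_id" %in% names(mock_rows)) names(out) <- mock_rows$orf_id
  out
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("Bagged decision-tree coding classifier: %d trees, %d training rows\n",
              x$n_bags, x$n_train))
  invisible(x)
}

#' @method glance bagged_trees
#' @export
glance.bagged_trees <- function(x, ...) {
  sizes <- vapply(x$trees, function(tr) sum(tr$frame$var == "<leaf>"),
                  numeric(1))
  tibble::tibble(n_bags = x$n_bags, n_train = x$n_train,
                 mean_leaves = mean(sizes))
}
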