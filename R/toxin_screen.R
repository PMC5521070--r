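# Type I toxin screen: physicochemical features of candidate small
# proteins, a transmembrane-helix screen, greedy identity clustering, and a
# small random-forest classifier trained with 1:20 length-matched
# negatives. The conformational/aggregation propensities are window
# statistics over published per-residue scales (Kyte-Doolittle hydropathy,
# Chou-Fasman secondary-structure propensities); they play the same feature
# roles as dedicated structure predictors without claiming per-tool
# concordance.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

CF_HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)

CF_STRAND <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
  I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
  R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47
)

CF_TURN <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60, G = 1.56, H = 0.95,
  I = 0.47, K = 1.01, L = 0.59, M = 0.60, N = 1.56, P = 1.52, Q = 0.98,
  R = 0.95, S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14
)

# side-chain and termini pKa values (fixed table)
PKA_SIDE <- c(C = 8.3, D = 3.65, E = 4.25, H = 6.0, K = 10.53, R = 12.48,
              Y = 10.07)
PKA_NTERM <- 9.0
PKA_CTERM <- 2.0

aa_vector <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (any(!aa %in% AA20)) {
    stop("peptide contains a nonstandard amino acid", call. = FALSE)
  }
  aa
}

window_means <- function(vals, window) {
  n <- length(vals)
  if (n < window) return(mean(vals))
  stats::filter(vals, rep(1 / window, window), sides = 1)[window:n]
}

net_charge <- function(aa, ph) {
  pos <- PKA_NTERM
  pos_side <- PKA_SIDE[c("K", "R", "H")]
  neg <- PKA_CTERM
  neg_side <- PKA_SIDE[c("D", "E", "C", "Y")]
  q <- 1 / (1 + 10^(ph - pos)) +
    sum(vapply(names(pos_side), function(a)
      sum(aa == a) / (1 + 10^(ph - pos_side[[a]])), numeric(1)))
  q <- q - 1 / (1 + 10^(neg - ph)) -
    sum(vapply(names(neg_side), function(a)
      sum(aa == a) / (1 + 10^(neg_side[[a]] - ph)), numeric(1)))
  q
}

solve_pi <- function(aa, lo = 0.001, hi = 13.999, tol = 1e-6) {
  f_lo <- net_charge(aa, lo)
  if (f_lo <= 0) return(lo)
  if (net_charge(aa, hi) >= 0) return(hi)
  stats::uniroot(function(p) net_charge(aa, p), c(lo, hi), tol = tol)$root
}

#' Physicochemical features of a peptide
#'
#' Window statistics over published per-residue scales: `helix/strand/turn`
#' propensities are the mean 7-residue-window Chou-Fasman propensity;
#' `aggregation_propensity` is the maximum 7-window Kyte-Doolittle
#' hydropathy (an aggregating-stretch proxy); `helical_aggregation` is the
#' maximum 7-window mean of hydropathy weighted by helix propensity;
#' `gravy` is the whole-chain mean hydropathy; `isoelectric_point` is the
#' bisection root of the Henderson-Hasselbalch net-charge function with a
#' fixed pKa table. Nonstandard residues are an error.
#'
#' @param peptides Character vector of amino-acid sequences.
#' @param window Sliding-window width in residues.
#' @return Tibble with one feature row per peptide.
#' @export
compute_physicochemical <- function(peptides, window = 7) {
  rows <- lapply(peptides, function(p) {
    aa <- aa_vector(p)
    kd <- unname(KD_HYDROPATHY[aa])
    tibble::tibble(
      aggregation_propensity = max(window_means(kd, window)),
      helix_propensity = mean(window_means(unname(CF_HELIX[aa]), window)),
      strand_propensity = mean(window_means(unname(CF_STRAND[aa]), window)),
      turn_propensity = mean(window_means(unname(CF_TURN[aa]), window)),
      helical_aggregation = max(window_means(kd * unname(CF_HELIX[aa]), window)),
      isoelectric_point = solve_pi(aa),
      gravy = mean(kd)
    )
  })
  dplyr::bind_rows(rows)
}

#' Greedy identity clustering of peptides at 90%
#'
#' Sequences are visited longest-first (ties broken lexicographically); a
#' sequence joins an existing cluster when its global pairwise identity to
#' the cluster representative exceeds `identity`, otherwise it founds a new
#' cluster. Cluster representatives are returned.
#'
#' @param seqs Character vector of peptides.
#' @param identity Identity threshold (fraction).
#' @return Character vector of representatives.
#' @export
cluster_90 <- function(seqs, identity = 0.9) {
  if (length(seqs) == 0L) return(character(0))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  reps <- character(0)
  for (s in seqs) {
    joined <- FALSE
    for (r in reps) {
      if (pair_identity(s, r) > identity) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, s)
  }
  reps
}

# global (Needleman-Wunsch) percent identity between two peptides
pair_identity <- local({
  sm <- NULL
  function(a, b) {
    if (a == b) return(1)
    if (is.null(sm)) {
      m <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
      diag(m) <- 1
      sm <<- m
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5
    )
    Biostrings::pid(al, type = "PID1") / 100
  }
})

#' Train the type I toxin random-forest classifier
#'
#' Negatives are drawn from `neg_pool` at exactly 20 per positive with the
#' length distribution of the positives matched exactly; the classifier is
#' a random forest of 10 trees on the physicochemical features. 10-fold
#' cross-validated probabilities, the ROC AUC, and the sensitivity at the
#' `max_fpr` operating point are reported.
#'
#' @param pos Character vector of toxin peptides (10-50 aa).
#' @param neg_pool Character vector of background peptides.
#' @param neg_ratio Negatives per positive.
#' @param n_trees Trees in the forest.
#' @param max_fpr False-positive-rate cap for the reported sensitivity.
#' @param seed Optional seed.
#' @return Object of class `toxin_model` with the fitted forest, feature
#'   table and CV metrics.
#' @export
train_toxin_model <- function(pos, neg_pool, neg_ratio = 20, n_trees = 10,
                              max_fpr = 0.1, seed = NULL) {
  local_seed(seed)
  pos_len <- nchar(pos)
  neg_len <- nchar(neg_pool)
  neg <- character(0)
  for (L in sort(unique(pos_len))) {
    need <- neg_ratio * sum(pos_len == L)
    avail <- which(neg_len == L)
    if (length(avail) < need) {
      stop(sprintf(
        "negative pool has %d peptides of length %d aa; %d required",
        length(avail), L, need), call. = FALSE)
    }
    neg <- c(neg, neg_pool[avail[sample.int(length(avail), need)]])
  }
  X <- compute_physicochemical(c(pos, neg))
  y <- factor(c(rep("toxin", length(pos)), rep("background", length(neg))),
              levels = c("background", "toxin"))
  forest <- randomForest::randomForest(
    x = as.data.frame(X), y = y, ntree = n_trees
  )
  # 10-fold CV probabilities
  k <- 10
  fold <- sample(rep(seq_len(k), length.out = length(y)))
  cv_prob <- numeric(length(y))
  for (f in seq_len(k)) {
    m <- randomForest::randomForest(
      x = as.data.frame(X)[fold != f, , drop = FALSE], y = y[fold != f],
      ntree = n_trees
    )
    cv_prob[fold == f] <- predict(
      m, as.data.frame(X)[fold == f, , drop = FALSE], type = "prob")[, "toxin"]
  }
  roc <- pROC::roc(response = y, predictor = cv_prob, levels = c("background", "toxin"),
                   direction = "<", quiet = TRUE)
  sens <- pROC::coords(roc, x = 1 - max_fpr, input = "specificity",
                       ret = "sensitivity", transpose = FALSE)[["sensitivity"]]
  structure(
    list(forest = forest, features = X, labels = y, cv_prob = cv_prob,
         auc = as.numeric(pROC::auc(roc)),
         cv_sensitivity = as.numeric(sens), max_fpr = max_fpr,
         n_pos = length(pos), neg_ratio = neg_ratio),
    class = "toxin_model"
  )
}

#' Predict toxin probability for peptides
#'
#' @param model A `toxin_model`.
#' @param peptides Character vector.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_toxin <- function(model, peptides) {
  X <- as.data.frame(compute_physicochemical(peptides))
  unname(predict(model$forest, X, type = "prob")[, "toxin"])
}

#' @export
print.toxin_model <- function(x, ...) {
  cat(sprintf(
    "Type I toxin classifier: %d positives, 1:%d negatives; CV AUC %.3f, sensitivity %.2f at FPR <= %.2f\n",
    x$n_pos, x$neg_ratio, x$auc, x$cv_sensitivity, x$max_fpr))
  invisible(x)
}

#' @method glance toxin_model
#' @export
glance.toxin_model <- function(x, ...) {
  tibble::tibble(n_pos = x$n_pos, neg_ratio = x$neg_ratio, auc = x$auc,
                 cv_sensitivity = x$cv_sensitivity, max_fpr = x$max_fpr)
}

#' Transmembrane-helix screen
#'
#' A peptide is flagged when some 19-residue window has mean Kyte-Doolittle
#' hydropathy at or above `cutoff`. Raising the cutoff never increases the
#' number of positives.
#'
#' @param peptides Character vector.
#' @param cutoff Mean-hydropathy threshold.
#' @param window Window width in residues.
#' @return Logical vector.
#' @export
predict_tm_helix <- function(peptides, cutoff = 1.6, window = 19) {
  vapply(peptides, function(p) {
    kd <- unname(KD_HYDROPATHY[aa_vector(p)])
    if (length(kd) < window) return(mean(kd) >= cutoff)
    max(window_means(kd, window)) >= cutoff
  }, logical(1), USE.NAMES = FALSE)
}

#' Excess of transmembrane predictions over control sets
#'
#' @param predictions Logical vector of TM calls for the real peptides.
#' @param control_sets List of logical vectors (one per control set, e.g.
#'   shuffled peptides or length-matched windows of annotated proteins).
#' @return Tibble with `observed`, `expected`, `ci95`, `excess`.
#' @export
tm_excess <- function(predictions, control_sets) {
  obs <- sum(predictions)
  cnt <- vapply(control_sets, sum, numeric(1))
  tibble::tibble(observed = obs, expected = mean(cnt),
                 ci95 = 1.96 * stats::sd(cnt), excess = obs - mean(cnt))
}
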