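# Phase-specific composition bias: the 69-parameter Z-curve transform and a
# ridge-penalized logistic regression returning a coding-likelihood score in
# [0, 1]. ATG codons are removed from every sequence before computing
# frequencies, because mock ORFs are constrained never to start with ATG and
# the start codon would otherwise leak label information.

#' Z-curve composition transform (69 components)
#'
#' Components, computed after removing all ATG codons:
#' * 9 phase-specific mononucleotide components: for each codon position k,
#'   the contrasts x = (fA+fG)-(fC+fT), y = (fA+fC)-(fG+fT),
#'   z = (fA+fT)-(fG+fC) of the base frequencies at that position;
#' * 12 dinucleotide components over codon positions (1,2): for each first
#'   base B, the same three contrasts of the joint frequencies p(B, .);
#' * 48 trinucleotide components: for each first dinucleotide D (16), the
#'   three contrasts of the joint frequencies p(D, .) over whole codons.
#'
#' Every component lies in [-1, 1]. Sequences with fewer than two non-ATG
#' codons return a vector of `NA` (missing-value marker).
#'
#' @param seq DNA string with length divisible by 3.
#' @return Named numeric vector of length 69.
#' @export
zcurve_transform <- function(seq) {
  assert_that(nchar(seq) %% 3 == 0, "sequence length must be divisible by 3")
  codons <- split_codons(toupper(seq))
  codons <- codons[codons != "ATG"]
  nm <- zcurve_names()
  if (length(codons) < 2L || any(!strsplit(paste(codons, collapse = ""), "")[[1]] %in% DNA_BASES)) {
    return(stats::setNames(rep(NA_real_, 69), nm))
  }
  n <- length(codons)
  i1 <- match(substr(codons, 1, 1), DNA_BASES)
  i2 <- match(substr(codons, 2, 2), DNA_BASES)
  i3 <- match(substr(codons, 3, 3), DNA_BASES)
  # contrast rows: x = (A+G)-(C+T), y = (A+C)-(G+T), z = (A+T)-(G+C)
  CM <- matrix(c(1, -1, 1, -1,
                 1, 1, -1, -1,
                 1, -1, -1, 1), nrow = 3, byrow = TRUE)
  f1 <- tabulate(i1, 4) / n
  f2 <- tabulate(i2, 4) / n
  f3 <- tabulate(i3, 4) / n
  mono <- c(CM %*% f1, CM %*% f2, CM %*% f3)
  # joint p(first base, second base) over codon positions (1, 2)
  j12 <- matrix(tabulate((i2 - 1L) * 4L + i1, 16), nrow = 4) / n
  di <- as.vector(apply(j12, 1, function(p) CM %*% p))
  # joint p(first dinucleotide, third base); dinucleotide order matches
  # as.vector(outer(DNA_BASES, DNA_BASES, paste0)): first base fastest
  j123 <- matrix(tabulate(((i3 - 1L) * 16L + (i2 - 1L) * 4L + i1), 64),
                 nrow = 16) / n
  tri <- as.vector(apply(j123, 1, function(p) CM %*% p))
  stats::setNames(c(mono, di, tri), nm)
}

zcurve_names <- function() {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  c(
    paste0(rep(c("x", "y", "z"), 3), "_pos", rep(1:3, each = 3)),
    paste0(rep(c("x", "y", "z"), 4), "_", rep(DNA_BASES, each = 3)),
    paste0(rep(c("x", "y", "z"), 16), "_", rep(dinucs, each = 3))
  )
}

zcurve_matrix <- function(seqs) {
  t(vapply(seqs, zcurve_transform, numeric(69), USE.NAMES = FALSE))
}

# The composition feature is computed on the coding part only: for rows
# whose nt span includes the stop codon (sRNA/intergenic ORFs and their
# span-matched mocks, 3*(aa_length+1) nt) the final codon is dropped, so
# real ORFs, mocks and annotated in-frame subsets are scored on the same
# footing and the terminal stop cannot leak label information.
comp_sequence <- function(orfs) {
  vapply(seq_len(nrow(orfs)), function(i) {
    nt <- orfs$nt_seq[i]
    m <- orfs$aa_length[i]
    if (!is.na(m) && nchar(nt) == 3L * (m + 1L)) substr(nt, 1L, 3L * m) else nt
  }, character(1))
}

#' Train the ridge-penalized logistic composition model
#'
#' Fits a logistic regression of coding status on the 69 Z-curve components
#' by penalized maximum likelihood (penalty `ridge * sum(w^2)` on the
#' coefficients, intercept unpenalized), with classes reweighted to equal
#' total weight when unbalanced. The tiny default ridge only stabilizes the
#' fit under perfect separation.
#'
#' @param pos,neg Character vectors of coding-like and noncoding-like DNA
#'   sequences (lengths divisible by 3).
#' @param ridge Regularization strength.
#' @param max_iter,tol IRLS controls.
#' @return Object of class `composition_model` (weights, intercept, ridge).
#' @export
train_composition_model <- function(pos, neg, ridge = 1e-8,
                                    max_iter = 400, tol = 1e-10) {
  assert_that(length(pos) > 0 && length(neg) > 0,
              "both classes must be non-empty")
  X <- rbind(zcurve_matrix(pos), zcurve_matrix(neg))
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  w <- ifelse(y == 1, length(y) / (2 * sum(y == 1)),
              length(y) / (2 * sum(y == 0)))
  fit <- ridge_logistic_irls(X, y, w, ridge, max_iter, tol)
  structure(
    list(weights = fit$beta[-1], intercept = fit$beta[1], ridge = ridge,
         converged = fit$converged, n_pos = sum(y == 1), n_neg = sum(y == 0),
         convention = "zcurve69/atg-skipped/pos12-dinucleotides"),
    class = "composition_model"
  )
}

# Penalized IRLS with ridge on the slopes only; damped steps if the
# penalized objective worsens.
ridge_logistic_irls <- function(X, y, w, ridge, max_iter, tol) {
  Xa <- cbind(1, X)
  p <- ncol(Xa)
  pen <- diag(c(0, rep(2 * ridge, p - 1L)))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    -sum(w * (y * eta - log1p(exp(eta)))) + ridge * sum(b[-1]^2)
  }
  o_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    W <- w * mu * (1 - mu)
    g <- drop(crossprod(Xa, w * (y - mu))) - c(0, 2 * ridge * beta[-1])
    H <- crossprod(Xa, Xa * W) + pen + diag(1e-12, p)
    step <- solve(H, g)
    lambda <- 1
    repeat {
      b_new <- beta + lambda * step
      o_new <- obj(b_new)
      if (is.finite(o_new) && o_new <= o_old + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { b_new <- beta; o_new <- o_old; break }
    }
    delta <- max(abs(b_new - beta))
    beta <- b_new
    if (abs(o_old - o_new) < tol * (abs(o_old) + 1) && delta < 1e-5) {
      converged <- TRUE
      o_old <- o_new
      break
    }
    o_old <- o_new
  }
  list(beta = beta, converged = converged)
}

#' Score sequences with a composition model
#'
#' @param model A `composition_model`.
#' @param seqs Character vector of DNA sequences.
#' @return Numeric scores in `[0, 1]`; `NA` where the Z-curve transform is
#'   undefined (fewer than two non-ATG codons).
#' @export
score_composition <- function(model, seqs) {
  Z <- zcurve_matrix(seqs)
  drop(stats::plogis(model$intercept + Z %*% model$weights))
}

#' @export
print.composition_model <- function(x, ...) {
  cat("Ridge-logistic Z-curve composition model\n")
  cat(sprintf("  69 components, ridge = %g, trained on %d pos / %d neg\n",
              x$ridge, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy composition_model
#' @export
tidy.composition_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", zcurve_names()),
                 estimate = c(x$intercept, x$weights))
}

#' @method glance composition_model
#' @export
glance.composition_model <- function(x, ...) {
  tibble::tibble(n_pos = x$n_pos, n_neg = x$n_neg, ridge = x$ridge,
                 converged = x$converged)
}
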