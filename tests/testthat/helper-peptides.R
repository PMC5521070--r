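# Synthetic peptide classes: membrane-toxin-like (hydrophobic, cationic)
# versus soluble background (hydrophilic, neutral).
toxin_like <- function(n, len_range = c(20, 40), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- c("L", "I", "V", "F", "A", "K", "R")
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(pool, L, TRUE, prob = c(3, 3, 3, 2, 2, 1.5, 1.5)),
          collapse = "")
  }, character(1))
}
background_like <- function(n, len_range = c(20, 40), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- c("D", "E", "N", "Q", "S", "T", "G", "P", "H", "A")
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(pool, L, TRUE), collapse = "")
  }, character(1))
}

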