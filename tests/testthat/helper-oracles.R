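# Independent oracles and small fixture builders. These re-derive expected
# results by routes deliberately different from the package implementation.

empty_cds <- function() {
  tibble::tibble(seqid = character(), start = integer(), end = integer(),
                 strand = character(), ftype = character(), id = character())
}

mk_genome <- function(seq, id = "g1") {
  tibble::tibble(id = id, seq = toupper(seq), circular = FALSE)
}

mk_feature <- function(start, end, strand = "+", ftype = "cds",
                       id = "f1", seqid = "g1") {
  tibble::tibble(seqid = seqid, start = as.integer(start),
                 end = as.integer(end), strand = strand, ftype = ftype,
                 id = id)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- regex/scan brute-force ORF oracle -------------------------------------
# Enumerates ATG-initiated ORFs on the + strand of `seq` whose ATG starts in
# [region_start, region_end) (0-based), walking character triplets to the
# first in-frame stop; completely independent of the package scanner.
oracle_orfs_plus <- function(seq, region_start, region_end, min_aa, max_aa,
                             extend = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  glen <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  atgs <- unlist(gregexpr("(?=ATG)", seq, perl = TRUE))
  atgs <- atgs[atgs > 0]
  for (a in atgs) {
    s0 <- a - 1L  # 0-based
    if (s0 < region_start || s0 >= region_end) next
    lim <- if (extend) glen else region_end
    p <- s0
    found <- FALSE
    while (p + 3L <= lim) {
      cod <- paste(chars[(p + 1L):(p + 3L)], collapse = "")
      if (p > s0 && cod %in% stops) { found <- TRUE; break }
      p <- p + 3L
    }
    if (!found) next
    e0 <- p + 3L
    aa <- (e0 - s0) %/% 3L - 1L
    if (aa < min_aa || aa > max_aa) next
    nt <- substr(seq, s0 + 1L, e0)
    if (grepl("N", nt)) next
    res[[length(res) + 1L]] <- c(start = s0, end = e0, aa = aa)
  }
  if (length(res) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), aa = integer()))
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, res)))
  out[order(out$start, out$end), ]
}

# ---- overlap-classification oracle -----------------------------------------
# Direct coordinate arithmetic, written independently of classify_overlap.
oracle_overlap <- function(os, oe, ostrand, cds) {
  res <- "none"
  best <- 0L  # 0 none, 1 antisense, 2 outframe, 3 inframe
  for (i in seq_len(nrow(cds))) {
    lo <- max(os, cds$start[i]); hi <- min(oe, cds$end[i])
    if (hi - lo <= 0) next
    if (ostrand != cds$strand[i]) { best <- max(best, 1L); next }
    orf_anchor <- if (ostrand == "+") os %% 3 else oe %% 3
    cds_anchor <- if (cds$strand[i] == "+") cds$start[i] %% 3 else cds$end[i] %% 3
    if (orf_anchor == cds_anchor) {
      # full shared codon on the common grid?
      a <- lo + ((orf_anchor - lo) %% 3)
      if (a + 3 <= hi) { best <- max(best, 3L); next }
    }
    best <- max(best, 2L)
  }
  c("none", "antisense", "sense_outframe", "sense_inframe")[best + 1L]
}

# ---- duplex energy oracles --------------------------------------------------
# Same published energy model as the implementation, but re-derived in R.
ORACLE_STACK <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
), nrow = 6, byrow = TRUE) * 4.184
ORACLE_INIT <- 4.10 * 4.184

oracle_pair_code <- function(x, y) {
  key <- paste0(x, y)
  codes <- c(CG = 1, GC = 2, GU = 3, UG = 4, AU = 5, UA = 6)
  if (key %in% names(codes)) codes[[key]] else NA_integer_
}
oracle_rev_pair <- function(p) c(2, 1, 4, 3, 6, 5)[p]
oracle_stack_e <- function(p1, p2) ORACLE_STACK[p1, oracle_rev_pair(p2)]

# O(n^2 m^2) dynamic program with explicit enumeration of every predecessor
# pair (a different formulation from the package's running-minimum DP).
oracle_duplex_dp <- function(up, asd, loop_penalty = 2.1) {
  a <- strsplit(chartr("T", "U", toupper(up)), "")[[1]]
  b <- rev(strsplit(chartr("T", "U", toupper(asd)), "")[[1]])
  n <- length(a); m <- length(b)
  E <- matrix(Inf, n, m)
  best <- Inf
  for (i in seq_len(n)) for (k in seq_len(m)) {
    p <- oracle_pair_code(a[i], b[k])
    if (is.na(p)) next
    e <- ORACLE_INIT
    if (i > 1 && k > 1) {
      for (i2 in seq_len(i - 1)) for (k2 in seq_len(k - 1)) {
        if (!is.finite(E[i2, k2])) next
        gap <- (i - i2 - 1) + (k - k2 - 1)
        if (gap == 0) {
          p2 <- oracle_pair_code(a[i2], b[k2])
          step <- min(oracle_stack_e(p2, p), 0)
        } else {
          step <- loop_penalty * gap
        }
        e <- min(e, E[i2, k2] + step)
      }
    }
    E[i, k] <- e
    best <- min(best, e)
  }
  if (!is.finite(best) || best >= 0) 0 else best
}

# True exhaustive enumeration of every monotone pairing (tiny inputs only).
oracle_duplex_enum <- function(up, asd, loop_penalty = 2.1) {
  a <- strsplit(chartr("T", "U", toupper(up)), "")[[1]]
  b <- rev(strsplit(chartr("T", "U", toupper(asd)), "")[[1]])
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, k, last_i, last_k, last_p, energy) {
    if (is.finite(energy)) best <<- min(best, energy)
    if (i > n || k > m) return(invisible())
    for (ii in i:n) for (kk in k:m) {
      p <- oracle_pair_code(a[ii], b[kk])
      if (is.na(p)) next
      if (is.na(last_p)) {
        step <- ORACLE_INIT
      } else {
        gap <- (ii - last_i - 1) + (kk - last_k - 1)
        step <- if (gap == 0) min(oracle_stack_e(last_p, p), 0) else
          loop_penalty * gap
      }
      recurse(ii + 1L, kk + 1L, ii, kk, p, energy + step)
    }
    invisible()
  }
  recurse(1L, 1L, NA, NA, NA_integer_, 0)
  if (!is.finite(best) || best >= 0) 0 else best
}

# ---- FDR / coding-count brute-force oracle ---------------------------------
oracle_fdr_scan <- function(s, m) {
  S <- length(s); M <- length(m)
  thr <- sort(unique(c(s, m)), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    st <- sum(s >= t); mt <- sum(m >= t)
    fdr <- if (st > 0) (mt / M) / (st / S) else NA_real_
    c(t = t, st = st, mt = mt, fdr = fdr)
  })
  df <- as.data.frame(do.call(rbind, rows))
  # Storey q: minimum FDR over thresholds at or below t
  df$q <- vapply(seq_len(nrow(df)), function(i) {
    vals <- df$fdr[df$t <= df$t[i]]
    min(c(vals[!is.na(vals)], 1))
  }, numeric(1))
  df
}

oracle_coding_count <- function(s, m) {
  df <- oracle_fdr_scan(s, m)
  S <- length(s); M <- length(m)
  signal <- df$st - (df$mt / M) * S
  tp <- if (any(signal <= -1)) max(df$t[signal <= -1]) else -Inf
  adm <- df$t > tp
  if (!any(adm)) return(list(c_raw = 0, t_prime = tp))
  vals <- df$st[adm] * (1 - df$q[adm])
  list(c_raw = max(max(vals), 0), t_prime = tp)
}

# closed-form probability that a Poisson(lambda)-per-position track has any
# signal in w independent positions
oracle_window_call_prob <- function(lambda, w) 1 - exp(-lambda * w)
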