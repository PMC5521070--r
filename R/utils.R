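# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion happens only at I/O boundaries.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Standard genetic code, DNA codons -> one-letter amino acid ("*" = stop).
GENETIC_CODE_DNA <- {
  bases <- c("T", "C", "A", "G")
  # standard table order: third base varies fastest (TTT, TTC, TTA, ...)
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
}

SENSE_CODONS <- setdiff(names(GENETIC_CODE_DNA), STOP_CODONS)

revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", seq))
}

# Split a DNA string into consecutive codons (drops trailing partial codon).
split_codons <- function(seq) {
  n <- floor(nchar(seq) / 3L)
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Extract [start, end) (0-based half-open) from a genome sequence string,
# reverse-complemented when strand == "-", so the result reads 5'->3'.
extract_interval <- function(seq, start, end, strand = "+") {
  s <- substr(seq, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed) %% .Machine$integer.max, .local_envir = env)
  }
  invisible(NULL)
}

# Deterministic child seeds derived from one master seed, kept < 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629)
}

orf_uid <- function(seqid, start, end, strand) {
  sprintf("%s:%d-%d:%s", seqid, start, end, strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Empty ORF-candidate tibble with canonical column set.
empty_orf_tbl <- function() {
  tibble::tibble(
    orf_id = character(), seqid = character(), start = integer(),
    end = integer(), strand = character(), parent_id = character(),
    aa_length = integer(), nt_seq = character(),
    overlap_class = character(), extended_3prime = logical(),
    provenance = character()
  )
}

translate_dna <- function(seq) {
  paste(GENETIC_CODE_DNA[split_codons(seq)], collapse = "")
}

# sample one integer uniformly from [a, b]; safe when a == b (R's sample()
# treats a scalar first argument as 1:n)
sample_range <- function(a, b) {
  if (a >= b) return(as.integer(a))
  sample(seq.int(a, b), 1L)
}
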