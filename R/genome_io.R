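#' Read a genome FASTA file
#'
#' Reads one or more chromosome/contig records. Sequences are upper-cased and
#' restricted to the alphabet `ACGTN`; any other character is a parse error
#' reported with the offending file line.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled over records. Reserved flag: the ORF
#'   search never wraps the origin in this version.
#' @return A tibble with one row per record and columns `id`, `seq`,
#'   `circular`, in file order.
#' @export
read_genome <- function(path, circular = FALSE) {
  assert_that(file.exists(path), sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    # recover an approximate file line for the offending character
    lines <- readLines(path, warn = FALSE)
    headers <- grep("^>", lines)
    rec_line <- headers[i]
    off <- bad[i]
    j <- rec_line
    while (j < length(lines) && off > 0) {
      j <- j + 1L
      off <- off - nchar(gsub("\\s", "", lines[j]))
    }
    stop(sprintf(
      "invalid character in sequence of record '%s' (near line %d)",
      names(set)[i], j
    ), call. = FALSE)
  }
  ids <- stringr::str_split_fixed(names(set), "\\s+", 2)[, 1]
  if (any(ids == "")) stop("malformed FASTA header (empty id)", call. = FALSE)
  tibble::tibble(id = ids, seq = unname(seqs),
                 circular = rep_len(circular, length(ids)))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble as returned by [read_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

default_type_map <- c(
  cds = "cds", gene = "other", srna = "srna", ncrna = "srna",
  srna_gene = "srna", other = "other"
)

#' Read genomic features from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) coordinates are both
#' converted to the package-internal 0-based half-open convention. The GFF3
#' `type` column (or the BED name prefix before the first `|`, if present) is
#' mapped to the internal feature classes `cds`, `srna`, `other` through
#' `type_map`; unmapped types become `other`.
#'
#' CDS and sRNA features must carry a defined strand (`+` or `-`).
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param type_map Named character vector mapping lower-cased source types to
#'   `c("cds","srna","other")`.
#' @return Tibble with columns `seqid`, `start`, `end`, `strand`, `ftype`,
#'   `id` (0-based half-open).
#' @export
read_features <- function(path, dialect = c("gff3", "bed"),
                          type_map = default_type_map) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed")
  if (length(gr) == 0L) return(features_tbl())
  md <- S4Vectors::mcols(gr)
  if (dialect == "gff3") {
    raw_type <- tolower(as.character(md$type))
    id <- as.character(md$ID %||% md$Name %||% NA_character_)
  } else {
    nm <- as.character(md$name %||% NA_character_)
    raw_type <- tolower(stringr::str_split_fixed(nm, "\\|", 2)[, 1])
    id <- nm
  }
  ftype <- unname(type_map[raw_type])
  ftype[is.na(ftype)] <- "other"
  strand <- as.character(BiocGenerics::strand(gr))
  start0 <- BiocGenerics::start(gr) - 1L  # GRanges is 1-based inclusive
  end0 <- BiocGenerics::end(gr)
  if (any(end0 < start0)) stop("feature with end < start after conversion", call. = FALSE)
  need_strand <- ftype %in% c("cds", "srna")
  if (any(need_strand & !(strand %in% c("+", "-")))) {
    stop("cds/srna feature with undefined strand", call. = FALSE)
  }
  id[is.na(id) | id == ""] <- sprintf("feat%06d", which(is.na(id) | id == ""))
  tibble::tibble(
    seqid = as.character(GenomeInfoDb::seqnames(gr)),
    start = as.integer(start0), end = as.integer(end0),
    strand = strand, ftype = ftype, id = id
  )
}

features_tbl <- function() {
  tibble::tibble(seqid = character(), start = integer(), end = integer(),
                 strand = character(), ftype = character(), id = character())
}

#' Write features to GFF3 or BED
#'
#' Inverse of [read_features()]: internal 0-based half-open intervals are
#' converted back to the dialect's native convention. Round-tripping a feature
#' table through either dialect reproduces identical internal coordinates.
#'
#' @param features Feature tibble (internal convention).
#' @param path Output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    lines <- c("##gff-version 3", sprintf(
      "%s\tsmorfselect\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      features$seqid, features$ftype, features$start + 1L, features$end,
      features$strand, features$id
    ))
  } else {
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t0\t%s",
      features$seqid, features$start, features$end,
      paste0(features$ftype, "|", features$id), features$strand
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a strand-specific coverage track from WIG
#'
#' Supports `fixedStep` and `variableStep` blocks. WIG positions are 1-based;
#' the returned track is a per-position vector indexed from genomic position 0
#' (element `i` of `values` is position `i - 1`). Unlisted positions are 0.
#'
#' @param path WIG file path.
#' @param strand `"+"` or `"-"` (WIG itself is unstranded; the caller states
#'   which strand the file describes).
#' @param genome_length Length of the genome sequence the track spans.
#' @param seqid Optional sequence id recorded on the track.
#' @return A list of class `coverage_track` with fields `seqid`, `strand`,
#'   `values`.
#' @export
read_coverage <- function(path, strand = c("+", "-"), genome_length,
                          seqid = NA_character_) {
  strand <- match.arg(strand)
  assert_that(file.exists(path), sprintf("WIG file not found: %s", path))
  values <- numeric(genome_length)
  nonempty <- any(!grepl("^(#.*)?\\s*$", readLines(path, warn = FALSE)))
  if (nonempty) {
    gr <- rtracklayer::import(path, format = "wig")
    if (inherits(gr, "GRangesList") || methods::is(gr, "SimpleList")) {
      gr <- unlist(methods::as(gr, "GRangesList"), use.names = FALSE)
    }
    if (length(gr) > 0) {
      if (max(BiocGenerics::end(gr)) > genome_length) {
        stop("WIG position beyond genome length", call. = FALSE)
      }
      sc <- S4Vectors::mcols(gr)$score
      st <- BiocGenerics::start(gr)
      en <- BiocGenerics::end(gr)
      for (k in seq_along(gr)) values[st[k]:en[k]] <- sc[k]
      if (is.na(seqid)) seqid <- as.character(GenomeInfoDb::seqnames(gr))[1]
    }
  }
  if (any(values < 0)) stop("negative coverage value in WIG", call. = FALSE)
  structure(list(seqid = seqid, strand = strand, values = values),
            class = "coverage_track")
}

#' Read a phylogenetic tree from a newick file
#'
#' @param path Newick file. Branch lengths are required (the codon-model
#'   likelihood-ratio test cannot run without them) and must be non-negative;
#'   leaf labels must be unique.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  assert_that(file.exists(path), sprintf("newick file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable newick file", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label in tree: ",
         tree$tip.label[duplicated(tree$tip.label)][1], call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree is missing branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree
}
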