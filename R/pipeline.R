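# End-to-end orchestration: ORF discovery -> control sets -> features ->
# bagged-tree classifier -> empirical-FDR coding estimate (-> optional
# ribosome-profiling evidence), either in memory (analyze_srna_coding) or
# from a YAML/list config referencing files on disk (run_pipeline).

#' Analyze coding potential of sRNA ORFs (in-memory engine)
#'
#' Runs the full discovery pipeline on in-memory objects: enumerates sRNA
#' ORF candidates, builds length-matched positive (annotated-subset) and
#' negative (mock) control sets, computes the three features (SD
#' hybridization energy, dN/dS log-likelihood difference via
#' `dnds_provider`, Z-curve composition score), trains the cost-sensitive
#' bagged-tree classifier, scores mocks under cross-validation, and
#' converts scores into per-category and total excess-over-null coding
#' estimates.
#'
#' @param genome One-row genome tibble.
#' @param cds CDS feature tibble.
#' @param srnas sRNA feature tibble.
#' @param anti_sd Anti-SD RNA string.
#' @param dnds_provider `NULL`, or `function(orfs)` returning a tibble with
#'   `orf_id`, `omega_hat`, `loglik_diff` for (a subset of) the rows passed
#'   in; called for non-overlapping ORFs, positives and plain mocks.
#' @param coverage Optional list with `plus`/`minus` coverage tracks for the
#'   ribosome-profiling evidence module.
#' @param min_aa,max_aa ORF peptide-length bounds.
#' @param n_sets Number of control sets for classifier training and the
#'   FDR null.
#' @param n_comp_sets Number of control sets used to train the composition
#'   model (defaults to `n_sets`; the composition fit has 69 parameters and
#'   benefits from more sequence sets, which are cheap because they need no
#'   conservation statistics). The first `n_sets` of them are the classifier
#'   /FDR sets.
#' @param n_bags Bagging iterations for the classifier.
#' @param n_shuffles Shuffled upstreams per ORF for the SD background.
#' @param cv_folds Folds for mock background scoring.
#' @param n_subsets Mock subsets for the fluctuation correction.
#' @param n_draws Draws for the sRNA-fraction estimate.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return List of class `srna_coding_analysis`.
#' @export
analyze_srna_coding <- function(genome, cds, srnas, anti_sd,
                                dnds_provider = NULL, coverage = NULL,
                                min_aa = 10, max_aa = 50, n_sets = 20,
                                n_comp_sets = NULL, n_bags = 100,
                                n_shuffles = 20,
                                cv_folds = 10, n_subsets = 20,
                                n_draws = 100, seed = 1) {
  seeds <- derive_seeds(seed, 12)
  n_comp_sets <- max(n_comp_sets %||% n_sets, n_sets)
  cds <- cds[cds$ftype == "cds", , drop = FALSE]
  srnas <- srnas[srnas$ftype == "srna", , drop = FALSE]
  assert_that(nrow(srnas) > 0, "no sRNA annotations supplied")

  # --- ORF discovery -------------------------------------------------------
  cand <- dplyr::bind_rows(lapply(seq_len(nrow(srnas)), function(i) {
    find_orfs_in_srna(srnas[i, ], genome, cds, min_aa, max_aa)
  }))
  cand <- dplyr::distinct(cand, .data$orf_id, .keep_all = TRUE)
  assert_that(nrow(cand) > 0, "no sRNA ORF candidates found")
  merged0 <- merge_inframe_overlaps(cand)

  # --- SD scores -----------------------------------------------------------
  cand <- sd_score_orfs(cand, genome, anti_sd, n_shuffles = n_shuffles,
                        seed = seeds[[1]])
  cds_like <- tibble::tibble(start = cds$start, end = cds$end,
                             strand = cds$strand)
  cds_sd <- stats::setNames(
    duplex_free_energy(extract_upstream(cds_like, genome), anti_sd)$delta_g,
    cds$id
  )
  cds_sd[is.na(cds_sd)] <- 0
  shuffled_pool <- unlist(cand$sd_shuffled)
  shuffled_pool <- shuffled_pool[!is.na(shuffled_pool)]
  if (length(shuffled_pool) == 0L) shuffled_pool <- 0

  # --- control sets --------------------------------------------------------
  target_all <- merged0$aa_length
  positives_all <- sample_positive_subsets(cds, genome, target_all,
                                           n_sets = n_comp_sets,
                                           seed = seeds[[2]])
  none_lengths <- merged0$aa_length[merged0$overlap_class == "none"]
  plain_mocks_all <- if (length(none_lengths) > 0) {
    sample_mock_orfs(genome, cds, cand, none_lengths, n_sets = n_comp_sets,
                     seed = seeds[[3]])
  } else {
    replicate(n_comp_sets, empty_orf_tbl(), simplify = FALSE)
  }
  positives <- positives_all[seq_len(n_sets)]
  plain_mocks <- plain_mocks_all[seq_len(n_sets)]
  overlap_orfs <- merged0[merged0$overlap_class %in%
                            c("sense_outframe", "antisense"), , drop = FALSE]
  ov_mock_sets <- replicate(n_sets, empty_orf_tbl(), simplify = FALSE)
  unmocked_overlap <- character(0)
  if (nrow(overlap_orfs) > 0) {
    ov_seeds <- derive_seeds(seeds[[4]], nrow(overlap_orfs))
    for (i in seq_len(nrow(overlap_orfs))) {
      mocks_i <- tryCatch(
        sample_overlap_matched_mocks(
          overlap_orfs[i, ], cds, genome, srna_orfs = cand, n = n_sets,
          seed = ov_seeds[[i]]
        ),
        error = function(e) {
          warning("no matched mocks for ", overlap_orfs$orf_id[i], ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      if (is.null(mocks_i)) {
        unmocked_overlap <- c(unmocked_overlap, overlap_orfs$orf_id[i])
        next
      }
      for (s in seq_len(n_sets)) {
        ov_mock_sets[[s]] <- dplyr::bind_rows(ov_mock_sets[[s]], mocks_i[s, ])
      }
    }
  }
  negatives <- lapply(seq_len(n_sets), function(s) {
    dplyr::bind_rows(plain_mocks[[s]], ov_mock_sets[[s]])
  })

  # --- composition model ---------------------------------------------------
  # When extra composition sets are available the classifier/FDR sets are
  # held out of the composition fit: the near-unpenalized logistic model
  # memorizes its training sequences, and mock ORFs must be scored
  # out-of-sample -- exactly like the sRNA ORFs they stand in for -- for the
  # empirical null to be exchangeable.
  comp_idx <- if (n_comp_sets > n_sets) (n_sets + 1L):n_comp_sets else
    seq_len(n_comp_sets)
  comp_model <- train_composition_model(
    pos = unlist(lapply(positives_all[comp_idx], comp_sequence)),
    neg = unlist(lapply(plain_mocks_all[comp_idx], comp_sequence))
  )

  # --- dN/dS ---------------------------------------------------------------
  dnds_tbl <- NULL
  if (!is.null(dnds_provider)) {
    need <- dplyr::bind_rows(
      merged0[merged0$overlap_class == "none", , drop = FALSE],
      dplyr::bind_rows(positives),
      dplyr::bind_rows(plain_mocks)
    )
    dnds_tbl <- dnds_provider(need)
  }

  # --- training table + classifier ----------------------------------------
  train_rows <- build_training_table(
    positives, negatives, cds_sd, shuffled_pool, comp_model,
    dnds = dnds_tbl, seed = seeds[[5]]
  )
  model <- train_bagged_trees(train_rows, n_bags = n_bags, seed = seeds[[6]])

  # --- score sRNA ORF candidates ------------------------------------------
  cand_rows <- tibble::tibble(
    orf_id = cand$orf_id,
    sd_score = cand$sd_delta_g,
    dnds_loglik = NA_real_,
    comp_score = score_composition(comp_model, comp_sequence(cand)),
    category = cand$overlap_class
  )
  if (!is.null(dnds_tbl)) {
    lut <- stats::setNames(dnds_tbl$loglik_diff, dnds_tbl$orf_id)
    hit <- cand_rows$category == "none" & cand_rows$orf_id %in% names(lut)
    cand_rows$dnds_loglik[hit] <- unname(lut[cand_rows$orf_id[hit]])
  }
  # snap scores to the ensemble's natural resolution (1/n_bags): sweep
  # thresholds must not distinguish differences smaller than one tree's
  # vote, which are model-family noise (full model vs CV fold models)
  snap <- function(x) round(x * n_bags) / n_bags
  cand_scores <- snap(coding_scores(model, cand_rows))
  merged <- merge_inframe_overlaps(cand, scores = cand_scores)

  # --- mock background scores under CV ------------------------------------
  mock_rows <- train_rows[train_rows$label == "noncoding", , drop = FALSE]
  pos_rows <- train_rows[train_rows$label == "coding", , drop = FALSE]
  mock_scores <- snap(background_scores_cv(mock_rows, pos_rows, k = cv_folds,
                                           n_bags = n_bags, seed = seeds[[7]]))

  # --- per-category estimates ----------------------------------------------
  estimates <- list()
  est_seeds <- derive_seeds(seeds[[8]], 3)
  cats <- intersect(c("none", "sense_outframe", "antisense"),
                    unique(merged$overlap_class))
  for (k in seq_along(cats)) {
    cat_i <- cats[k]
    # overlap ORFs without a matched mock null cannot enter the estimate
    in_cat <- merged$overlap_class == cat_i &
      !(merged$orf_id %in% unmocked_overlap)
    s_sc <- merged$coding_score[in_cat]
    m_sc <- unname(mock_scores[mock_rows$category == cat_i])
    if (length(s_sc) == 0L || length(m_sc) <= length(s_sc)) next
    estimates[[cat_i]] <- correct_fluctuation(s_sc, m_sc,
                                              n_subsets = n_subsets,
                                              seed = est_seeds[[k]])
  }
  combined <- combine_categories(estimates)
  fraction <- fraction_srnas_coding(merged, nrow(srnas), estimates,
                                    n_draws = n_draws, seed = seeds[[9]])

  # per-ORF q-values from the category curves
  merged$q_value <- NA_real_
  for (cat_i in names(estimates)) {
    curve <- estimates[[cat_i]]$curve
    rows_i <- which(merged$overlap_class == cat_i)
    merged$q_value[rows_i] <- vapply(merged$coding_score[rows_i], function(sc) {
      curve$q[match(sc, curve$threshold)]
    }, numeric(1))
  }

  ribo <- NULL
  if (!is.null(coverage)) {
    eligible <- merged[merged$overlap_class != "sense_outframe", , drop = FALSE]
    orf_calls <- call_translated(eligible, coverage$plus, coverage$minus)
    mock_calls <- lapply(negatives, function(m) {
      m2 <- m[m$overlap_class != "sense_outframe", , drop = FALSE]
      call_translated(m2, coverage$plus, coverage$minus)
    })
    ribo <- list(calls = orf_calls,
                 excess = translation_excess(orf_calls, mock_calls))
  }

  structure(
    list(
      orfs = merged, candidates = cand, orf_features = cand_rows,
      control_features = train_rows,
      positives = positives, negatives = negatives,
      comp_model = comp_model, model = model, dnds = dnds_tbl,
      mock_scores = mock_scores, mock_categories = mock_rows$category,
      estimates = estimates, combined = combined, fraction = fraction,
      ribo = ribo, n_srnas = nrow(srnas),
      params = list(min_aa = min_aa, max_aa = max_aa, n_sets = n_sets,
                    n_bags = n_bags, seed = seed)
    ),
    class = "srna_coding_analysis"
  )
}

#' @export
print.srna_coding_analysis <- function(x, ...) {
  tot <- x$combined[x$combined$category == "total", ]
  cat(sprintf(
    "sRNA ORF coding analysis: %d merged ORFs in %d sRNAs\n",
    nrow(x$orfs), x$n_srnas))
  cat(sprintf("  Coding above background: C' = %.1f +/- %.1f\n",
              tot$c_corrected, tot$ci95))
  cat(sprintf("  Fraction of sRNAs with >= 1 coding ORF: %.3f +/- %.3f\n",
              x$fraction$fraction, x$fraction$ci95))
  invisible(x)
}

#' @method glance srna_coding_analysis
#' @export
glance.srna_coding_analysis <- function(x, ...) {
  tot <- x$combined[x$combined$category == "total", ]
  tibble::tibble(
    n_srnas = x$n_srnas, n_orfs = nrow(x$orfs),
    c_corrected = tot$c_corrected, ci95 = tot$ci95,
    fraction_coding = x$fraction$fraction
  )
}

#' @method tidy srna_coding_analysis
#' @export
tidy.srna_coding_analysis <- function(x, ...) {
  x$orfs[, c("orf_id", "parent_id", "overlap_class", "aa_length",
             "coding_score", "q_value")]
}

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a YAML file) with at least `genome`,
#'   `cds`, `srna`, `anti_sd`, `out_dir`; optional `tree`, `alignments`,
#'   `coverage_plus`, `coverage_minus`, `seed`, and numeric overrides
#'   (`min_aa`, `max_aa`, `n_sets`, `n_bags`, ...). `modes` may name any of
#'   `"srna"`, `"intergenic"`.
#' @return The normalized config list; errors list all problems at once.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  for (key in c("genome", "cds", "srna")) {
    if (is.null(config[[key]])) errs <- c(errs, paste0("missing path: ", key))
    else if (!file.exists(config[[key]]))
      errs <- c(errs, paste0("file not found: ", config[[key]]))
  }
  if (is.null(config$anti_sd)) errs <- c(errs, "missing anti_sd sequence")
  config$modes <- config$modes %||% "srna"
  if (length(config$modes) == 0L ||
      !all(config$modes %in% c("srna", "intergenic"))) {
    errs <- c(errs, "modes must be a non-empty subset of {srna, intergenic}")
  }
  for (key in c("tree", "coverage_plus", "coverage_minus")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      errs <- c(errs, paste0("file not found: ", config[[key]]))
  }
  if (length(errs) > 0) {
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  config$seed <- config$seed %||% 1
  config$out_dir <- config$out_dir %||% "."
  config
}

safe_orf_filename <- function(orf_id) gsub("[:]", "_", orf_id)

#' Run the full pipeline from a config
#'
#' Thin file-based wrapper around [analyze_srna_coding()]: reads the genome,
#' annotations, optional tree/alignments (a directory of aligned FASTA
#' files named `<orf id with : replaced by _>.fasta`) and optional coverage,
#' runs the analysis, and writes the score table (TSV) and a summary report
#' (JSON) into `out_dir`.
#'
#' @param config Named list or YAML path (see [validate_config()]).
#' @return The `srna_coding_analysis` object, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  genome <- read_genome(config$genome)[1, ]
  cds <- read_features(config$cds, dialect = config$cds_dialect %||% "gff3")
  srnas <- read_features(config$srna, dialect = config$srna_dialect %||% "gff3")
  dnds_provider <- NULL
  if (!is.null(config$alignments) && !is.null(config$tree)) {
    tree <- read_tree(config$tree)
    aln_dir <- config$alignments
    dnds_provider <- function(orfs) {
      rows <- lapply(orfs$orf_id, function(id) {
        f <- file.path(aln_dir, paste0(safe_orf_filename(id), ".fasta"))
        if (!file.exists(f)) return(NULL)
        aln <- preprocess_alignment(f, reference_id = config$reference_id %||%
                                      "reference")
        res <- dnds_loglik_test(aln, tree)
        tibble::tibble(orf_id = id, omega_hat = res$omega_hat,
                       loglik_diff = res$loglik_diff)
      })
      dplyr::bind_rows(rows)
    }
  }
  coverage <- NULL
  if (!is.null(config$coverage_plus) && !is.null(config$coverage_minus)) {
    glen <- nchar(genome$seq)
    coverage <- list(
      plus = read_coverage(config$coverage_plus, "+", glen),
      minus = read_coverage(config$coverage_minus, "-", glen)
    )
  }
  res <- analyze_srna_coding(
    genome, cds, srnas, anti_sd = config$anti_sd,
    dnds_provider = dnds_provider, coverage = coverage,
    min_aa = config$min_aa %||% 10, max_aa = config$max_aa %||% 50,
    n_sets = config$n_sets %||% 20,
    n_comp_sets = config$n_comp_sets %||% NULL,
    n_bags = config$n_bags %||% 100,
    n_shuffles = config$n_shuffles %||% 20,
    cv_folds = config$cv_folds %||% 10,
    n_subsets = config$n_subsets %||% 20,
    n_draws = config$n_draws %||% 100,
    seed = config$seed
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    tidy(res), file.path(config$out_dir, "orf_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  report <- list(
    combined = as.list(res$combined),
    fraction = as.list(res$fraction),
    n_srnas = res$n_srnas, n_orfs = nrow(res$orfs),
    params = res$params
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
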