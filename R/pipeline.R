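#' Pipeline run configuration
#'
#' Collects every input path, threshold and mode flag for the staged
#' pipeline (`qc` → `filter` → `rescue`), with the package defaults for all
#' tunables. Stages write their outputs (and a log of the configuration and
#' seed) under `out_dir` and later stages fail with an actionable error when
#' an upstream output is missing.
#'
#' @param query_gtf,ref_gtf,genome_fa Input paths (query transcriptome,
#'   reference annotation, genome FASTA).
#' @param cage_bed,polya_bed,polya_motifs Optional evidence file paths.
#' @param coverage_bedgraphs,sj_tabs Optional character vectors of
#'   per-replicate coverage / SJ.out.tab paths.
#' @param out_dir Output directory.
#' @param mode Filter mode, `"rules"` or `"ml"`.
#' @param rules_json Optional rules JSON path (rules mode; defaults to
#'   [default_rules()]).
#' @param seed Seed for all randomness (default 1).
#' @param params [qc_params()] overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(query_gtf, ref_gtf, genome_fa, cage_bed = NULL,
                       polya_bed = NULL, polya_motifs = NULL,
                       coverage_bedgraphs = NULL, sj_tabs = NULL,
                       out_dir = "isocurate_out", mode = c("rules", "ml"),
                       rules_json = NULL, seed = 1, params = qc_params()) {
  mode <- match.arg(mode)
  structure(list(query_gtf = query_gtf, ref_gtf = ref_gtf,
                 genome_fa = genome_fa, cage_bed = cage_bed,
                 polya_bed = polya_bed, polya_motifs = polya_motifs,
                 coverage_bedgraphs = coverage_bedgraphs, sj_tabs = sj_tabs,
                 out_dir = out_dir, mode = mode, rules_json = rules_json,
                 seed = seed, params = params),
            class = "run_config")
}

log_line <- function(config, ...) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              paste0(...)),
      file = file.path(config$out_dir, "log.txt"), append = TRUE)
}

load_run_inputs <- function(config) {
  genome <- Biostrings::readDNAStringSet(config$genome_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  list(
    queries = load_gtf(config$query_gtf, min_len = 0),
    reference = load_gtf(config$ref_gtf, min_len = config$params$min_ref_len),
    reference_full = load_gtf(config$ref_gtf, min_len = 0),
    genome = genome,
    cage = if (!is.null(config$cage_bed))
      load_bed_peaks(config$cage_bed, "five_prime"),
    polya = if (!is.null(config$polya_bed))
      load_bed_peaks(config$polya_bed, "three_prime"),
    motifs = if (!is.null(config$polya_motifs))
      load_polya_motifs(config$polya_motifs),
    coverage = if (!is.null(config$coverage_bedgraphs))
      lapply(config$coverage_bedgraphs, load_bedgraph),
    sj = if (!is.null(config$sj_tabs)) load_sj_tab(config$sj_tabs))
}

#' Run the QC stage
#'
#' Classifies the query transcriptome and computes all QC attributes,
#' writing `classification.txt` and `junctions.txt` under the configured
#' output directory.
#'
#' @param config A [run_config()].
#' @return The QC tables, invisibly.
#' @export
run_qc <- function(config) {
  x <- load_run_inputs(config)
  index <- build_reference_index(x$reference,
                                 min_ref_len = config$params$min_ref_len)
  qc <- compute_qc_tables(x$queries, index, genome = x$genome,
                          cage_peaks = x$cage, polya_peaks = x$polya,
                          polya_motifs = x$motifs, coverage = x$coverage,
                          sj = x$sj, params = config$params)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_classification_table(qc$classification,
                             file.path(config$out_dir, "classification.txt"))
  if (!is.null(qc$junctions))
    write_junction_table(qc$junctions,
                         file.path(config$out_dir, "junctions.txt"))
  log_line(config, "qc: ", nrow(qc$classification), " transcripts, seed ",
           config$seed)
  invisible(qc)
}

stage_output <- function(config, file, stage) {
  p <- file.path(config$out_dir, file)
  if (!file.exists(p))
    stop("missing ", file, ": run the '", stage, "' stage first")
  p
}

#' Run the filter stage
#'
#' Applies the configured filter (JSON rules or the random-forest
#' classifier with automatic training sets) to the QC classification table,
#' writing `filter_reasons.txt`.
#'
#' @param config A [run_config()].
#' @param ml_spec [ml_training_spec()] settings (ml mode).
#' @return List with `decisions` (and `model` in ml mode), invisibly.
#' @export
run_filter <- function(config, ml_spec = NULL) {
  records <- read_table_tsv(stage_output(config, "classification.txt", "qc"))
  if (config$mode == "rules") {
    rules <- if (is.null(config$rules_json)) default_rules(
      config$params$min_junction_support) else parse_rules(config$rules_json)
    decisions <- apply_rules(records, rules)
    model <- NULL
  } else {
    if (is.null(ml_spec))
      ml_spec <- ml_training_spec(threshold = config$params$ml_threshold,
                                  seed = config$seed)
    sets <- auto_training_sets(records, ml_spec)
    ml_spec$excluded_columns <- union(ml_spec$excluded_columns,
                                      sets$auto_excluded_columns)
    model <- train_ml_filter(records, sets$tp_ids, sets$tn_ids, ml_spec)
    decisions <- score_and_filter(records, model, ml_spec)
  }
  write_filter_decisions(decisions,
                         file.path(config$out_dir, "filter_reasons.txt"))
  log_line(config, "filter (", config$mode, "): ",
           sum(decisions$verdict == "artifact"), " artifacts of ",
           nrow(decisions))
  invisible(list(decisions = decisions, model = model))
}

#' Run the rescue stage
#'
#' Recovers discarded signal after filtering: automatic FSM rescue plus
#' rescue-by-mapping of ISM/NIC/NNC artifacts against filter-validated
#' reference targets. Writes `rescue_table.tsv` and the final expanded
#' transcriptome `curated.gtf`.
#'
#' @param config A [run_config()].
#' @param filter_result Optional result of [run_filter()] (re-run
#'   otherwise); in ml mode its trained model is reused on the reference.
#' @return The rescue outcome list, invisibly.
#' @export
run_rescue <- function(config, filter_result = NULL) {
  records <- read_table_tsv(stage_output(config, "classification.txt", "qc"))
  stage_output(config, "filter_reasons.txt", "filter")
  if (is.null(filter_result)) filter_result <- run_filter(config)
  decisions <- filter_result$decisions
  x <- load_run_inputs(config)
  index <- build_reference_index(x$reference,
                                 min_ref_len = config$params$min_ref_len)
  rules <- if (config$mode == "rules") {
    if (is.null(config$rules_json)) default_rules(
      config$params$min_junction_support) else parse_rules(config$rules_json)
  }
  refv <- validate_reference_targets(
    x$reference_full, mode = config$mode, rules = rules,
    ml_model = filter_result$model,
    ml_spec = ml_training_spec(threshold = config$params$ml_threshold,
                               seed = config$seed),
    genome = x$genome, cage_peaks = x$cage, polya_peaks = x$polya,
    polya_motifs = x$motifs, coverage = x$coverage, sj = x$sj,
    params = config$params)
  res <- run_rescue_stage(records, decisions, x$queries, index, refv,
                          mode = config$mode)
  utils::write.table(res$outcomes,
                     file.path(config$out_dir, "rescue_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  final <- c(x$queries[intersect(names(x$queries), res$curated_ids)],
             x$reference_full[intersect(names(x$reference_full),
                                        res$additions)])
  write_gtf(final, file.path(config$out_dir, "curated.gtf"))
  log_line(config, "rescue: ", length(res$additions),
           " reference models added; final size ", length(final))
  invisible(res)
}

#' Summarize a pipeline run
#'
#' Per-category and per-subcategory counts, the fraction of transcript ends
#' supported by each evidence type, and filter/rescue tallies, written to
#' `summary.txt` and returned.
#'
#' @param config A [run_config()].
#' @return List of summary tables.
#' @export
summarize_run <- function(config) {
  records <- read_table_tsv(stage_output(config, "classification.txt", "qc"))
  out <- list(
    n_transcripts = nrow(records),
    category_counts = table(records$structural_category),
    label_counts = table(paste(records$structural_category,
                               records$subcategory, sep = "/")),
    end_support = c(
      cage = mean(records$within_CAGE_peak, na.rm = TRUE),
      polya_site = mean(records$within_polyA_site, na.rm = TRUE),
      polya_motif = mean(records$polyA_motif_found, na.rm = TRUE),
      tss_ratio_gt_1.5 = mean(records$ratio_TSS > 1.5, na.rm = TRUE)))
  fr <- file.path(config$out_dir, "filter_reasons.txt")
  if (file.exists(fr)) {
    d <- read_table_tsv(fr)
    out$filter_counts <- table(d$verdict)
  }
  rt <- file.path(config$out_dir, "rescue_table.tsv")
  if (file.exists(rt)) {
    r <- read_table_tsv(rt)
    out$rescue_actions <- table(r$action)
  }
  con <- file(file.path(config$out_dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(out)), con)
  out
}

#' Run a spike-in evaluation
#'
#' Builds the corrupted-annotation scenario from a true annotation, tallies
#' a detection set against it and computes the six performance metrics.
#'
#' @param true_transcripts Named list of true `transcript_model`s.
#' @param detected Named list of detected models.
#' @param n_false,n_true_removed Scenario corruption counts.
#' @param seed Scenario seed.
#' @param out Optional TSV path for the metrics.
#' @return List with `scenario`, `tally`, `metrics`.
#' @export
run_eval <- function(true_transcripts, detected, n_false = 39,
                     n_true_removed = 26, seed = 1, out = NULL) {
  scenario <- build_scenario(true_transcripts, n_false, n_true_removed, seed)
  tally <- tally_detections(detected, scenario)
  metrics <- compute_metrics(tally)
  if (!is.null(out)) {
    utils::write.table(as.data.frame(metrics), out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(scenario = scenario, tally = tally, metrics = metrics)
}
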