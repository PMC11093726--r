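#' Machine-learning filter settings
#'
#' @param min_size Minimum per-class training list size; training refuses to
#'   run below it (default 250).
#' @param max_size Per-class cap applied after balancing (default 3000).
#' @param excluded_columns Extra classification columns to withhold from
#'   training (on top of the identifier, genome-structure and category
#'   columns that are always withheld).
#' @param threshold Isoform probability at or above which a multi-exonic
#'   transcript is kept (default 0.7, inclusive).
#' @param force_fsm_in Keep every FSM transcript regardless of probability.
#' @param drop_mono_exon Remove mono-exonic transcripts (they are otherwise
#'   not evaluated and kept).
#' @param seed Seed driving downsampling, the held-out split and forest
#'   fitting.
#' @param ntree Number of trees in the random forest (default 500).
#' @return Named list of settings.
#' @export
ml_training_spec <- function(min_size = 250, max_size = 3000,
                             excluded_columns = character(0),
                             threshold = 0.7, force_fsm_in = FALSE,
                             drop_mono_exon = FALSE, seed = 42, ntree = 500) {
  stopifnot(threshold > 0, threshold < 1)
  min_size <- max(min_size, 250)  # lower sizes are banned
  list(min_size = min_size, max_size = max_size,
       excluded_columns = excluded_columns, threshold = threshold,
       force_fsm_in = force_fsm_in, drop_mono_exon = drop_mono_exon,
       seed = seed, ntree = ntree)
}

# Columns never used as predictive variables: identifiers, genome structure,
# the associated reference, and the categories/subcategories themselves.
ML_ALWAYS_EXCLUDED <- c("isoform", "chrom", "strand", "associated_gene",
                        "associated_transcript", "structural_category",
                        "subcategory", "POS_MLprob")

# Columns additionally withheld when the training sets are derived from the
# categories themselves (junction canonicality and reference end distances),
# to prevent the classifier from simply re-learning the set definitions.
ML_AUTO_EXCLUDED <- c("all_canonical", "diff_to_TSS", "diff_to_TTS",
                      "diff_to_gene_TSS", "diff_to_gene_TTS")

#' Automatic true-positive / true-negative training sets
#'
#' True positives are FSM transcripts of the `reference_match` subcategory
#' (reference-supported junctions and ends); true negatives are NNC
#' transcripts with at least one noncanonical junction. Because these
#' definitions lean on junction type and end distances, the corresponding
#' columns are excluded from training. The larger set is downsampled to the
#' size of the smaller, then both are capped at `max_size` (sampling is
#' seeded).
#'
#' @param records Classification data.frame.
#' @param spec See [ml_training_spec()].
#' @return List with `tp_ids`, `tn_ids`, `auto_excluded_columns`.
#' @export
auto_training_sets <- function(records, spec = ml_training_spec()) {
  tp <- records$isoform[records$subcategory == "reference_match"]
  tn <- records$isoform[records$structural_category == "NNC" &
                          !records$all_canonical]
  if (length(tp) < spec$min_size || length(tn) < spec$min_size)
    stop(sprintf(paste0("machine-learning filter refused to run: training ",
                        "sets need at least %d transcripts per class ",
                        "(got %d true positives, %d true negatives)"),
                 spec$min_size, length(tp), length(tn)))
  set.seed(spec$seed)
  k <- min(length(tp), length(tn), spec$max_size)
  if (length(tp) > k) tp <- sort(sample(tp, k))
  if (length(tn) > k) tn <- sort(sample(tn, k))
  list(tp_ids = tp, tn_ids = tn, auto_excluded_columns = ML_AUTO_EXCLUDED)
}

#' Train the random-forest artifact classifier
#'
#' Fits a random forest distinguishing isoforms (true positives) from
#' artifacts (true negatives) on the QC attributes of the classification
#' table. Missing numeric features are imputed with the training-set column
#' median; missing categorical values become an explicit `"NA"` level.
#' Held-out diagnostics come from a stratified 80/20 split; the reported
#' model is refitted on the full training data. Fully deterministic given
#' `spec$seed`.
#'
#' @param records Classification data.frame.
#' @param tp_ids,tn_ids Transcript id vectors (each at least
#'   `spec$min_size`).
#' @param spec See [ml_training_spec()].
#' @return An `isocurate_ml_model`: the fitted forest, feature list,
#'   variable importances and held-out accuracy.
#' @export
train_ml_filter <- function(records, tp_ids, tn_ids,
                            spec = ml_training_spec()) {
  if (length(tp_ids) < spec$min_size || length(tn_ids) < spec$min_size)
    stop(sprintf(paste0("machine-learning filter refused to run: training ",
                        "sets need at least %d transcripts per class ",
                        "(got %d true positives, %d true negatives)"),
                 spec$min_size, length(tp_ids), length(tn_ids)))
  feature_cols <- setdiff(names(records),
                          c(ML_ALWAYS_EXCLUDED, spec$excluded_columns))
  sub <- records[match(c(tp_ids, tn_ids), records$isoform), , drop = FALSE]
  if (anyNA(sub$isoform)) stop("training ids missing from records")
  y <- factor(rep(c("isoform", "artifact"),
                  c(length(tp_ids), length(tn_ids))),
              levels = c("artifact", "isoform"))

  medians <- lapply(sub[feature_cols], function(v) {
    if (is.numeric(v)) stats::median(v, na.rm = TRUE) else NULL
  })
  cat_levels <- lapply(sub[feature_cols], function(v) {
    if (is.numeric(v)) NULL else unique(c(as.character(v[!is.na(v)]), "NA"))
  })
  x <- ml_feature_frame(sub, feature_cols, medians, cat_levels)

  set.seed(spec$seed)
  idx_tr <- unlist(lapply(split(seq_along(y), y), function(ii) {
    sample(ii, floor(0.8 * length(ii)))
  }), use.names = FALSE)
  fit_ho <- randomForest::randomForest(x[idx_tr, , drop = FALSE], y[idx_tr],
                                       ntree = spec$ntree)
  pred_ho <- stats::predict(fit_ho, x[-idx_tr, , drop = FALSE])
  heldout_acc <- mean(pred_ho == y[-idx_tr])

  set.seed(spec$seed)
  forest <- randomForest::randomForest(x, y, ntree = spec$ntree,
                                       importance = TRUE)
  imp <- randomForest::importance(forest)[, "MeanDecreaseGini"]
  imp <- sort(imp, decreasing = TRUE)

  structure(list(forest = forest, feature_cols = feature_cols,
                 medians = medians, cat_levels = cat_levels,
                 importance = data.frame(variable = names(imp),
                                         importance = unname(imp)),
                 heldout_accuracy = heldout_acc, spec = spec),
            class = "isocurate_ml_model")
}

ml_feature_frame <- function(records, feature_cols, medians, cat_levels) {
  out <- lapply(feature_cols, function(col) {
    v <- records[[col]]
    if (is.numeric(v)) {
      v[!is.finite(v)] <- medians[[col]]
      v
    } else {
      v <- as.character(v)
      v[is.na(v) | !(v %in% cat_levels[[col]])] <- "NA"
      factor(v, levels = cat_levels[[col]])
    }
  })
  names(out) <- feature_cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.isocurate_ml_model <- function(x, ...) {
  cat(sprintf("<isocurate_ml_model> %d features, held-out accuracy %.3f\n",
              length(x$feature_cols), x$heldout_accuracy))
  invisible(x)
}

#' Isoform probabilities for classification records
#'
#' Generic so that stub models (fixed per-transcript probabilities, see
#' [manual_prob_model()]) can stand in for a trained forest when probing
#' threshold behavior.
#'
#' @param model A model object.
#' @param records Classification data.frame.
#' @return Numeric vector of isoform probabilities, one per record.
#' @export
ml_predict_prob <- function(model, records) UseMethod("ml_predict_prob")

#' @export
ml_predict_prob.isocurate_ml_model <- function(model, records) {
  x <- ml_feature_frame(records, model$feature_cols, model$medians,
                        model$cat_levels)
  unname(stats::predict(model$forest, x, type = "prob")[, "isoform"])
}

#' Stub model with fixed probabilities
#'
#' @param probs Numeric vector of isoform probabilities named by transcript
#'   id.
#' @return A `manual_prob_model` usable with [score_and_filter()].
#' @export
manual_prob_model <- function(probs) {
  structure(list(probs = probs), class = "manual_prob_model")
}

#' @export
ml_predict_prob.manual_prob_model <- function(model, records) {
  unname(model$probs[records$isoform])
}

#' Score records and emit filter verdicts
#'
#' Multi-exonic transcripts are kept when their isoform probability reaches
#' `spec$threshold` (inclusive). Mono-exonic transcripts are not evaluated:
#' they are kept, unless `spec$drop_mono_exon`. With `spec$force_fsm_in`,
#' every FSM transcript is kept regardless of probability.
#'
#' @param records Classification data.frame.
#' @param model An `isocurate_ml_model` or [manual_prob_model()].
#' @param spec See [ml_training_spec()].
#' @return data.frame `isoform`, `verdict`, `reasons`, `POS_MLprob`.
#' @export
score_and_filter <- function(records, model, spec = ml_training_spec()) {
  probs <- ml_predict_prob(model, records)
  verdict <- character(nrow(records))
  reasons <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (records$exons[i] == 1L) {
      if (spec$drop_mono_exon) {
        verdict[i] <- "artifact"; reasons[i] <- "mono_exon"
      } else verdict[i] <- "isoform"
      probs[i] <- NA_real_
      next
    }
    if (spec$force_fsm_in && records$structural_category[i] == "FSM") {
      verdict[i] <- "isoform"
      next
    }
    if (!is.na(probs[i]) && probs[i] >= spec$threshold) {
      verdict[i] <- "isoform"
    } else {
      verdict[i] <- "artifact"; reasons[i] <- "ml_probability"
    }
  }
  data.frame(isoform = records$isoform, verdict = verdict, reasons = reasons,
             POS_MLprob = probs, stringsAsFactors = FALSE)
}
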