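#' Build a corrupted spike-in annotation scenario
#'
#' Starting from the true (complete and correct) spike-in annotation, this
#' removes `n_true_removed` transcripts from the annotation even though they
#' remain present in the simulated RNA mix (the "novel true positive"
#' scenario) and fabricates `n_false` plausible but absent models (the
#' "over-annotated false positive" scenario). Fabricated models are
#' internal-exon-skip variants of true transcripts, falling back to
#' 100-300 bp end shifts for genes without skippable exons; duplicates of
#' existing models are rejected. Deterministic given `seed`.
#'
#' @param true_transcripts Named list of `transcript_model`s: the complete
#'   and correct annotation, all present in the sample.
#' @param n_false Number of fabricated models to add.
#' @param n_true_removed Number of true transcripts to remove from the
#'   annotation.
#' @param seed Integer seed.
#' @return A `sirv_scenario`: `true`, `modified`, `fabricated_ids`,
#'   `removed_ids`.
#' @export
build_scenario <- function(true_transcripts, n_false, n_true_removed, seed = 1) {
  if (n_true_removed > length(true_transcripts))
    stop("cannot remove more transcripts than the annotation contains")
  set.seed(seed)
  ids <- sort(names(true_transcripts))
  removed <- if (n_true_removed > 0) sort(sample(ids, n_true_removed)) else character(0)

  existing_chains <- vapply(true_transcripts, chain_key, character(1))
  fabricated <- list()
  # exon-skip fabrication over shuffled (transcript, internal exon) pairs
  combos <- do.call(rbind, lapply(ids, function(id) {
    n <- tm_n_exons(true_transcripts[[id]])
    if (n >= 3L) data.frame(id = id, exon = 2:(n - 1L)) else NULL
  }))
  if (!is.null(combos)) combos <- combos[sample(nrow(combos)), , drop = FALSE]
  k <- 0L
  for (r in seq_len(NROW(combos))) {
    if (k >= n_false) break
    src <- true_transcripts[[combos$id[r]]]
    ex <- src$exons[-combos$exon[r], , drop = FALSE]
    cand <- transcript_model(sprintf("FALSE_SIRV_%03d", k + 1L),
                             gene_id = src$gene_id, chrom = src$chrom,
                             strand = src$strand, exons = ex)
    ck <- chain_key(cand)
    if (ck %in% existing_chains) next
    existing_chains <- c(existing_chains, ck)
    k <- k + 1L
    fabricated[[cand$transcript_id]] <- cand
  }
  # fallback: shift both ends outward by 100-300 bp
  src_pool <- sample(ids)
  i <- 0L
  while (k < n_false && i < length(src_pool)) {
    i <- i + 1L
    src <- true_transcripts[[src_pool[i]]]
    d5 <- sample(100:300, 1L); d3 <- sample(100:300, 1L)
    ex <- src$exons
    ex[1L, 1L] <- max(0, ex[1L, 1L] - d5)
    ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] + d3
    k <- k + 1L
    cand <- transcript_model(sprintf("FALSE_SIRV_%03d", k),
                             gene_id = src$gene_id, chrom = src$chrom,
                             strand = src$strand, exons = ex)
    fabricated[[cand$transcript_id]] <- cand
  }
  if (k < n_false)
    stop("could not fabricate the requested number of false models")

  modified <- c(true_transcripts[setdiff(ids, removed)], fabricated)
  structure(list(true = true_transcripts,
                 modified = modified[order(names(modified))],
                 fabricated_ids = sort(names(fabricated)),
                 removed_ids = removed,
                 n_false_added = n_false,
                 n_true_removed = n_true_removed),
            class = "sirv_scenario")
}

#' Tally detections against a spike-in scenario
#'
#' Each detected model is classified against both the true and the modified
#' annotation. A detection matching a true transcript as an FSM reference
#' match is a known TP when that transcript is still annotated in the
#' modified reference, and a novel TP when it was removed. A detection
#' matching a fabricated model as an FSM reference match (without matching
#' any true model) is an over-annotation FP. An FSM to a true transcript
#' with either end off by more than the reference-match window is a partial
#' TP. Detections classified NIC or NNC against both annotations are FPs.
#' Matched classes are de-duplicated by matched annotation model, so a true
#' transcript detected twice (or re-added by rescue) counts once and
#' sensitivity cannot exceed 1; FPs count detections. Detections matching
#' nothing spike-in-like (e.g. fragments) enter `n_detected` only.
#'
#' @param detected Named list of detected `transcript_model`s.
#' @param scenario A `sirv_scenario`.
#' @param ref_match_window End window in bp (default 50, as in
#'   classification).
#' @return A `sirv_tally` list of counts.
#' @export
tally_detections <- function(detected, scenario, ref_match_window = 50) {
  idx_true <- build_reference_index(scenario$true, min_ref_len = 0)
  idx_mod <- build_reference_index(scenario$modified, min_ref_len = 0)
  cls_true <- classify_transcripts(detected, idx_true,
                                   ref_match_window = ref_match_window)
  cls_mod <- classify_transcripts(detected, idx_mod,
                                  ref_match_window = ref_match_window)
  known <- character(0); novel <- character(0); partial <- character(0)
  overannot <- character(0); fp <- 0L; n_detected <- 0L
  for (i in seq_len(nrow(cls_true))) {
    ct <- cls_true[i, ]; cm <- cls_mod[i, ]
    sirv_like <- ct$structural_category %in% c("FSM", "ISM", "NIC", "NNC") ||
      cm$structural_category %in% c("FSM", "ISM", "NIC", "NNC")
    if (sirv_like) n_detected <- n_detected + 1L
    if (ct$structural_category == "FSM" && ct$subcategory == "reference_match") {
      t <- ct$associated_transcript
      if (t %in% names(scenario$modified)) known <- union(known, t)
      else novel <- union(novel, t)
    } else if (cm$structural_category == "FSM" &&
               cm$subcategory == "reference_match" &&
               cm$associated_transcript %in% scenario$fabricated_ids) {
      overannot <- union(overannot, cm$associated_transcript)
    } else if (ct$structural_category == "FSM" &&
               ct$subcategory != "mono-exon") {
      partial <- union(partial, ct$associated_transcript)
    } else if (ct$structural_category %in% c("NIC", "NNC") &&
               cm$structural_category %in% c("NIC", "NNC")) {
      fp <- fp + 1L
    }
  }
  structure(list(known_TP = length(known), novel_TP = length(novel),
                 partial_TP = length(partial), overannot_FP = length(overannot),
                 FP = fp, n_introduced = length(scenario$true),
                 n_detected = n_detected),
            class = "sirv_tally")
}

#' Spike-in performance metrics
#'
#' The six detection metrics:
#' \deqn{Sensitivity = (known TP + novel TP) / introduced}
#' \deqn{Precision = (known TP + novel TP) / detected}
#' \deqn{Fscore = 2 \cdot Sens \cdot Prec / (Sens + Prec)}
#' \deqn{FDR = (FP + overannot FP + partial TP) / detected}
#' \deqn{ODR = overannot FP / detected}
#' \deqn{NDR = (novel TP + FP) / detected}
#' Zero denominators (including a zero F-score denominator) yield `NA`.
#'
#' @param t A `sirv_tally` or any list with the same count fields.
#' @return Named list `sensitivity`, `precision`, `fscore`, `fdr`, `odr`,
#'   `ndr`.
#' @export
compute_metrics <- function(t) {
  tp <- t$known_TP + t$novel_TP
  sens <- if (t$n_introduced > 0) tp / t$n_introduced else NA_real_
  prec <- if (t$n_detected > 0) tp / t$n_detected else NA_real_
  fscore <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  div <- function(num) if (t$n_detected > 0) num / t$n_detected else NA_real_
  list(sensitivity = sens, precision = prec, fscore = fscore,
       fdr = div(t$FP + t$overannot_FP + t$partial_TP),
       odr = div(t$overannot_FP),
       ndr = div(t$novel_TP + t$FP))
}
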