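#' Automatic rescue of reference transcripts for removed FSMs
#'
#' An FSM artifact usually means the end validation failed while the splice
#' chain is annotated; the associated reference transcript is therefore
#' added back, unless an FSM of that reference already passed the filter.
#' Each reference id is added at most once.
#'
#' @param records Classification data.frame of the long-read set.
#' @param decisions Filter decisions for `records`.
#' @param curated_ids Ids currently in the curated transcriptome (the
#'   filter-passing long-read models).
#' @return Character vector of reference transcript ids to add.
#' @export
automatic_rescue <- function(records, decisions, curated_ids) {
  verdict <- decisions$verdict[match(records$isoform, decisions$isoform)]
  is_fsm <- records$structural_category == "FSM"
  removed_refs <- unique(records$associated_transcript[
    is_fsm & verdict == "artifact"])
  kept_refs <- unique(records$associated_transcript[
    is_fsm & verdict == "isoform"])
  sort(setdiff(setdiff(removed_refs, kept_refs), curated_ids))
}

#' Select rescue candidates
#'
#' Multi-exonic artifacts of the ISM, NIC and NNC categories; ISM artifacts
#' are skipped when any FSM in the dataset is associated with the same
#' reference transcript (the automatic step covers that reference).
#'
#' @inheritParams automatic_rescue
#' @return Character vector of candidate transcript ids.
#' @export
select_rescue_candidates <- function(records, decisions) {
  verdict <- decisions$verdict[match(records$isoform, decisions$isoform)]
  fsm_refs <- unique(records$associated_transcript[
    records$structural_category == "FSM"])
  keep <- verdict == "artifact" & records$exons > 1L &
    (records$structural_category %in% c("NIC", "NNC") |
       (records$structural_category == "ISM" &
          !(records$associated_transcript %in% fsm_refs)))
  sort(records$isoform[keep])
}

#' Map rescue candidates to potential replacement targets
#'
#' For each candidate, targets are all long-read models and reference
#' transcripts of the gene(s) the candidate was classified against. The
#' internal mapper scores a candidate/target pair as the fraction of the
#' candidate's junctions present in the target's chain plus the Jaccard
#' index of their exonic base sets (0..2); at most `max_hits` hits per
#' candidate are kept (primary plus up to 6 secondary by default, mirroring
#' a spliced aligner's default secondary-alignment cap). Externally computed
#' hits (e.g. from a SAM alignment of candidate to target sequences) may be
#' supplied to downstream steps in the same shape.
#'
#' @param candidates Candidate transcript ids.
#' @param records Classification data.frame of the long-read set.
#' @param queries Named list of long-read `transcript_model`s.
#' @param index Reference index.
#' @param max_hits Per-candidate hit cap (default 7).
#' @return data.frame `candidate_id`, `target_id`, `target_kind`
#'   (`"reference"`/`"long_read"`), `score`.
#' @export
map_candidates <- function(candidates, records, queries, index, max_hits = 7) {
  rows <- list()
  for (cid in candidates) {
    cand <- queries[[cid]]
    gene <- records$associated_gene[records$isoform == cid]
    if (length(gene) != 1L || is.na(gene) || gene == "novel") next
    ref_ids <- index$genes[[gene]]
    lr_ids <- setdiff(records$isoform[records$associated_gene == gene], cid)
    targets <- c(stats::setNames(rep("reference", length(ref_ids)), ref_ids),
                 stats::setNames(rep("long_read", length(lr_ids)), lr_ids))
    if (length(targets) == 0L) next
    hit <- do.call(rbind, lapply(names(targets), function(tid) {
      tgt <- if (targets[[tid]] == "reference") index$transcripts[[tid]] else
        queries[[tid]]
      data.frame(candidate_id = cid, target_id = tid,
                 target_kind = targets[[tid]],
                 score = mapping_score(cand, tgt), stringsAsFactors = FALSE)
    }))
    hit <- hit[hit$score > 0, , drop = FALSE]
    hit <- hit[order(-hit$score, hit$target_id), , drop = FALSE]
    if (nrow(hit) > max_hits) hit <- hit[seq_len(max_hits), , drop = FALSE]
    rows[[length(rows) + 1L]] <- hit
  }
  if (length(rows) == 0L)
    return(data.frame(candidate_id = character(0), target_id = character(0),
                      target_kind = character(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Junction-chain compatibility plus exon-space similarity.
mapping_score <- function(cand, tgt) {
  if (cand$chrom != tgt$chrom || cand$strand != tgt$strand) return(0)
  ck <- junction_keys(cand)
  jfrac <- if (length(ck) == 0L) 0 else mean(ck %in% junction_keys(tgt))
  jfrac + exon_jaccard(cand, tgt)
}

#' Characterize and filter the reference transcriptome for rescue
#'
#' The rescue step only trusts reference targets that would themselves pass
#' the filter, so the reference annotation is run through QC and the same
#' filter configuration as the long-read set. The reference is
#' characterized against itself with `min_ref_len = 0` so that short
#' annotated transcripts are classified rather than silently dropped; every
#' reference transcript self-classifies as an FSM reference match with zero
#' end distances.
#'
#' @param ref_transcripts Named list of reference `transcript_model`s
#'   (loaded with `min_len = 0`).
#' @param mode `"rules"` or `"ml"`.
#' @param rules A `rules_spec` (rules mode), the same one used on the
#'   long-read set.
#' @param ml_model A pre-trained `isocurate_ml_model` (ml mode), the same
#'   one used on the long-read set.
#' @param ml_spec [ml_training_spec()] used for thresholding in ml mode.
#' @inheritParams compute_qc_tables
#' @return List with `records` (classification data.frame) and `decisions`.
#' @export
validate_reference_targets <- function(ref_transcripts, mode = c("rules", "ml"),
                                       rules = NULL, ml_model = NULL,
                                       ml_spec = ml_training_spec(),
                                       genome = NULL, cage_peaks = NULL,
                                       polya_peaks = NULL, polya_motifs = NULL,
                                       coverage = NULL, sj = NULL,
                                       params = qc_params()) {
  mode <- match.arg(mode)
  self_index <- build_reference_index(ref_transcripts, min_ref_len = 0)
  qc <- compute_qc_tables(ref_transcripts, self_index, genome = genome,
                          cage_peaks = cage_peaks, polya_peaks = polya_peaks,
                          polya_motifs = polya_motifs, coverage = coverage,
                          sj = sj, params = params)
  decisions <- if (mode == "rules") {
    if (is.null(rules)) stop("rules mode needs the rules_spec used on the long-read set")
    apply_rules(qc$classification, rules)
  } else {
    if (is.null(ml_model)) stop("ml mode needs the pre-trained model used on the long-read set")
    score_and_filter(qc$classification, ml_model, ml_spec)
  }
  list(records = qc$classification, decisions = decisions)
}

#' Resolve mapping hits into rescue outcomes
#'
#' Hits whose target failed its filter are dropped. In ml mode the single
#' best surviving target by isoform probability is chosen (ties by mapping
#' score, then id); in rules mode every surviving reference target is
#' considered. A candidate whose retained target is a long-read model
#' already in the curated set is already represented; reference targets are
#' deduplicated across candidates and checked for redundancy (a reference
#' already represented by a curated FSM, or already added, is not added
#' again).
#'
#' @param hits data.frame from [map_candidates()].
#' @param decisions Long-read filter decisions (with `POS_MLprob` in ml
#'   mode).
#' @param ref_decisions Reference-side decisions from
#'   [validate_reference_targets()].
#' @param records Long-read classification data.frame (for redundancy
#'   checks).
#' @param curated_ids Filter-passing long-read ids.
#' @param mode `"rules"` or `"ml"`.
#' @return List with `outcomes` (data.frame `artifact_id`, `action`,
#'   `chosen_target`) and `additions` (reference ids to add).
#' @export
resolve_hits <- function(hits, decisions, ref_decisions, records, curated_ids,
                         mode = c("rules", "ml")) {
  mode <- match.arg(mode)
  lr_pass <- decisions$isoform[decisions$verdict == "isoform"]
  ref_pass <- ref_decisions$decisions$isoform[
    ref_decisions$decisions$verdict == "isoform"]
  represented_refs <- unique(records$associated_transcript[
    records$structural_category == "FSM" & records$isoform %in% curated_ids])

  additions <- character(0)
  outcomes <- list()
  for (cid in sort(unique(hits$candidate_id))) {
    h <- hits[hits$candidate_id == cid, , drop = FALSE]
    ok <- (h$target_kind == "long_read" & h$target_id %in% lr_pass) |
      (h$target_kind == "reference" & h$target_id %in% ref_pass)
    h <- h[ok, , drop = FALSE]
    if (nrow(h) == 0L) {
      outcomes[[cid]] <- c(cid, "unrescued", NA_character_)
      next
    }
    if (mode == "ml") {
      prob <- ifelse(h$target_kind == "long_read",
                     decisions$POS_MLprob[match(h$target_id, decisions$isoform)],
                     ref_decisions$decisions$POS_MLprob[
                       match(h$target_id, ref_decisions$decisions$isoform)])
      prob[is.na(prob)] <- -1
      h <- h[order(-prob, -h$score, h$target_id), , drop = FALSE]
      best <- h[1L, ]
      if (best$target_kind == "long_read") {
        action <- if (best$target_id %in% curated_ids) "already_represented"
        else "rescued_long_read"
        outcomes[[cid]] <- c(cid, action, best$target_id)
      } else if (best$target_id %in% represented_refs ||
                 best$target_id %in% curated_ids) {
        outcomes[[cid]] <- c(cid, "already_represented", best$target_id)
      } else {
        additions <- union(additions, best$target_id)
        outcomes[[cid]] <- c(cid, "rescued_reference", best$target_id)
      }
    } else {
      refs <- h[h$target_kind == "reference", , drop = FALSE]
      new_refs <- refs$target_id[!(refs$target_id %in% represented_refs) &
                                   !(refs$target_id %in% curated_ids)]
      if (length(new_refs) > 0L) {
        additions <- union(additions, new_refs)
        best_ref <- refs$target_id[refs$target_id %in% new_refs][1L]
        outcomes[[cid]] <- c(cid, "rescued_reference", best_ref)
      } else if (any(h$target_kind == "long_read" &
                     h$target_id %in% curated_ids) || nrow(refs) > 0L) {
        outcomes[[cid]] <- c(cid, "already_represented", h$target_id[1L])
      } else {
        outcomes[[cid]] <- c(cid, "unrescued", NA_character_)
      }
    }
  }
  out <- as.data.frame(do.call(rbind, outcomes), stringsAsFactors = FALSE)
  if (nrow(out) > 0L) names(out) <- c("artifact_id", "action", "chosen_target")
  else out <- data.frame(artifact_id = character(0), action = character(0),
                         chosen_target = character(0))
  rownames(out) <- NULL
  list(outcomes = out, additions = sort(additions))
}

#' Run the full rescue stage
#'
#' Applies automatic FSM rescue, candidate selection, candidate-to-target
#' mapping and hit resolution, returning the expanded curated transcriptome.
#'
#' @param records Long-read classification data.frame.
#' @param decisions Long-read filter decisions.
#' @param queries Named list of long-read `transcript_model`s.
#' @param index Reference index the long-read set was classified against.
#' @param ref_validation Output of [validate_reference_targets()].
#' @param mode `"rules"` or `"ml"`.
#' @param max_hits Per-candidate mapping hit cap (default 7).
#' @return List with `curated_ids` (kept long-read ids), `additions`
#'   (reference ids added, automatic + by mapping), `outcomes` (per-artifact
#'   actions) and `final_ids` (curated + additions).
#' @export
run_rescue_stage <- function(records, decisions, queries, index,
                             ref_validation, mode = c("rules", "ml"),
                             max_hits = 7) {
  mode <- match.arg(mode)
  curated_ids <- decisions$isoform[decisions$verdict == "isoform"]
  auto <- automatic_rescue(records, decisions, curated_ids)
  cands <- select_rescue_candidates(records, decisions)
  hits <- map_candidates(cands, records, queries, index, max_hits = max_hits)
  res <- resolve_hits(hits, decisions, ref_validation, records, curated_ids,
                      mode = mode)
  unresolved <- setdiff(cands, res$outcomes$artifact_id)
  if (length(unresolved) > 0L) {
    res$outcomes <- rbind(res$outcomes,
                          data.frame(artifact_id = unresolved,
                                     action = "unrescued",
                                     chosen_target = NA_character_))
  }
  additions <- sort(union(auto, setdiff(res$additions, curated_ids)))
  list(curated_ids = sort(curated_ids),
       additions = additions,
       automatic_additions = auto,
       outcomes = res$outcomes[order(res$outcomes$artifact_id), , drop = FALSE],
       final_ids = sort(union(curated_ids, additions)))
}
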