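# Small classification/decision scaffolding for the rescue unit tests.
mk_records <- function(df) {
  base <- stub_records(nrow(df))
  base$isoform <- df$isoform
  base$structural_category <- df$category
  base$associated_gene <- df$gene
  base$associated_transcript <- df$ref
  base$exons <- if (is.null(df$exons)) 3L else df$exons
  base
}
mk_decisions <- function(records, artifacts, probs = NULL) {
  data.frame(isoform = records$isoform,
             verdict = ifelse(records$isoform %in% artifacts, "artifact",
                              "isoform"),
             reasons = "", POS_MLprob = if (is.null(probs)) 0.9 else probs,
             stringsAsFactors = FALSE)
}

test_that("automatic rescue adds each removed FSM's reference once", {
  rec <- mk_records(data.frame(
    isoform = c("q1", "q2", "q3", "q4"),
    category = c("FSM", "FSM", "FSM", "FSM"),
    gene = "A", ref = c("A.1", "A.1", "A.2", "A.3")))
  dec <- mk_decisions(rec, artifacts = c("q1", "q2", "q3"))
  curated <- dec$isoform[dec$verdict == "isoform"]
  # q1, q2 share A.1 -> one addition; A.3 has passing FSM q4? no, q4 is A.3
  dec2 <- mk_decisions(rec, artifacts = c("q1", "q2"))
  expect_equal(automatic_rescue(rec, dec2,
                                dec2$isoform[dec2$verdict == "isoform"]),
               "A.1")
  # a reference with a surviving FSM is not re-added
  rec3 <- mk_records(data.frame(isoform = c("q1", "q2"),
                                category = c("FSM", "FSM"), gene = "A",
                                ref = c("A.1", "A.1")))
  dec3 <- mk_decisions(rec3, artifacts = "q1")
  expect_length(automatic_rescue(rec3, dec3, "q2"), 0L)
  # nothing removed, nothing added
  dec4 <- mk_decisions(rec, artifacts = character(0))
  expect_length(automatic_rescue(rec, dec4, rec$isoform), 0L)
})

test_that("rescue candidates are multi-exonic ISM/NIC/NNC artifacts without FSM cover", {
  rec <- mk_records(data.frame(
    isoform = c("f1", "i1", "i2", "n1", "n2", "a1", "m1"),
    category = c("FSM", "ISM", "ISM", "NIC", "NNC", "antisense", "ISM"),
    gene = "A",
    ref = c("A.1", "A.1", "A.2", "novel", "novel", "novel", "A.3"),
    exons = c(3L, 3L, 3L, 3L, 3L, 3L, 1L)))
  dec <- mk_decisions(rec, artifacts = c("i1", "i2", "n1", "n2", "a1", "m1"))
  cands <- select_rescue_candidates(rec, dec)
  # i1 is covered by FSM f1 on A.1; antisense and mono-exon never qualify
  expect_setequal(cands, c("i2", "n1", "n2"))
})

test_that("the internal mapper ranks the degraded candidate's source first and caps hits", {
  refs <- tiny_reference()
  idx <- build_reference_index(refs)
  cand <- mk_tm("cand", refs$A.1$exons[2:4, ])   # degraded copy of A.1
  queries <- list(cand = cand)
  rec <- mk_records(data.frame(isoform = "cand", category = "ISM",
                               gene = "A", ref = "A.1"))
  hits <- map_candidates("cand", rec, queries, idx)
  expect_equal(hits$target_id[1L], "A.1")
  expect_equal(hits$target_kind[1L], "reference")
  expect_gt(hits$score[1L], max(hits$score[-1L]))

  # hit cap: a gene with 10 isoform targets yields at most 7 hits
  many <- lapply(1:10, function(k) {
    ex <- refs$A.1$exons
    ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] + k  # distinct ends, same chain
    mk_tm(sprintf("B.%02d", k), ex, gene = "B")
  })
  names(many) <- vapply(many, `[[`, "", "transcript_id")
  idx_b <- build_reference_index(many)
  rec_b <- mk_records(data.frame(isoform = "cand", category = "ISM",
                                 gene = "B", ref = "B.01"))
  hits_b <- map_candidates("cand", rec_b, list(cand = cand), idx_b)
  expect_lte(nrow(hits_b), 7L)
  expect_equal(nrow(hits_b), 7L)

  # candidates without a gene association produce no hits
  rec_n <- mk_records(data.frame(isoform = "cand", category = "NNC",
                                 gene = "novel", ref = "novel"))
  expect_equal(nrow(map_candidates("cand", rec_n, list(cand = cand), idx)), 0L)
})

test_that("hit resolution follows probability in ml mode and keeps all passing refs in rules mode", {
  hits <- data.frame(candidate_id = "c1",
                     target_id = c("refA", "refB", "lr1"),
                     target_kind = c("reference", "reference", "long_read"),
                     score = c(1.5, 1.4, 1.2), stringsAsFactors = FALSE)
  records <- mk_records(data.frame(isoform = "lr1", category = "NIC",
                                   gene = "A", ref = "novel"))
  decisions <- mk_decisions(records, artifacts = character(0), probs = 0.75)
  refd <- list(decisions = data.frame(
    isoform = c("refA", "refB"), verdict = "isoform", reasons = "",
    POS_MLprob = c(0.9, 0.8), stringsAsFactors = FALSE))

  ml <- resolve_hits(hits, decisions, refd, records, curated_ids = "lr1",
                     mode = "ml")
  expect_equal(ml$outcomes$action, "rescued_reference")
  expect_equal(ml$outcomes$chosen_target, "refA")
  expect_equal(ml$additions, "refA")

  # the long-read target wins on probability -> already represented
  refd_low <- refd
  refd_low$decisions$POS_MLprob <- c(0.5, 0.4)
  ml2 <- resolve_hits(hits, decisions, refd_low, records, curated_ids = "lr1",
                      mode = "ml")
  expect_equal(ml2$outcomes$action, "already_represented")
  expect_length(ml2$additions, 0L)

  rules <- resolve_hits(hits, decisions, refd, records, curated_ids = "lr1",
                        mode = "rules")
  expect_setequal(rules$additions, c("refA", "refB"))

  # a failing target is never chosen
  refd_fail <- refd
  refd_fail$decisions$verdict <- c("artifact", "isoform")
  ml3 <- resolve_hits(hits, decisions, refd_fail, records, curated_ids = "lr1",
                      mode = "ml")
  expect_equal(ml3$outcomes$chosen_target, "refB")

  # two candidates resolving to one reference add it once
  hits2 <- rbind(hits, transform(hits, candidate_id = "c2"))
  ml4 <- resolve_hits(hits2, decisions, refd, records, curated_ids = "lr1",
                      mode = "ml")
  expect_equal(ml4$additions, "refA")
  expect_equal(nrow(ml4$outcomes), 2L)
})

test_that("rescue conserves transcripts and can only grow the gene set", {
  b <- generate_fixture(fixture_spec(
    n_genes = 8, isoforms_per_gene = 2,
    mix = c(reference_match = 8, ism_3prime_fragment = 6,
            nnc_noncanonical = 6, intrapriming = 3)), seed = 31)
  idx <- build_reference_index(b$reference)
  qc <- compute_qc_tables(b$query, idx, genome = b$genome,
                          cage_peaks = b$cage_peaks, polya_peaks = b$polya_peaks,
                          polya_motifs = b$motifs, coverage = b$coverage,
                          sj = b$sj)
  dec <- apply_rules(qc$classification, default_rules())
  refv <- validate_reference_targets(b$reference, mode = "rules",
                                     rules = default_rules(),
                                     genome = b$genome,
                                     cage_peaks = b$cage_peaks,
                                     polya_peaks = b$polya_peaks,
                                     polya_motifs = b$motifs,
                                     coverage = b$coverage, sj = b$sj)
  # reference self-classification: all FSM reference matches at distance 0
  expect_true(all(refv$records$structural_category == "FSM"))
  expect_true(all(refv$records$subcategory %in% c("reference_match", "mono-exon")))
  expect_true(all(refv$records$diff_to_TSS[refv$records$exons > 1] == 0))

  res <- run_rescue_stage(qc$classification, dec, b$query, idx, refv,
                          mode = "rules")
  # conservation: every input transcript is kept or has exactly one outcome
  artifacts <- dec$isoform[dec$verdict == "artifact"]
  expect_setequal(c(res$curated_ids, artifacts), qc$classification$isoform)
  non_cand <- setdiff(artifacts, c(res$outcomes$artifact_id))
  expect_equal(length(res$curated_ids) + length(res$outcomes$artifact_id) +
                 length(non_cand), nrow(qc$classification))
  # additions are reference ids, unique, disjoint from kept query ids
  expect_false(any(res$additions %in% res$curated_ids))
  expect_equal(anyDuplicated(res$additions), 0L)
  expect_true(all(res$additions %in% names(b$reference)))
  # gene-count monotonicity
  genes_of <- function(ids) unique(c(
    qc$classification$associated_gene[qc$classification$isoform %in% ids],
    vapply(b$reference[intersect(ids, names(b$reference))], `[[`, "",
           "gene_id")))
  expect_true(all(genes_of(res$curated_ids) %in% genes_of(res$final_ids)))
})

test_that("rescue recovers deleted source models through reference targets", {
  # every query is a degraded fragment whose source transcript is absent
  # from the long-read set; a 5'-support rule removes them all
  b <- generate_fixture(fixture_spec(
    n_genes = 10, isoforms_per_gene = 1,
    mix = c(ism_3prime_fragment = 10)), seed = 17)
  idx <- build_reference_index(b$reference)
  qc <- compute_qc_tables(b$query, idx, genome = b$genome,
                          cage_peaks = b$cage_peaks, polya_peaks = b$polya_peaks,
                          polya_motifs = b$motifs, coverage = b$coverage,
                          sj = b$sj)
  rules <- parse_rules('{"rest":[{"ratio_TSS":[1.5,1e9]}]}')
  dec <- apply_rules(qc$classification, rules)
  expect_true(all(dec$verdict == "artifact"))
  refv <- validate_reference_targets(b$reference, mode = "rules",
                                     rules = rules, genome = b$genome,
                                     cage_peaks = b$cage_peaks,
                                     polya_peaks = b$polya_peaks,
                                     polya_motifs = b$motifs,
                                     coverage = b$coverage, sj = b$sj)
  res <- run_rescue_stage(qc$classification, dec, b$query, idx, refv,
                          mode = "rules")
  sources <- unique(b$truth$source_transcript)
  recovered <- mean(sources %in% res$additions)
  expect_gte(recovered, 0.9)
})
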