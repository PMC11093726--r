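test_that("splice-chain matching distinguishes full, subchain and none", {
  refs <- tiny_reference()
  q_full <- mk_tm("q", refs$A.1$exons)
  expect_equal(match_splice_chain(q_full, refs$A.1), "full")

  # last 2 of the reference's 3 junctions
  q_sub <- mk_tm("q", refs$A.1$exons[2:4, ])
  expect_equal(match_splice_chain(q_sub, refs$A.1), "consecutive_subchain")

  # junctions {J1, J3} of {J1, J2, J3}: non-contiguous
  q_gap <- mk_tm("q", rbind(c(100, 200), c(500, 1150), c(1500, 1700)))
  expect_equal(match_splice_chain(q_gap, refs$A.1), "none")

  expect_error(match_splice_chain(mk_tm("q", cbind(100, 200)), refs$A.1),
               "multi-exonic")
})

test_that("category priority assigns FSM, ISM, NIC, NNC and locus classes", {
  idx <- tiny_index()
  refs <- tiny_reference()

  fsm <- classify_transcript(mk_tm("q", refs$A.1$exons), idx)
  expect_equal(fsm$structural_category, "FSM")
  expect_equal(fsm$subcategory, "reference_match")
  expect_equal(fsm$associated_transcript, "A.1")
  expect_equal(fsm$diff_to_TSS, 0)

  ism <- classify_transcript(mk_tm("q", refs$A.1$exons[2:4, ]), idx)
  expect_equal(ism$structural_category, "ISM")
  expect_equal(ism$subcategory, "3prime_fragment")

  # junctions {J1, J3}: all known, novel combination
  nic <- classify_transcript(
    mk_tm("q", rbind(c(100, 200), c(500, 1150), c(1500, 1700))), idx)
  expect_equal(nic$structural_category, "NIC")
  expect_equal(nic$subcategory, "combination_of_known_junctions")
  expect_equal(nic$associated_gene, "A")

  # novel junction from known donor 650 and known acceptor 1500
  cks <- classify_transcript(
    mk_tm("q", rbind(c(500, 650), c(1500, 1700))), idx)
  expect_equal(cks$structural_category, "NIC")
  expect_equal(cks$subcategory, "combination_of_known_splicesites")

  # one novel donor (position 210)
  nnc <- classify_transcript(
    mk_tm("q", rbind(c(100, 210), c(500, 650), c(1000, 1150), c(1500, 1700))),
    idx)
  expect_equal(nnc$structural_category, "NNC")
  expect_equal(nnc$subcategory, "at_least_one_novel_splicesite")

  # spliced query fully inside intron 1 of gene A, same strand
  genic <- classify_transcript(
    mk_tm("q", rbind(c(220, 280), c(350, 430))), idx)
  expect_equal(genic$structural_category, "genic_genomic")

  anti <- classify_transcript(
    mk_tm("q", rbind(c(100, 200), c(500, 650)), strand = "-"), idx)
  expect_equal(anti$structural_category, "antisense")

  inter <- classify_transcript(
    mk_tm("q", rbind(c(20000, 20150), c(20400, 20500))), idx)
  expect_equal(inter$structural_category, "intergenic")
  expect_equal(inter$associated_gene, "novel")
})

test_that("a chain concatenating junctions of two disjoint loci is a fusion", {
  refs <- list(
    B.1 = mk_tm("B.1", rbind(c(100, 200), c(500, 700)), gene = "B"),
    C.1 = mk_tm("C.1", rbind(c(5000, 5200), c(5500, 5700)), gene = "C"))
  idx <- build_reference_index(refs)
  fus <- classify_transcript(
    mk_tm("q", rbind(c(100, 200), c(500, 700), c(5000, 5200), c(5500, 5700))),
    idx)
  expect_equal(fus$structural_category, "fusion")
  expect_equal(fus$subcategory, "multi-exon")
  # but multiple isoforms of ONE gene never trigger fusion
  one_gene <- classify_transcript(
    mk_tm("q", rbind(c(100, 200), c(500, 1150), c(1500, 1700))), tiny_index())
  expect_equal(one_gene$structural_category, "NIC")
})

test_that("the reference-match window is inclusive at 50 bp", {
  expect_equal(assign_fsm_subcategory(0, 0), "reference_match")
  expect_equal(assign_fsm_subcategory(50, -50), "reference_match")
  expect_equal(assign_fsm_subcategory(51, 0), "alternative_5end")
  expect_equal(assign_fsm_subcategory(0, -51), "alternative_3end")
  expect_equal(assign_fsm_subcategory(200, 300), "alternative_3end5end")
})

test_that("ISM subcategories reflect the missing side and intron retention", {
  refs <- tiny_reference()
  idx <- tiny_index()
  ex <- refs$A.1$exons

  r3 <- classify_transcript(mk_tm("q", ex[2:4, ]), idx)
  expect_equal(r3$subcategory, "3prime_fragment")
  r5 <- classify_transcript(mk_tm("q", ex[1:3, ]), idx)
  expect_equal(r5$subcategory, "5prime_fragment")
  ri <- classify_transcript(mk_tm("q", ex[2:3, ]), idx)
  expect_equal(ri$subcategory, "internal_fragment")

  # exon bridging the retained last intron
  ir <- classify_transcript(
    mk_tm("q", rbind(ex[1:2, ], c(1000, 1700))), idx)
  expect_equal(ir$subcategory, "intron_retention")

  # on the minus strand the missing side flips
  refs_m <- list(D.1 = mk_tm("D.1", ex, strand = "-", gene = "D"))
  idx_m <- build_reference_index(refs_m)
  m3 <- classify_transcript(mk_tm("q", ex[1:3, ], strand = "-"), idx_m)
  expect_equal(m3$subcategory, "3prime_fragment")
  m5 <- classify_transcript(mk_tm("q", ex[2:4, ], strand = "-"), idx_m)
  expect_equal(m5$subcategory, "5prime_fragment")
})

test_that("mono-exon queries follow the overlap rules", {
  idx <- tiny_index()
  # contained in exon 2 of multi-exonic A.1
  ism <- classify_transcript(mk_tm("q", cbind(520, 640)), idx)
  expect_equal(ism$structural_category, "ISM")
  expect_equal(ism$subcategory, "mono-exon")
  # overlapping the mono-exonic reference
  fsm <- classify_transcript(mk_tm("q", cbind(5100, 5300)), idx)
  expect_equal(fsm$structural_category, "FSM")
  expect_equal(fsm$subcategory, "mono-exon")
  expect_equal(fsm$associated_transcript, "M.1")
  # crossing an exon boundary without containment
  nic <- classify_transcript(mk_tm("q", cbind(450, 560)), idx)
  expect_equal(nic$structural_category, "NIC")
  expect_equal(nic$subcategory, "mono-exon")
  # spanning a whole annotated intron
  ir <- classify_transcript(mk_tm("q", cbind(600, 1100)), idx)
  expect_equal(ir$subcategory, "mono-exon_by_intron_retention")
  # intron-only
  gg <- classify_transcript(mk_tm("q", cbind(250, 400)), idx)
  expect_equal(gg$structural_category, "genic_genomic")
  # no overlap at all
  inter <- classify_transcript(mk_tm("q", cbind(30000, 30200)), idx)
  expect_equal(inter$structural_category, "intergenic")
})

test_that("FSM ties resolve by closest ends then transcript id", {
  ex <- rbind(c(100, 200), c(500, 700))
  refs <- list(
    Z.2 = mk_tm("Z.2", rbind(c(90, 200), c(500, 700)), gene = "Z"),
    Z.1 = mk_tm("Z.1", rbind(c(100, 200), c(500, 710)), gene = "Z"))
  idx <- build_reference_index(refs)
  # query matches Z.1 ends at |d5|=0,|d3|=10 (sum 10) vs Z.2 sum 10: tie -> id
  q <- classify_transcript(mk_tm("q", ex), idx)
  expect_equal(q$associated_transcript, "Z.1")
  # closer ends win over id order
  q2 <- classify_transcript(mk_tm("q", rbind(c(95, 200), c(500, 700))), idx)
  expect_equal(q2$associated_transcript, "Z.2")
})

test_that("classification is order-independent and labels stay admissible", {
  b <- generate_fixture(fixture_spec(n_genes = 6, mix = label_coverage_mix()),
                        seed = 42)
  idx <- build_reference_index(b$reference)
  cls <- classify_transcripts(b$query, idx)
  cls_rev <- classify_transcripts(rev(b$query), idx)
  reord <- cls_rev[match(cls$isoform, cls_rev$isoform), ]
  rownames(reord) <- NULL
  expect_equal(reord, cls)

  adm <- admissible_labels()
  expect_true(all(paste(cls$structural_category, cls$subcategory) %in%
                    paste(adm$structural_category, adm$subcategory)))
  expect_equal(nrow(adm), 22L)
})

test_that("category calls are invariant under genome mirror-image", {
  b <- generate_fixture(fixture_spec(n_genes = 5, mix = label_coverage_mix()),
                        seed = 9)
  L <- nchar(genome_chars(b$genome)[["chr1"]], type = "bytes")
  refs_f <- lapply(b$reference, flip_tm, chrom_len = L)
  qry_f <- lapply(b$query, flip_tm, chrom_len = L)
  cls <- classify_transcripts(b$query, build_reference_index(b$reference))
  cls_f <- classify_transcripts(qry_f, build_reference_index(refs_f))
  expect_equal(cls_f$structural_category, cls$structural_category)
  expect_equal(cls_f$subcategory, cls$subcategory)
})

test_that("the classifier agrees with the brute-force oracle on random fixtures", {
  set.seed(2024)
  for (rep in 1:25) {
    b <- generate_fixture(random_fixture_spec(), seed = 1000 + rep)
    idx <- build_reference_index(b$reference)
    cls <- classify_transcripts(b$query, idx)
    for (i in seq_along(b$query)) {
      oc <- oracle_classify(b$query[[i]], b$reference)
      expect_equal(cls$structural_category[i], oc$category,
                   info = sprintf("rep %d query %s", rep, cls$isoform[i]))
      expect_equal(cls$subcategory[i], oc$subcategory,
                   info = sprintf("rep %d query %s", rep, cls$isoform[i]))
    }
  }
})
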