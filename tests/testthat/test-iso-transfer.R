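# Donor: 3 exons, CDS covering the middle of the transcript.
mk_donor <- function() {
  mk_tm("D1", rbind(c(100, 200), c(300, 400), c(500, 600)), gene = "G",
        cds = c(150, 550))
}
donor_features <- function() {
  data.frame(
    donor_id = "D1", level = c("UTR", "CDS_transcript", "protein", "gene"),
    label = c("utr_motif", "domain1", "site1", "GO:0001"),
    # transcript coords: exon1 = 1..100, exon2 = 101..200, exon3 = 201..300;
    # domain1 (t 150..230) crosses the exon2/exon3 junction (genomic 400/500)
    t_start = c(10, 150, 120, 1), t_end = c(40, 230, 130, 1),
    stringsAsFactors = FALSE)
}

test_that("identical transcripts receive the donor's own annotations back", {
  don <- mk_donor()
  donors <- list(transcripts = list(D1 = don), features = donor_features())
  acc <- don
  out <- transfer_features(list(acc), donors, novel_mode = FALSE)
  expect_equal(nrow(out), 4L)
  expect_setequal(out$label, donor_features()$label)
  # positions round-trip exactly for the donor itself
  expect_equal(out$t_start[out$label == "domain1"], 150)
  expect_equal(out$t_end[out$label == "domain1"], 230)
})

test_that("UTR features must avoid the acceptor CDS and stay exonic", {
  don <- mk_donor()
  donors <- list(transcripts = list(D1 = don), features = donor_features())
  # acceptor with CDS covering the whole transcript: UTR feature now overlaps
  acc_allcds <- mk_tm("A1", don$exons, gene = "G", cds = c(100, 600))
  out <- transfer_features(list(acc_allcds), donors)
  expect_false("utr_motif" %in% out$label)
  # acceptor missing exon 1 entirely: UTR span is not exonic
  acc_noex1 <- mk_tm("A2", don$exons[2:3, ], gene = "G", cds = c(310, 550))
  out2 <- transfer_features(list(acc_noex1), donors)
  expect_false("utr_motif" %in% out2$label)
})

test_that("multi-exon CDS features require matching internal boundaries", {
  don <- mk_donor()
  donors <- list(transcripts = list(D1 = don), features = donor_features())
  # domain1 spans donor exons 2-3 (transcript 150..230 -> crosses 400/500)
  same_bnd <- mk_tm("A3", rbind(c(250, 400), c(500, 620)), gene = "G",
                    cds = c(260, 610))
  out <- transfer_features(list(same_bnd), donors)
  expect_true("domain1" %in% out$label)
  # acceptor junction shifted: boundary mismatch blocks the transfer
  diff_bnd <- mk_tm("A4", rbind(c(250, 410), c(500, 620)), gene = "G",
                    cds = c(260, 610))
  out2 <- transfer_features(list(diff_bnd), donors)
  expect_false("domain1" %in% out2$label)
})

test_that("protein features follow the CDS identity / partial-overlap rules", {
  don <- mk_donor()
  donors <- list(transcripts = list(D1 = don), features = donor_features())
  # identical CDS exon set, different UTR: all protein features transfer
  same_cds <- mk_tm("A5", rbind(c(80, 200), c(300, 400), c(500, 650)),
                    gene = "G", cds = c(150, 550))
  expect_true("site1" %in% transfer_features(list(same_cds), donors)$label)
  # site1 sits in donor exon 2 (genomic 319..329); an acceptor sharing only
  # exon 2 of the CDS transfers it via the partial-match rule
  partial <- mk_tm("A6", rbind(c(300, 400), c(700, 800)), gene = "G",
                   cds = c(300, 750))
  expect_true("site1" %in% transfer_features(list(partial), donors)$label)
  # no CDS overlap at all: nothing transfers at protein level
  nocds <- mk_tm("A7", rbind(c(700, 800), c(900, 1000)), gene = "G",
                 cds = c(710, 950))
  expect_false("site1" %in% transfer_features(list(nocds), donors)$label)
  # non-coding acceptor: protein features are skipped
  noncoding <- mk_tm("A8", don$exons, gene = "G")
  expect_false("site1" %in% transfer_features(list(noncoding), donors)$label)
})

test_that("duplicates collapse and the transfer is idempotent", {
  don <- mk_donor()
  don2 <- mk_tm("D2", don$exons, gene = "G", cds = c(150, 550))
  feats <- rbind(donor_features(),
                 transform(donor_features(), donor_id = "D2"))
  donors <- list(transcripts = list(D1 = don, D2 = don2), features = feats)
  acc <- mk_tm("A9", don$exons, gene = "G", cds = c(150, 550))
  out <- transfer_features(list(acc), donors)
  expect_equal(anyDuplicated(out[c("level", "label", "t_start", "t_end")]), 0L)
  expect_equal(nrow(out), 4L)
  out2 <- transfer_features(list(acc), donors)
  expect_identical(out, out2)
  # gene-level information follows gene identity only
  other_gene <- mk_tm("A10", don$exons, gene = "H", cds = c(150, 550))
  expect_equal(nrow(transfer_features(list(other_gene), donors)), 0L)
})

test_that("the GFF3 dialect round-trips structures and features", {
  don <- mk_donor()
  path <- tempfile(fileext = ".gff3")
  write_tappas_gff3(list(D1 = don), donor_features(), path)
  back <- read_tappas_gff3(path)
  expect_equal(back$transcripts$D1$exons, don$exons)
  expect_equal(back$transcripts$D1$cds, don$cds)
  expect_equal(back$transcripts$D1$gene_id, "G")
  expect_equal(nrow(back$features), 4L)
  expect_setequal(back$features$label, donor_features()$label)

  # structural-only output has no feature rows and parses back
  p2 <- tempfile(fileext = ".gff3")
  emit_structural_only(list(D1 = don, M = mk_tm("M", cbind(10, 60))), p2)
  lines <- readLines(p2)
  expect_equal(sum(grepl("\ttranscript\t", lines)), 2L)
  expect_equal(sum(grepl("\texon\t", lines)), 4L)
  back2 <- read_tappas_gff3(p2)
  expect_equal(nrow(back2$features), 0L)
  expect_equal(back2$transcripts$M$exons, mk_tm("M", cbind(10, 60))$exons)

  # empty input still yields a valid header-only file
  p3 <- tempfile(fileext = ".gff3")
  emit_structural_only(list(), p3)
  expect_equal(readLines(p3), "##gff-version 3")
})
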