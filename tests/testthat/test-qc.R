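test_that("TSS ratio reproduces the pseudocount formula on plateau coverage", {
  mk_cov <- function(inside, outside) {
    # TSS at 1000 on +: inside = [1000, 1100), outside = [900, 1000)
    coverage_track(data.frame(chrom = "chr1", start = c(900, 1000),
                              end = c(1000, 1100), value = c(outside, inside)))
  }
  r <- function(ci, co) compute_tss_ratio(1000, "+", "chr1", list(mk_cov(ci, co)))
  expect_identical(r(7, 7), 1.0)
  expect_identical(r(0, 0), 1.0)
  expect_equal(r(2.99, 0.99), 3.0)
  expect_equal(r(10, 0), 10.01 / 0.01)

  # minus strand: inside is the window left of (and including) the TSS
  tr <- coverage_track(data.frame(chrom = "chr1", start = c(901, 1001),
                                  end = c(1001, 1101), value = c(6, 2)))
  expect_equal(compute_tss_ratio(1000, "-", "chr1", list(tr)),
               (6 + 0.01) / (2 + 0.01))
})

test_that("replicate TSS ratios aggregate with max by default", {
  cov1 <- coverage_track(data.frame(chrom = "chr1", start = c(900, 1000),
                                    end = c(1000, 1100), value = c(1, 1.2)))
  cov2 <- coverage_track(data.frame(chrom = "chr1", start = c(900, 1000),
                                    end = c(1000, 1100), value = c(1, 3.4)))
  r1 <- compute_tss_ratio(1000, "+", "chr1", list(cov1))
  r2 <- compute_tss_ratio(1000, "+", "chr1", list(cov2))
  both <- list(cov1, cov2)
  expect_equal(compute_tss_ratio(1000, "+", "chr1", both), max(r1, r2))
  expect_equal(compute_tss_ratio(1000, "+", "chr1", both, aggregate = "mean"),
               mean(c(r1, r2)))
  expect_equal(compute_tss_ratio(1000, "+", "chr1", both, aggregate = "median"),
               stats::median(c(r1, r2)))
})

test_that("TSS ratio moves toward the raw ratio as coverage scales up", {
  vals <- vapply(c(1, 10, 100, 1000), function(c0) {
    tr <- coverage_track(data.frame(chrom = "chr1", start = c(900, 1000),
                                    end = c(1000, 1100),
                                    value = c(1 * c0, 3 * c0)))
    compute_tss_ratio(1000, "+", "chr1", list(tr))
  }, numeric(1))
  expect_true(all(diff(abs(vals - 3)) < 0))   # monotone approach to 3
})

test_that("intrapriming flags A-rich downstream windows inclusively", {
  for (k in c(0, 11, 12, 20)) {
    g <- flat_genome()
    if (k > 0) g <- plant_str(g, "chr1", 1001, strrep("A", k))
    ip <- compute_intrapriming(1000, "+", "chr1", g)
    expect_equal(ip$perc_A, k / 20)
    expect_equal(ip$flag, k >= 12)          # 12/20 = 60 %, inclusive
  }
  # minus strand reads the reverse complement (T-tract upstream)
  g <- plant_str(flat_genome(), "chr1", 980, strrep("T", 20))
  ipm <- compute_intrapriming(1000, "-", "chr1", g)
  expect_equal(ipm$perc_A, 1.0)
  expect_true(ipm$flag)
  # window clipped to nothing at the chromosome end
  g2 <- flat_genome(len = 1001)
  ip2 <- compute_intrapriming(1000, "+", "chr1", g2)
  expect_equal(ip2$perc_A, 0)
  expect_false(ip2$flag)
})

test_that("polyA motif search scans the terminal window only", {
  motifs <- c("AATAAA", "ATTAAA")
  base <- strrep("C", 200)
  at_dist <- function(d) {
    s <- base
    substr(s, 200 - d - 5, 200 - d) <- "AATAAA"
    s
  }
  hit <- find_polya_motif(at_dist(18), motifs)
  expect_equal(hit$motif, "AATAAA")
  expect_equal(hit$polyA_dist, 18)
  expect_equal(find_polya_motif(at_dist(50), motifs)$polyA_dist, 50)
  expect_null(find_polya_motif(at_dist(51), motifs))
  expect_null(find_polya_motif(at_dist(60), motifs))
  expect_null(find_polya_motif(base, motifs))
  # the occurrence closest to the 3' end wins
  s2 <- at_dist(40)
  substr(s2, 200 - 10 - 5, 200 - 10) <- "ATTAAA"
  expect_equal(find_polya_motif(s2, motifs)$motif, "ATTAAA")
  # short transcripts are scanned whole
  expect_equal(find_polya_motif("AATAAACC", motifs)$polyA_dist, 2)
})

test_that("peak support distinguishes containment and eligible midpoints", {
  peaks <- data.frame(chrom = "chr1", start = c(950, 1200), end = c(1010, 1260),
                      strand = "*", mid = c(980, 1230))
  class(peaks) <- c("peak_set", class(peaks))
  inpeak <- peak_support(1000, "+", "chr1", peaks, "five_prime")
  expect_true(inpeak$within)
  expect_equal(inpeak$dist, -20)            # midpoint 980, 20 bp upstream
  # midpoint 30 bp upstream of the TSS
  up <- peak_support(1010, "+", "chr1", peaks[1, ], "five_prime")
  expect_equal(up$dist, -30)
  # the only peak is downstream and non-containing: ineligible for a TSS
  down <- peak_support(1100, "+", "chr1", peaks[2, ], "five_prime")
  expect_false(down$within)
  expect_true(is.na(down$dist))
  # ...but eligible for a TTS, with positive (downstream) distance
  tts <- peak_support(1100, "+", "chr1", peaks[2, ], "three_prime")
  expect_equal(tts$dist, 130)
  # minus strand: upstream is the high-coordinate side
  upm <- peak_support(1100, "-", "chr1", peaks[2, ], "five_prime")
  expect_equal(upm$dist, -130)
})

test_that("junction motifs, canonical status and support come out right", {
  g <- flat_genome()
  g <- plant_str(g, "chr1", 500, "GT")
  g <- plant_str(g, "chr1", 798, "AG")
  sj <- sj_support(list(rep1 = data.frame(key = "chr1:+:500-800", count = 7)))
  jq <- junction_qc("chr1:+:500-800", g, sj)
  expect_equal(jq$splice_motif, "GT-AG")
  expect_true(jq$canonical)
  expect_equal(jq$total_cov, 7)

  # same genomic bases on the minus strand read CT-AC
  jm <- junction_qc("chr1:-:500-800", g, sj = NULL)
  expect_equal(jm$splice_motif, "CT-AC")
  expect_false(jm$canonical)

  g2 <- plant_str(plant_str(flat_genome(), "chr1", 500, "CT"),
                  "chr1", 798, "AC")
  expect_true(junction_qc("chr1:-:500-800", g2)$canonical)
  expect_equal(junction_qc("chr1:+:500-800", g2)$splice_motif, "CT-AC")

  expect_equal(junction_qc("chr1:+:600-900", g, sj)$total_cov, 0)
})

test_that("RTS flags exact direct repeats spanning the junction boundaries", {
  rep8 <- "GATTACCA"
  g <- rnd_genome()
  g <- plant_str(g, "chr1", 492, rep8)      # donor window [492, 508)
  g <- plant_str(g, "chr1", 800, rep8)      # acceptor window [792, 808)
  expect_true(rts_flag("chr1:+:500-800", g))
  expect_false(rts_flag("chr1:+:500-800", rnd_genome()))
  # a window shorter than the repeat can never contain it
  expect_false(rts_flag("chr1:+:500-800", g, repeat_len = 20))
  # repeat fully outside the boundary windows does not flag
  g2 <- plant_str(plant_str(rnd_genome(), "chr1", 460, rep8), "chr1", 900, rep8)
  expect_false(rts_flag("chr1:+:500-800", g2))
})

test_that("sequence attributes are invariant under genome mirror-image", {
  b <- generate_fixture(fixture_spec(
    n_genes = 4, mix = c(reference_match = 4, intrapriming = 2, rts = 1)),
    seed = 21)
  gc <- genome_chars(b$genome)
  L <- nchar(gc[["chr1"]], type = "bytes")
  gf <- flip_genome(gc)
  qf <- lapply(b$query, flip_tm, chrom_len = L)
  for (i in seq_along(b$query)) {
    tm <- b$query[[i]]; fm <- qf[[i]]
    ip <- compute_intrapriming(tm_tts(tm), tm$strand, tm$chrom, gc)
    ipf <- compute_intrapriming(tm_tts(fm), fm$strand, fm$chrom, gf)
    expect_equal(ipf$perc_A, ip$perc_A, info = tm$transcript_id)
    expect_identical(find_polya_motif(tm_sequence(tm, gc), b$motifs),
                     find_polya_motif(tm_sequence(fm, gf), b$motifs))
    k <- junction_keys(tm); kf <- junction_keys(fm)
    if (length(k) > 0) {
      expect_equal(junction_qc(rev(kf)[1], gf)$splice_motif,
                   junction_qc(k[1], gc)$splice_motif, info = tm$transcript_id)
      expect_equal(rts_flag(rev(kf)[1], gf), rts_flag(k[1], gc))
    }
  }
})

test_that("planted fixture attributes are recovered exactly", {
  b <- generate_fixture(fixture_spec(
    n_genes = 6, isoforms_per_gene = 2,
    mix = c(reference_match = 6, ism_3prime_fragment = 3,
            nnc_noncanonical = 2, intrapriming = 2, rts = 1)), seed = 5)
  idx <- build_reference_index(b$reference)
  qc <- compute_qc_tables(b$query, idx, genome = b$genome,
                          cage_peaks = b$cage_peaks,
                          polya_peaks = b$polya_peaks,
                          polya_motifs = b$motifs, coverage = b$coverage,
                          sj = b$sj)
  cls <- qc$classification
  rm_ <- b$truth$type == "reference_match"
  # analytic plateau: inside 10x, outside 0 -> (10.01)/(0.01)
  expect_equal(cls$ratio_TSS[rm_], rep(10.01 / 0.01, sum(rm_)))
  expect_true(all(cls$within_CAGE_peak[rm_]))
  expect_true(all(cls$within_polyA_site[rm_]))
  expect_equal(cls$polyA_motif[rm_], rep("AATAAA", sum(rm_)))
  expect_equal(cls$polyA_dist[rm_], rep(17, sum(rm_)))
  expect_equal(cls$min_cov[rm_], rep(35, sum(rm_)))
  expect_true(all(cls$all_canonical[rm_]))
  expect_false(any(cls$intrapriming[rm_]))
  # degraded 5' fragments sit inside uniform coverage: ratio exactly 1
  frag <- b$truth$type == "ism_3prime_fragment"
  expect_equal(cls$ratio_TSS[frag], rep(1, sum(frag)))
  expect_false(any(cls$within_CAGE_peak[frag]))
  # planted artifacts
  expect_identical(cls$intrapriming, b$truth$intrapriming_planted)
  expect_identical(cls$RTS_stage, b$truth$rts_planted)
  expect_equal(cls$perc_A_downstream_TTS[b$truth$intrapriming_planted],
               rep(0.8, 2))
  nnc <- b$truth$type == "nnc_noncanonical"
  expect_false(any(cls$all_canonical[nnc]))
  expect_equal(cls$min_cov[nnc], rep(0, sum(nnc)))
})
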