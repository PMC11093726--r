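#' Fixture specification
#'
#' Describes a synthetic study: a random genome, a multi-isoform reference
#' annotation, and a query transcript set with planted truth labels plus the
#' orthogonal evidence around it (CAGE-like 5' peaks, polyA 3' peaks, polyA
#' motifs, per-replicate short-read coverage with an analytic step at every
#' true TSS, and short-read junction support). All annotated introns carry
#' canonical GT-AG sites; artifact constructs plant their own signal
#' (noncanonical/unsupported junctions, A-rich downstream windows, direct
#' repeats at junction boundaries, degraded 5' ends).
#'
#' `mix` is a named count vector over query construct types:
#' `reference_match`, `alternative_5end`, `alternative_3end`,
#' `alternative_3end5end`, `fsm_mono_exon`, `ism_3prime_fragment`,
#' `ism_5prime_fragment`, `ism_internal_fragment`, `ism_intron_retention`,
#' `ism_mono_exon`, `nic_combination_of_known_junctions`,
#' `nic_combination_of_known_splicesites`, `nic_mono_exon`,
#' `nic_mono_exon_by_intron_retention`, `nnc`, `nnc_noncanonical`, `rts`,
#' `intrapriming`, `fusion`, `antisense_multi`, `antisense_mono`,
#' `genic_multi`, `genic_mono`, `intergenic_multi`, `intergenic_mono`.
#'
#' @param n_genes Number of multi-exonic genes.
#' @param isoforms_per_gene 1-3 annotated isoforms per gene.
#' @param n_exons Range (min, max) of exons per gene (min 4).
#' @param exon_len,intron_len Ranges in bp.
#' @param mix Named counts of query constructs (see above).
#' @param peak_halfwidth Peak half-width in bp (default 25).
#' @param peak_jitter Uniform jitter applied to peak placement, bp
#'   (default 0).
#' @param gap Intergenic gap between genes, bp (default 5000).
#' @param n_chroms Number of chromosomes (1-3).
#' @param coverage_values Per-replicate plateau coverage over gene bodies.
#' @param sj_values Per-replicate unique-read counts for supported
#'   junctions.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 8, isoforms_per_gene = 2,
                         n_exons = c(4, 6), exon_len = c(120, 250),
                         intron_len = c(300, 800),
                         mix = c(reference_match = 4, ism_3prime_fragment = 2,
                                 nnc_noncanonical = 2, intrapriming = 1),
                         peak_halfwidth = 25, peak_jitter = 0, gap = 5000,
                         n_chroms = 1,
                         coverage_values = c(rep1 = 10, rep2 = 8),
                         sj_values = c(rep1 = 20, rep2 = 15)) {
  stopifnot(n_exons[1L] >= 4, n_chroms >= 1, n_chroms <= 3,
            exon_len[1L] >= 120, intron_len[1L] >= 300)
  structure(list(n_genes = n_genes, isoforms_per_gene = isoforms_per_gene,
                 n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len, mix = mix,
                 peak_halfwidth = peak_halfwidth, peak_jitter = peak_jitter,
                 gap = gap, n_chroms = n_chroms,
                 coverage_values = coverage_values, sj_values = sj_values),
            class = "fixture_spec")
}

#' One exemplar per admissible classification label
#'
#' @return Named count vector realizing all 22 (category, subcategory)
#'   pairs.
#' @export
label_coverage_mix <- function() {
  c(reference_match = 1, alternative_5end = 1, alternative_3end = 1,
    alternative_3end5end = 1, fsm_mono_exon = 1,
    ism_3prime_fragment = 1, ism_5prime_fragment = 1,
    ism_internal_fragment = 1, ism_intron_retention = 1, ism_mono_exon = 1,
    nic_combination_of_known_junctions = 1,
    nic_combination_of_known_splicesites = 1,
    nic_mono_exon = 1, nic_mono_exon_by_intron_retention = 1,
    nnc = 1, fusion = 1, antisense_multi = 1, antisense_mono = 1,
    genic_multi = 1, genic_mono = 1, intergenic_multi = 1,
    intergenic_mono = 1)
}

#' Generate a fixture bundle
#'
#' Deterministic given `seed`: the same seed reproduces the bundle (and its
#' serialized files) byte for byte.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A `fixture_bundle`: `genome` (DNAStringSet), `reference` and
#'   `query` (named lists of `transcript_model`s), `truth` (data.frame),
#'   `cage_peaks`, `polya_peaks`, `motifs`, `coverage` (list of
#'   `coverage_track`s), `sj` (`sj_support`).
#' @export
generate_fixture <- function(spec, seed = 1) {
  set.seed(seed)
  mix <- spec$mix[spec$mix > 0]
  need_mono_gene <- "fsm_mono_exon" %in% names(mix)

  ## ---- gene layout ----
  strands <- rep(c("+", "+", "-", "-"), length.out = spec$n_genes)
  chrom_of <- paste0("chr", rep(seq_len(spec$n_chroms),
                                each = ceiling(spec$n_genes / spec$n_chroms),
                                length.out = spec$n_genes))
  cursor <- stats::setNames(rep(2000, spec$n_chroms),
                            paste0("chr", seq_len(spec$n_chroms)))
  genes <- vector("list", spec$n_genes)
  resample <- function(x, ...) x[sample.int(length(x), ...)]
  for (i in seq_len(spec$n_genes)) {
    ne <- resample(spec$n_exons[1L]:spec$n_exons[2L], 1L)
    elens <- resample(spec$exon_len[1L]:spec$exon_len[2L], ne, replace = TRUE)
    ilens <- resample(spec$intron_len[1L]:spec$intron_len[2L], ne - 1L,
                      replace = TRUE)
    chrom <- chrom_of[i]
    gs <- cursor[[chrom]]
    starts <- gs + cumsum(c(0, elens[-ne] + ilens))
    exons <- cbind(starts, starts + elens)
    cursor[[chrom]] <- exons[ne, 2L] + spec$gap
    genes[[i]] <- list(gene_id = sprintf("G%03d", i), chrom = chrom,
                       strand = strands[i], exons = exons, mono = FALSE)
  }
  mono_gene <- NULL
  if (need_mono_gene) {
    gs <- cursor[["chr1"]]
    mono_gene <- list(gene_id = "GMONO", chrom = "chr1", strand = "+",
                      exons = cbind(gs, gs + 300), mono = TRUE)
    cursor[["chr1"]] <- gs + 300 + spec$gap
  }

  ## ---- genome scaffold ----
  chrom_len <- cursor + 2000
  ctx <- new.env(parent = emptyenv())
  ctx$chrom <- lapply(chrom_len, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  ctx$supported <- character(0)

  ## ---- reference isoforms ----
  reference <- list()
  for (g in genes) {
    n <- nrow(g$exons)
    iso <- list(g$exons)
    if (spec$isoforms_per_gene >= 2L) iso <- c(iso, list(g$exons[-2L, , drop = FALSE]))
    if (spec$isoforms_per_gene >= 3L) iso <- c(iso, list(g$exons[-(n - 1L), , drop = FALSE]))
    for (k in seq_along(iso)) {
      tid <- sprintf("%s.%d", g$gene_id, k)
      reference[[tid]] <- transcript_model(tid, gene_id = g$gene_id,
                                           chrom = g$chrom, strand = g$strand,
                                           exons = iso[[k]])
    }
  }
  if (!is.null(mono_gene)) {
    reference[["GMONO.1"]] <- transcript_model("GMONO.1", gene_id = "GMONO",
                                               chrom = "chr1", strand = "+",
                                               exons = mono_gene$exons)
  }

  # canonical sites at every annotated intron; supported junctions; 3' plants
  for (tm in reference) {
    j <- tm_junctions(tm)
    for (r in seq_len(nrow(j))) {
      if (tm$strand == "+") {
        plant(ctx, tm$chrom, j[r, 1L], "GT"); plant(ctx, tm$chrom, j[r, 2L] - 2, "AG")
      } else {
        plant(ctx, tm$chrom, j[r, 1L], "CT"); plant(ctx, tm$chrom, j[r, 2L] - 2, "AC")
      }
    }
    ctx$supported <- union(ctx$supported, junction_keys(tm))
  }
  all_genes <- c(genes, if (!is.null(mono_gene)) list(mono_gene))
  for (g in all_genes) {
    tts <- if (g$strand == "+") g$exons[nrow(g$exons), 2L] - 1 else g$exons[1L, 1L]
    plant_downstream_tts(ctx, g$chrom, g$strand, tts, "ACGTACGTACGTACGTACGT")
    plant_motif_at_dist(ctx, g$chrom, g$strand, tts, "AATAAA", 17)
  }

  ## ---- queries ----
  fusion_partner <- vapply(seq_len(spec$n_genes), function(i) {
    if (i < spec$n_genes && strands[i + 1L] == strands[i] &&
        chrom_of[i + 1L] == chrom_of[i]) i + 1L else NA_integer_
  }, integer(1))
  queries <- list(); truth <- list()
  qn <- 0L
  occ_count <- new.env(parent = emptyenv())
  for (type in names(mix)) {
    eligible <- if (type == "fsm_mono_exon") {
      if (is.null(mono_gene)) stop("mix requests fsm_mono_exon but no mono gene")
      list(mono_gene)
    } else if (type == "fusion") {
      gl <- genes[!is.na(fusion_partner)]
      if (length(gl) == 0L) stop("fusion requested but no same-strand adjacent gene pair")
      gl
    } else genes
    for (k in seq_len(mix[[type]])) {
      gi <- ((k - 1L) %% length(eligible)) + 1L
      g <- eligible[[gi]]
      okey <- paste(type, g$gene_id, sep = "|")
      occ <- (get0(okey, occ_count) %||% 0L) + 1L
      assign(okey, occ, occ_count)
      qn <- qn + 1L
      qid <- sprintf("Q%04d", qn)
      partner <- if (type == "fusion") genes[[fusion_partner[[match(g$gene_id,
        vapply(genes, `[[`, character(1), "gene_id"))]]]] else NULL
      built <- build_query(type, qid, g, occ, spec, ctx, partner)
      queries[[qid]] <- built$model
      truth[[qid]] <- built$truth
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ## ---- genome, evidence tracks ----
  genome <- Biostrings::DNAStringSet(vapply(ctx$chrom, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(ctx$chrom)

  jit <- function() if (spec$peak_jitter > 0)
    sample(-spec$peak_jitter:spec$peak_jitter, 1L) else 0
  peak_row <- function(g, at) {
    c0 <- at + jit()
    data.frame(chrom = g$chrom, start = c0 - spec$peak_halfwidth,
               end = c0 + spec$peak_halfwidth + 1, strand = g$strand,
               stringsAsFactors = FALSE)
  }
  cage <- do.call(rbind, lapply(all_genes, function(g) {
    peak_row(g, if (g$strand == "+") g$exons[1L, 1L] else g$exons[nrow(g$exons), 2L] - 1)
  }))
  pa <- do.call(rbind, lapply(all_genes, function(g) {
    peak_row(g, if (g$strand == "+") g$exons[nrow(g$exons), 2L] - 1 else g$exons[1L, 1L])
  }))
  cage$mid <- floor((cage$start + cage$end) / 2)
  pa$mid <- floor((pa$start + pa$end) / 2)
  class(cage) <- c("peak_set", class(cage)); attr(cage, "kind") <- "five_prime"
  class(pa) <- c("peak_set", class(pa)); attr(pa, "kind") <- "three_prime"

  cov_df <- do.call(rbind, lapply(all_genes, function(g) {
    data.frame(chrom = g$chrom, start = g$exons[1L, 1L],
               end = g$exons[nrow(g$exons), 2L], value = 1,
               stringsAsFactors = FALSE)
  }))
  cov_df <- cov_df[order(cov_df$chrom, cov_df$start), , drop = FALSE]
  coverage <- lapply(names(spec$coverage_values), function(r) {
    d <- cov_df; d$value <- spec$coverage_values[[r]]
    coverage_track(d, r)
  })
  names(coverage) <- names(spec$coverage_values)

  skeys <- sort(ctx$supported)
  sj <- sj_support(lapply(spec$sj_values, function(v) {
    data.frame(key = skeys, count = rep(v, length(skeys)),
               stringsAsFactors = FALSE)
  }))

  structure(list(genome = genome, reference = reference, query = queries,
                 truth = truth, cage_peaks = cage, polya_peaks = pa,
                 motifs = c("AATAAA", "ATTAAA", "AGTAAA", "TATAAA"),
                 coverage = coverage, sj = sj, spec = spec, seed = seed),
            class = "fixture_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plant <- function(ctx, chrom, start0, seq) {
  ctx$chrom[[chrom]][(start0 + 1):(start0 + nchar(seq))] <-
    strsplit(seq, "")[[1L]]
}

# Plant `seq` so it occupies the `window` immediately downstream of the TTS
# on the transcript strand (reverse-complemented on minus).
plant_downstream_tts <- function(ctx, chrom, strand, tts, seq) {
  if (strand == "+") plant(ctx, chrom, tts + 1, seq)
  else plant(ctx, chrom, tts - nchar(seq), revcomp(seq))
}

# Plant `seq` inside the transcript so that its last base sits `dist` nt
# before the 3' end (assumes the region lies within the 3'-terminal exon).
plant_motif_at_dist <- function(ctx, chrom, strand, tts, seq, dist) {
  if (strand == "+") plant(ctx, chrom, tts - dist - nchar(seq) + 1, seq)
  else plant(ctx, chrom, tts + dist, revcomp(seq))
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## ---- query constructors ----

build_query <- function(type, qid, g, occ, spec, ctx, partner = NULL) {
  ex <- g$exons
  n <- nrow(ex)
  plus <- g$strand == "+"
  mk <- function(exons, strand = g$strand, chrom = g$chrom) {
    transcript_model(qid, gene_id = qid, chrom = chrom, strand = strand,
                     exons = exons)
  }
  tr <- function(category, subcategory, source = NA_character_,
                 is_artifact = FALSE, intrapriming = FALSE, rts = FALSE) {
    data.frame(isoform = qid, type = type, structural_category = category,
               subcategory = subcategory, source_gene = g$gene_id,
               source_transcript = source, is_artifact = is_artifact,
               intrapriming_planted = intrapriming, rts_planted = rts,
               stringsAsFactors = FALSE)
  }
  ext5 <- function(e, d) { if (plus) e[1L, 1L] <- e[1L, 1L] - d else e[nrow(e), 2L] <- e[nrow(e), 2L] + d; e }
  ext3 <- function(e, d) { if (plus) e[nrow(e), 2L] <- e[nrow(e), 2L] + d else e[1L, 1L] <- e[1L, 1L] - d; e }
  r1 <- sprintf("%s.1", g$gene_id)

  switch(type,
    reference_match = {
      n_iso <- 1L + (spec$isoforms_per_gene >= 2L) + (spec$isoforms_per_gene >= 3L)
      k <- ((occ - 1L) %% n_iso) + 1L
      iso_ex <- switch(k, ex, ex[-2L, , drop = FALSE], ex[-(n - 1L), , drop = FALSE])
      list(model = mk(iso_ex),
           truth = tr("FSM", "reference_match", sprintf("%s.%d", g$gene_id, k)))
    },
    alternative_5end = list(model = mk(ext5(ex, 100)),
                            truth = tr("FSM", "alternative_5end", r1)),
    alternative_3end = list(model = mk(ext3(ex, 100)),
                            truth = tr("FSM", "alternative_3end", r1)),
    alternative_3end5end = list(model = mk(ext3(ext5(ex, 120), 100)),
                                truth = tr("FSM", "alternative_3end5end", r1)),
    fsm_mono_exon = list(model = mk(ex),
                         truth = tr("FSM", "mono-exon", sprintf("%s.1", g$gene_id))),
    ism_3prime_fragment = {
      e <- if (plus) ex[-1L, , drop = FALSE] else ex[-n, , drop = FALSE]
      list(model = mk(e), truth = tr("ISM", "3prime_fragment", r1,
                                     is_artifact = TRUE))
    },
    ism_5prime_fragment = {
      e <- if (plus) ex[-n, , drop = FALSE] else ex[-1L, , drop = FALSE]
      list(model = mk(e), truth = tr("ISM", "5prime_fragment", r1,
                                     is_artifact = TRUE))
    },
    ism_internal_fragment = list(model = mk(ex[-c(1L, n), , drop = FALSE]),
                                 truth = tr("ISM", "internal_fragment", r1,
                                            is_artifact = TRUE)),
    ism_intron_retention = {
      e <- rbind(ex[seq_len(n - 2L), , drop = FALSE],
                 c(ex[n - 1L, 1L], ex[n, 2L]))
      list(model = mk(e), truth = tr("ISM", "intron_retention", r1))
    },
    ism_mono_exon = list(model = mk(cbind(ex[2L, 1L] + 10, ex[2L, 2L] - 10)),
                         truth = tr("ISM", "mono-exon", r1)),
    nic_combination_of_known_junctions = {
      e <- rbind(ex[1L, ], c(ex[2L, 1L], ex[3L, 2L]),
                 ex[4:n, , drop = FALSE])
      list(model = mk(e),
           truth = tr("NIC", "combination_of_known_junctions"))
    },
    nic_combination_of_known_splicesites = {
      e <- rbind(ex[1L, ], ex[4:n, , drop = FALSE])
      ctx$supported <- union(ctx$supported,
        sprintf("%s:%s:%d-%d", g$chrom, g$strand, ex[1L, 2L], ex[4L, 1L]))
      list(model = mk(e),
           truth = tr("NIC", "combination_of_known_splicesites"))
    },
    nic_mono_exon = list(model = mk(cbind(ex[2L, 1L] - 50, ex[2L, 1L] + 60)),
                         truth = tr("NIC", "mono-exon")),
    nic_mono_exon_by_intron_retention =
      list(model = mk(cbind(ex[2L, 2L] - 50, ex[3L, 1L] + 50)),
           truth = tr("NIC", "mono-exon_by_intron_retention")),
    nnc = {
      # novel-donor offsets: canonical 12+6k, noncanonical 9+6k, RTS 29 —
      # distinct modulo 6, so plants never collide within a gene
      d <- ex[2L, 2L] + 12 + 6 * (occ - 1L)
      plant(ctx, g$chrom, d, if (plus) "GT" else "CT")
      e <- ex; e[2L, 2L] <- d
      key <- sprintf("%s:%s:%d-%d", g$chrom, g$strand, d, ex[3L, 1L])
      ctx$supported <- union(ctx$supported, key)
      list(model = mk(e), truth = tr("NNC", "at_least_one_novel_splicesite"))
    },
    nnc_noncanonical = {
      d <- ex[2L, 2L] + 9 + 6 * (occ - 1L)
      plant(ctx, g$chrom, d, "CC")
      e <- ex; e[2L, 2L] <- d
      if (plus) e[1L, 1L] <- e[1L, 1L] + 80 else e[n, 2L] <- e[n, 2L] - 80
      list(model = mk(e), truth = tr("NNC", "at_least_one_novel_splicesite",
                                     is_artifact = TRUE))
    },
    rts = {
      d <- ex[2L, 2L] + 29
      plant(ctx, g$chrom, d, "CC")
      rep8 <- "TCGATCGG"
      plant(ctx, g$chrom, d - 8, rep8)
      plant(ctx, g$chrom, ex[3L, 1L], rep8)
      e <- ex; e[2L, 2L] <- d
      list(model = mk(e), truth = tr("NNC", "at_least_one_novel_splicesite",
                                     is_artifact = TRUE, rts = TRUE))
    },
    intrapriming = {
      e <- ext3(ex, 100)
      tts <- if (plus) e[n, 2L] - 1 else e[1L, 1L]
      plant_downstream_tts(ctx, g$chrom, g$strand, tts, "AAAAAAAAAAAAAAAACGTC")
      list(model = mk(e), truth = tr("FSM", "alternative_3end", r1,
                                     is_artifact = TRUE, intrapriming = TRUE))
    },
    fusion = {
      px <- partner$exons
      e <- rbind(ex[(n - 1L):n, , drop = FALSE], px[1:2, , drop = FALSE])
      list(model = mk(e),
           truth = tr("fusion", "multi-exon"))
    },
    antisense_multi = list(model = mk(ex[2:3, , drop = FALSE],
                                      strand = flip_strand(g$strand)),
                           truth = tr("antisense", "multi-exon")),
    antisense_mono = list(model = mk(ex[2L, , drop = FALSE],
                                     strand = flip_strand(g$strand)),
                          truth = tr("antisense", "mono-exon")),
    genic_multi = {
      b <- ex[1L, 2L]
      list(model = mk(rbind(c(b + 40, b + 100), c(b + 150, b + 210))),
           truth = tr("genic_genomic", "multi-exon"))
    },
    genic_mono = {
      b <- ex[1L, 2L]
      list(model = mk(cbind(b + 40, b + 140)),
           truth = tr("genic_genomic", "mono-exon"))
    },
    intergenic_multi = {
      b <- ex[n, 2L] + 1500
      list(model = mk(rbind(c(b, b + 150), c(b + 350, b + 500))),
           truth = tr("intergenic", "multi-exon"))
    },
    intergenic_mono = {
      b <- ex[n, 2L] + 1500
      list(model = mk(cbind(b + 700, b + 900)),
           truth = tr("intergenic", "mono-exon"))
    },
    stop("unknown query construct type: ", type)
  )
}

#' Write a fixture bundle to disk
#'
#' Serializes the bundle to the standard formats: `genome.fa`,
#' `reference.gtf`, `query.gtf`, `cage.bed`, `polya_peaks.bed`,
#' `polya_motifs.txt`, `coverage_<rep>.bedGraph`, `SJ_<rep>.tab` (STAR
#' dialect) and `truth_labels.tsv`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_gtf(bundle$reference, p("reference.gtf"))
  write_gtf(bundle$query, p("query.gtf"))
  write_bed <- function(peaks, f) {
    df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                     paste0("peak", seq_len(nrow(peaks))), 0,
                     ifelse(peaks$strand == "*", ".", peaks$strand))
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(bundle$cage_peaks, "cage.bed")
  write_bed(bundle$polya_peaks, "polya_peaks.bed")
  writeLines(bundle$motifs, p("polya_motifs.txt"))
  for (r in names(bundle$coverage)) {
    seg <- bundle$coverage[[r]]$by_chrom
    df <- do.call(rbind, lapply(names(seg), function(ch) {
      data.frame(ch, seg[[ch]]$start, seg[[ch]]$end, seg[[ch]]$value)
    }))
    utils::write.table(df, p(sprintf("coverage_%s.bedGraph", r)), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (r in bundle$sj$replicates) {
    tab <- bundle$sj$tables[[r]]
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    coords <- t(vapply(parts, function(x)
      as.numeric(strsplit(x[3L], "-", fixed = TRUE)[[1L]]), numeric(2)))
    df <- data.frame(vapply(parts, `[[`, character(1), 1L),
                     as.integer(coords[, 1L]) + 1L, as.integer(coords[, 2L]),
                     match(vapply(parts, `[[`, character(1), 2L),
                           c("*", "+", "-")) - 1L,
                     1L, 1L, as.integer(tab), 0L, 30L)
    df <- df[order(df[[1L]], df[[2L]]), ]
    utils::write.table(df, p(sprintf("SJ_%s.tab", r)), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(bundle$truth, p("truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
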