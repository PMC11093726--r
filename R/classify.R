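#' Structural category label space
#'
#' The classifier assigns every query transcript exactly one of 8 structural
#' categories and one admissible subcategory; the admissible
#' (category, subcategory) pairs number exactly 22:
#'
#' * FSM: `reference_match`, `alternative_5end`, `alternative_3end`,
#'   `alternative_3end5end`, `mono-exon` (5)
#' * ISM: `3prime_fragment`, `5prime_fragment`, `internal_fragment`,
#'   `intron_retention`, `mono-exon` (5)
#' * NIC: `combination_of_known_junctions`,
#'   `combination_of_known_splicesites`, `mono-exon`,
#'   `mono-exon_by_intron_retention` (4)
#' * NNC: `at_least_one_novel_splicesite` (1)
#' * fusion: `multi-exon` (1)
#' * antisense, genic_genomic, intergenic: `mono-exon` / `multi-exon` (6)
#'
#' @return data.frame with columns `structural_category` and `subcategory`,
#'   one row per admissible pair.
#' @export
admissible_labels <- function() {
  rbind(
    data.frame(structural_category = "FSM",
               subcategory = c("reference_match", "alternative_5end",
                               "alternative_3end", "alternative_3end5end",
                               "mono-exon")),
    data.frame(structural_category = "ISM",
               subcategory = c("3prime_fragment", "5prime_fragment",
                               "internal_fragment", "intron_retention",
                               "mono-exon")),
    data.frame(structural_category = "NIC",
               subcategory = c("combination_of_known_junctions",
                               "combination_of_known_splicesites",
                               "mono-exon", "mono-exon_by_intron_retention")),
    data.frame(structural_category = "NNC",
               subcategory = "at_least_one_novel_splicesite"),
    data.frame(structural_category = "fusion", subcategory = "multi-exon"),
    data.frame(structural_category = rep(c("antisense", "genic_genomic",
                                           "intergenic"), each = 2L),
               subcategory = rep(c("multi-exon", "mono-exon"), 3L))
  )
}

#' Compare two splice-junction chains
#'
#' @param query,ref Multi-exonic `transcript_model`s on the same chromosome
#'   and strand.
#' @return `"full"` if the junction chains are identical,
#'   `"consecutive_subchain"` if the query chain is a non-empty contiguous
#'   sublist of the reference chain, else `"none"`.
#' @export
match_splice_chain <- function(query, ref) {
  if (tm_n_exons(query) < 2L || tm_n_exons(ref) < 2L)
    stop("match_splice_chain requires multi-exonic transcripts")
  qk <- junction_keys(query)
  rk <- junction_keys(ref)
  if (length(qk) == length(rk) && all(qk == rk)) return("full")
  if (find_subchain(qk, rk) > 0L) return("consecutive_subchain")
  "none"
}

# 1-based offset of qk as a contiguous sublist of rk, or 0.
find_subchain <- function(qk, rk) {
  m <- length(qk); r <- length(rk)
  if (m == 0L || m > r) return(0L)
  for (k in seq_len(r - m + 1L)) {
    if (all(rk[k:(k + m - 1L)] == qk)) return(k)
  }
  0L
}

#' Classify one query transcript
#'
#' Assigns the structural category and subcategory of a query transcript
#' model against a [build_reference_index()] index, together with the
#' associated gene/transcript and the signed distances between query and
#' reference ends (positive = query end downstream, in transcription
#' direction, of the reference end).
#'
#' Category priority for multi-exonic queries: FSM (identical junction
#' chain; ties between references broken by smallest
#' `|diff_to_TSS| + |diff_to_TTS|`, then transcript id), ISM (contiguous
#' subchain), fusion (junction chain spanning two or more mutually
#' non-overlapping same-strand gene loci), NIC/NNC by donor/acceptor/junction
#' catalog membership within the overlapped gene set, then genic_genomic
#' (intron-only overlap), antisense, intergenic. Mono-exonic queries follow
#' the overlap rules of [classify_mono_exon()].
#'
#' @param query A `transcript_model`.
#' @param index A `reference_index`.
#' @param ref_match_window End distance (bp) within which an FSM is a
#'   `reference_match`; inclusive. Default 50.
#' @return One-row data.frame of classification fields.
#' @export
classify_transcript <- function(query, index, ref_match_window = 50) {
  call_row_df(classify_row(query, index, ref_match_window))
}

classify_row <- function(query, index, ref_match_window = 50) {
  if (tm_n_exons(query) == 1L)
    return(classify_mono_row(query, index, ref_match_window))

  res <- blank_call(query)
  qk <- junction_keys(query)
  gs <- overlapping_genes(index, query$chrom, tm_start(query), tm_end(query),
                          strand = query$strand)
  go <- overlapping_genes(index, query$chrom, tm_start(query), tm_end(query),
                          strand = flip_strand(query$strand))

  # FSM: identical chain
  ck <- chain_key(query)
  fsm_ids <- index$by_chain[[ck]]
  if (!is.null(fsm_ids) && length(fsm_ids) > 0L) {
    best <- pick_closest_ends(query, index$transcripts[sort(fsm_ids)])
    return(finish_call(res, "FSM",
                       fsm_subcategory(query, best, ref_match_window),
                       query, best, index))
  }

  # ISM: contiguous non-empty subchain of a same-gene reference
  ism <- ism_matches(query, qk, index, gs)
  if (length(ism) > 0L) {
    best <- pick_closest_ends(query, ism)
    return(finish_call(res, "ISM", ism_subcategory(query, best),
                       query, best, index))
  }

  # fusion: chain spans >= 2 mutually non-overlapping same-strand loci
  if (length(gs) >= 2L) {
    comp <- locus_components(index, gs)
    if (length(unique(comp)) >= 2L) {
      res$structural_category <- "fusion"
      res$subcategory <- "multi-exon"
      res$associated_gene <- paste(sort(gs), collapse = "_")
      return(res)
    }
  }

  if (length(gs) > 0L) {
    cat_g <- gene_catalogs(index, gs)
    if (query_exonic_overlap(query, index, gs) > 0) {
      novel_site <- any(!(donor_keys(query) %in% cat_g$donors)) ||
        any(!(acceptor_keys(query) %in% cat_g$acceptors))
      if (novel_site) {
        res$structural_category <- "NNC"
        res$subcategory <- "at_least_one_novel_splicesite"
      } else if (all(qk %in% cat_g$junctions)) {
        res$structural_category <- "NIC"
        res$subcategory <- "combination_of_known_junctions"
      } else {
        res$structural_category <- "NIC"
        res$subcategory <- "combination_of_known_splicesites"
      }
      return(attach_gene(res, query, index, gs))
    }
    res$structural_category <- "genic_genomic"
    res$subcategory <- "multi-exon"
    return(attach_gene(res, query, index, gs, gene_dists = FALSE))
  }

  if (length(go) > 0L) {
    res$structural_category <- "antisense"
    res$subcategory <- "multi-exon"
    res$associated_gene <- best_overlap_gene(query, index, go)
    return(res)
  }

  res$structural_category <- "intergenic"
  res$subcategory <- "multi-exon"
  res
}

#' Classify a mono-exonic query transcript
#'
#' A mono-exon query overlapping a mono-exonic same-strand reference is FSM;
#' one lying within the boundaries of a single exon of a multi-exonic
#' reference is ISM; one overlapping same-strand exons without being
#' contained in one is NIC (subcategory `mono-exon_by_intron_retention` when
#' it fully spans an annotated intron); intron-only, antisense-only and
#' no-overlap cases map to genic_genomic, antisense and intergenic.
#'
#' @inheritParams classify_transcript
#' @return One-row data.frame of classification fields.
#' @export
classify_mono_exon <- function(query, index, ref_match_window = 50) {
  call_row_df(classify_mono_row(query, index, ref_match_window))
}

classify_mono_row <- function(query, index, ref_match_window = 50) {
  if (tm_n_exons(query) != 1L) stop("classify_mono_exon requires a mono-exon query")
  res <- blank_call(query)
  qs <- tm_start(query); qe <- tm_end(query)
  gs <- overlapping_genes(index, query$chrom, qs, qe, strand = query$strand)
  go <- overlapping_genes(index, query$chrom, qs, qe,
                          strand = flip_strand(query$strand))

  if (length(gs) > 0L) {
    cand <- index$transcripts[sort(unlist(index$genes[gs], use.names = FALSE))]
    mono_refs <- Filter(function(r) tm_n_exons(r) == 1L &&
                          tm_start(r) < qe && tm_end(r) > qs, cand)
    if (length(mono_refs) > 0L) {
      best <- pick_closest_ends(query, mono_refs)
      return(finish_call(res, "FSM", "mono-exon", query, best, index))
    }
    multi_refs <- Filter(function(r) tm_n_exons(r) > 1L, cand)
    contained <- Filter(function(r) {
      any(r$exons[, 1L] <= qs & qe <= r$exons[, 2L])
    }, multi_refs)
    if (length(contained) > 0L) {
      best <- pick_closest_ends(query, contained)
      return(finish_call(res, "ISM", "mono-exon", query, best, index))
    }
    if (query_exonic_overlap(query, index, gs) > 0) {
      cat_g <- gene_catalogs(index, gs)
      spans_intron <- any(vapply(cat_g$junctions, function(k) {
        j <- parse_junction_key(k)
        qs < j[1L] && qe > j[2L]
      }, logical(1)))
      res$structural_category <- "NIC"
      res$subcategory <- if (spans_intron) "mono-exon_by_intron_retention" else "mono-exon"
      return(attach_gene(res, query, index, gs))
    }
    res$structural_category <- "genic_genomic"
    res$subcategory <- "mono-exon"
    return(attach_gene(res, query, index, gs, gene_dists = FALSE))
  }

  if (length(go) > 0L) {
    res$structural_category <- "antisense"
    res$subcategory <- "mono-exon"
    res$associated_gene <- best_overlap_gene(query, index, go)
    return(res)
  }

  res$structural_category <- "intergenic"
  res$subcategory <- "mono-exon"
  res
}

#' Classify a set of query transcripts
#'
#' @param queries Named list of `transcript_model` objects.
#' @inheritParams classify_transcript
#' @return data.frame with one row per query, in input order, carrying
#'   `isoform`, `chrom`, `strand`, `length`, `exons`, `structural_category`,
#'   `subcategory`, `associated_gene`, `associated_transcript`,
#'   `diff_to_TSS`, `diff_to_TTS`, `diff_to_gene_TSS`, `diff_to_gene_TTS`.
#' @export
classify_transcripts <- function(queries, index, ref_match_window = 50) {
  rows <- lapply(queries, classify_row, index = index,
                 ref_match_window = ref_match_window)
  cols <- names(blank_call(queries[[1L]]))
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

## ---- internals ----

flip_strand <- function(s) if (s == "+") "-" else "+"

parse_junction_key <- function(key) {
  parts <- strsplit(sub("^[^:]+:[+-]:", "", key), "-", fixed = TRUE)[[1L]]
  as.numeric(parts)
}

call_row_df <- function(row) {
  as.data.frame(row, stringsAsFactors = FALSE)
}

blank_call <- function(query) {
  list(isoform = query$transcript_id,
             chrom = query$chrom, strand = query$strand,
             length = tm_spliced_length(query), exons = tm_n_exons(query),
             structural_category = NA_character_, subcategory = NA_character_,
             associated_gene = "novel", associated_transcript = "novel",
             diff_to_TSS = NA_real_, diff_to_TTS = NA_real_,
             diff_to_gene_TSS = NA_real_, diff_to_gene_TTS = NA_real_)
}

# Among candidate references, pick min |dTSS| + |dTTS|; ties by transcript id.
pick_closest_ends <- function(query, cands) {
  cands <- cands[order(names(cands))]
  cost <- vapply(cands, function(r) {
    abs(tm_tss(query) - tm_tss(r)) + abs(tm_tts(query) - tm_tts(r))
  }, numeric(1))
  cands[[which.min(cost)]]
}

fsm_subcategory <- function(query, ref, window) {
  d5 <- abs(tm_tss(query) - tm_tss(ref))
  d3 <- abs(tm_tts(query) - tm_tts(ref))
  if (d5 <= window && d3 <= window) return("reference_match")
  if (d5 > window && d3 > window) return("alternative_3end5end")
  if (d5 > window) "alternative_5end" else "alternative_3end"
}

# References of the overlapped same-strand genes of which the query chain is
# a proper contiguous subchain.
ism_matches <- function(query, qk, index, gs) {
  if (length(gs) == 0L) return(list())
  cand <- index$transcripts[sort(unlist(index$genes[gs], use.names = FALSE))]
  Filter(function(r) {
    if (tm_n_exons(r) <= tm_n_exons(query)) return(FALSE)
    find_subchain(qk, junction_keys(r)) > 0L
  }, cand)
}

ism_subcategory <- function(query, ref) {
  rj <- tm_junctions(ref)
  # intron retention: a query exon bridges a whole reference intron
  for (i in seq_len(nrow(rj))) {
    if (any(query$exons[, 1L] < rj[i, 1L] & query$exons[, 2L] > rj[i, 2L]))
      return("intron_retention")
  }
  qk <- junction_keys(query)
  rk <- junction_keys(ref)
  k <- find_subchain(qk, rk)
  missing_low <- k > 1L
  missing_high <- (k + length(qk) - 1L) < length(rk)
  if (query$strand == "-") {
    tmp <- missing_low; missing_low <- missing_high; missing_high <- tmp
  }
  # missing_low now means junctions missing on the 5' side
  if (missing_low && missing_high) return("internal_fragment")
  if (missing_low) "3prime_fragment" else "5prime_fragment"
}

finish_call <- function(res, category, subcategory, query, ref, index) {
  res$structural_category <- category
  res$subcategory <- subcategory
  res$associated_gene <- ref$gene_id
  res$associated_transcript <- ref$transcript_id
  res$diff_to_TSS <- signed_end_diff(tm_tss(query), tm_tss(ref), query$strand)
  res$diff_to_TTS <- signed_end_diff(tm_tts(query), tm_tts(ref), query$strand)
  gd <- gene_end_dists(query, index, ref$gene_id)
  res$diff_to_gene_TSS <- gd[1L]
  res$diff_to_gene_TTS <- gd[2L]
  res
}

gene_catalogs <- function(index, gs) {
  cats <- index$per_gene[gs]
  list(junctions = unique(unlist(lapply(cats, `[[`, "junctions"))),
       donors = unique(unlist(lapply(cats, `[[`, "donors"))),
       acceptors = unique(unlist(lapply(cats, `[[`, "acceptors"))))
}

# Exonic (reference exon vs query exon) overlap in bp with the given genes.
query_exonic_overlap <- function(query, index, gs) {
  tot <- 0
  for (tid in unlist(index$genes[gs], use.names = FALSE)) {
    tot <- tot + exon_overlap_bp(query, index$transcripts[[tid]])
  }
  tot
}

best_overlap_gene <- function(query, index, gs) {
  ov <- vapply(sort(gs), function(g) {
    gt <- index$gene_table
    row <- gt[gt$gene_id == g, ]
    max(0, min(row$end, tm_end(query)) - max(row$start, tm_start(query)))
  }, numeric(1))
  names(ov)[which.max(ov)]
}

attach_gene <- function(res, query, index, gs, gene_dists = TRUE) {
  # prefer the gene with most exonic overlap, falling back to locus overlap
  ex_ov <- vapply(sort(gs), function(g) {
    sum(vapply(index$genes[[g]], function(tid) {
      exon_overlap_bp(query, index$transcripts[[tid]])
    }, numeric(1)))
  }, numeric(1))
  g <- if (max(ex_ov) > 0) names(ex_ov)[which.max(ex_ov)] else
    best_overlap_gene(query, index, gs)
  res$associated_gene <- g
  if (gene_dists) {
    gd <- gene_end_dists(query, index, g)
    res$diff_to_gene_TSS <- gd[1L]
    res$diff_to_gene_TTS <- gd[2L]
  }
  res
}

# Signed distances to the nearest annotated gene TSS/TTS (by |distance|).
gene_end_dists <- function(query, index, gene_id) {
  pg <- index$per_gene[[gene_id]]
  if (is.null(pg)) return(c(NA_real_, NA_real_))
  d5 <- signed_end_diff(tm_tss(query), pg$tss, query$strand)
  d3 <- signed_end_diff(tm_tts(query), pg$tts, query$strand)
  c(d5[which.min(abs(d5))], d3[which.min(abs(d3))])
}

# Connected components of locus overlap among genes (same chrom+strand);
# two mutually non-overlapping components under one query chain mean fusion.
locus_components <- function(index, gs) {
  gt <- index$gene_table
  gt <- gt[match(sort(gs), gt$gene_id), , drop = FALSE]
  n <- nrow(gt)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && gt$chrom[i] == gt$chrom[j] && gt$strand[i] == gt$strand[j] &&
        gt$start[i] < gt$end[j] && gt$end[i] > gt$start[j]) {
      comp[comp == comp[j]] <- comp[i]
    }
  }
  stats::setNames(comp, gt$gene_id)
}

#' Assign the FSM end subcategory
#'
#' Exposed for boundary sweeps: `reference_match` iff both
#' `|diff_to_TSS| <= window` and `|diff_to_TTS| <= window` (inclusive),
#' otherwise the alternative-end subcategory naming the offending end(s).
#'
#' @param diff_to_TSS,diff_to_TTS Signed end distances in bp.
#' @param window Window in bp (default 50).
#' @return Subcategory label.
#' @export
assign_fsm_subcategory <- function(diff_to_TSS, diff_to_TTS, window = 50) {
  d5 <- abs(diff_to_TSS); d3 <- abs(diff_to_TTS)
  if (d5 <= window && d3 <= window) return("reference_match")
  if (d5 > window && d3 > window) return("alternative_3end5end")
  if (d5 > window) "alternative_5end" else "alternative_3end"
}
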