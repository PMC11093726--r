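# Brute-force structural classifier, written independently of the package
# implementation: enumerates every reference transcript and performs naive
# loop-based set/sublist tests. Used as the oracle for equivalence tests.

oracle_junctions <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2) return(NULL)
  out <- NULL
  for (i in 1:(n - 1)) out <- rbind(out, c(tm$exons[i, 2], tm$exons[i + 1, 1]))
  out
}

oracle_jstr <- function(tm) {
  j <- oracle_junctions(tm)
  if (is.null(j)) character(0) else paste(j[, 1], j[, 2], sep = "_")
}

oracle_same_loc <- function(a, b) a$chrom == b$chrom && a$strand == b$strand

oracle_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

oracle_gene_spans <- function(refs) {
  genes <- unique(vapply(refs, function(r) r$gene_id, ""))
  out <- list()
  for (g in genes) {
    tms <- Filter(function(r) r$gene_id == g, refs)
    out[[g]] <- list(chrom = tms[[1]]$chrom, strand = tms[[1]]$strand,
                     start = min(vapply(tms, function(t) t$exons[1, 1], 0)),
                     end = max(vapply(tms, function(t) max(t$exons[, 2]), 0)),
                     tms = tms)
  }
  out
}

oracle_classify <- function(q, refs, window = 50) {
  spans <- oracle_gene_spans(refs)
  qs <- q$exons[1, 1]; qe <- max(q$exons[, 2])
  same <- list(); anti <- list()
  for (g in names(spans)) {
    sp <- spans[[g]]
    if (sp$chrom == q$chrom && oracle_overlap(qs, qe, sp$start, sp$end)) {
      if (sp$strand == q$strand) same[[g]] <- sp else anti[[g]] <- sp
    }
  }
  mono <- nrow(q$exons) == 1
  sub_me <- if (mono) "mono-exon" else "multi-exon"

  if (!mono) {
    qj <- oracle_jstr(q)
    # FSM: some reference with the identical chain
    for (r in refs) {
      if (oracle_same_loc(q, r) && length(oracle_jstr(r)) == length(qj) &&
          all(oracle_jstr(r) == qj)) {
        d5 <- abs((if (q$strand == "+") q$exons[1, 1] else max(q$exons[, 2]) - 1) -
                    (if (r$strand == "+") r$exons[1, 1] else max(r$exons[, 2]) - 1))
        d3 <- abs((if (q$strand == "+") max(q$exons[, 2]) - 1 else q$exons[1, 1]) -
                    (if (r$strand == "+") max(r$exons[, 2]) - 1 else r$exons[1, 1]))
        sub <- if (d5 <= window && d3 <= window) "reference_match"
        else if (d5 > window && d3 > window) "alternative_3end5end"
        else if (d5 > window) "alternative_5end" else "alternative_3end"
        return(list(category = "FSM", subcategory = sub))
      }
    }
    # ISM: contiguous proper sublist of a same-gene reference chain
    for (g in names(same)) for (r in same[[g]]$tms) {
      rj <- oracle_jstr(r)
      if (length(rj) <= length(qj)) next
      for (k in seq_len(length(rj) - length(qj) + 1)) {
        if (all(rj[k:(k + length(qj) - 1)] == qj)) {
          ret <- FALSE
          rint <- oracle_junctions(r)
          for (i in seq_len(nrow(rint))) for (e in seq_len(nrow(q$exons))) {
            if (q$exons[e, 1] < rint[i, 1] && q$exons[e, 2] > rint[i, 2]) ret <- TRUE
          }
          if (ret) return(list(category = "ISM", subcategory = "intron_retention"))
          lo <- k > 1; hi <- k + length(qj) - 1 < length(rj)
          if (q$strand == "-") { t <- lo; lo <- hi; hi <- t }
          sub <- if (lo && hi) "internal_fragment" else if (lo) "3prime_fragment" else "5prime_fragment"
          return(list(category = "ISM", subcategory = sub))
        }
      }
    }
    # fusion: two overlapped same-strand loci that do not overlap each other
    gn <- names(same)
    if (length(gn) >= 2) {
      for (a in gn) for (b in gn) {
        if (a < b && !oracle_overlap(same[[a]]$start, same[[a]]$end,
                                     same[[b]]$start, same[[b]]$end))
          return(list(category = "fusion", subcategory = "multi-exon"))
      }
    }
    if (length(same) > 0) {
      exonic <- FALSE
      donors <- c(); acceptors <- c(); juncs <- c()
      for (g in names(same)) for (r in same[[g]]$tms) {
        for (i in seq_len(nrow(r$exons))) for (e in seq_len(nrow(q$exons))) {
          if (oracle_overlap(q$exons[e, 1], q$exons[e, 2],
                             r$exons[i, 1], r$exons[i, 2])) exonic <- TRUE
        }
        rint <- oracle_junctions(r)
        if (!is.null(rint)) {
          dd <- if (r$strand == "+") rint[, 1] else rint[, 2]
          aa <- if (r$strand == "+") rint[, 2] else rint[, 1]
          donors <- c(donors, dd); acceptors <- c(acceptors, aa)
          juncs <- c(juncs, paste(rint[, 1], rint[, 2], sep = "_"))
        }
      }
      if (exonic) {
        qint <- oracle_junctions(q)
        qd <- if (q$strand == "+") qint[, 1] else qint[, 2]
        qa <- if (q$strand == "+") qint[, 2] else qint[, 1]
        if (any(!(qd %in% donors)) || any(!(qa %in% acceptors)))
          return(list(category = "NNC", subcategory = "at_least_one_novel_splicesite"))
        if (all(qj %in% juncs))
          return(list(category = "NIC", subcategory = "combination_of_known_junctions"))
        return(list(category = "NIC", subcategory = "combination_of_known_splicesites"))
      }
      return(list(category = "genic_genomic", subcategory = "multi-exon"))
    }
    if (length(anti) > 0) return(list(category = "antisense", subcategory = "multi-exon"))
    return(list(category = "intergenic", subcategory = "multi-exon"))
  }

  # mono-exon query
  if (length(same) > 0) {
    for (g in names(same)) for (r in same[[g]]$tms) {
      if (nrow(r$exons) == 1 && oracle_overlap(qs, qe, r$exons[1, 1], r$exons[1, 2]))
        return(list(category = "FSM", subcategory = "mono-exon"))
    }
    for (g in names(same)) for (r in same[[g]]$tms) {
      if (nrow(r$exons) > 1) {
        for (i in seq_len(nrow(r$exons))) {
          if (r$exons[i, 1] <= qs && qe <= r$exons[i, 2])
            return(list(category = "ISM", subcategory = "mono-exon"))
        }
      }
    }
    exonic <- FALSE; spans_intron <- FALSE
    for (g in names(same)) for (r in same[[g]]$tms) {
      for (i in seq_len(nrow(r$exons))) {
        if (oracle_overlap(qs, qe, r$exons[i, 1], r$exons[i, 2])) exonic <- TRUE
      }
      rint <- oracle_junctions(r)
      if (!is.null(rint)) for (i in seq_len(nrow(rint))) {
        if (qs < rint[i, 1] && qe > rint[i, 2]) spans_intron <- TRUE
      }
    }
    if (exonic) {
      sub <- if (spans_intron) "mono-exon_by_intron_retention" else "mono-exon"
      return(list(category = "NIC", subcategory = sub))
    }
    return(list(category = "genic_genomic", subcategory = "mono-exon"))
  }
  if (length(anti) > 0) return(list(category = "antisense", subcategory = "mono-exon"))
  list(category = "intergenic", subcategory = "mono-exon")
}

# Random small fixture spec for oracle-equivalence sweeps.
random_fixture_spec <- function() {
  types <- c("reference_match", "alternative_5end", "alternative_3end",
             "alternative_3end5end", "ism_3prime_fragment",
             "ism_5prime_fragment", "ism_internal_fragment",
             "ism_intron_retention", "ism_mono_exon",
             "nic_combination_of_known_junctions",
             "nic_combination_of_known_splicesites", "nic_mono_exon",
             "nic_mono_exon_by_intron_retention", "nnc", "nnc_noncanonical",
             "fusion", "antisense_multi", "antisense_mono", "genic_multi",
             "genic_mono", "intergenic_multi", "intergenic_mono")
  mix <- stats::setNames(sample(0:2, length(types), replace = TRUE), types)
  if (sum(mix) == 0) mix["reference_match"] <- 1
  fixture_spec(n_genes = sample(2:10, 1),
               isoforms_per_gene = sample(1:3, 1),
               n_exons = c(4, sample(4:6, 1)), mix = mix)
}
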