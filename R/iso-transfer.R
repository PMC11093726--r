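#' tappAS-style GFF3 dialect
#'
#' The transfer module reads and writes a minimal, round-trip-tested GFF3
#' dialect for functionally annotated transcripts:
#'
#' * structural rows: `seqid` = chromosome, `type` in
#'   `transcript`/`exon`/`CDS`, 1-based genomic coordinates, attributes
#'   `ID=<transcript>;gene_id=<gene>` (transcript) or `Parent=<transcript>`;
#' * functional rows: `seqid` = transcript id, `source` = feature level
#'   (`UTR`, `CDS_transcript`, `protein`, `gene`), `type` = feature label,
#'   coordinates in 1-based spliced-transcript nucleotides (ignored at gene
#'   level).
#'
#' @param path GFF3 path.
#' @return List with `transcripts` (named `transcript_model` list) and
#'   `features` (data.frame `donor_id`, `level`, `label`, `t_start`,
#'   `t_end`).
#' @export
read_tappas_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- if (length(lines) > 0L) do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tx <- list(); ex <- list(); cds <- list(); feats <- list()
  for (i in seq_len(NROW(f))) {
    row <- f[i, ]
    attrs <- parse_gff3_attrs(row[9L])
    if (row[3L] == "transcript" && !is.null(attrs[["ID"]])) {
      tx[[attrs[["ID"]]]] <- list(chrom = row[1L], strand = row[7L],
                                  gene_id = attrs[["gene_id"]] %||% attrs[["ID"]])
    } else if (row[3L] == "exon") {
      p <- attrs[["Parent"]]
      ex[[p]] <- rbind(ex[[p]], c(as.numeric(row[4L]) - 1, as.numeric(row[5L])))
    } else if (row[3L] == "CDS") {
      p <- attrs[["Parent"]]
      cds[[p]] <- rbind(cds[[p]], c(as.numeric(row[4L]) - 1, as.numeric(row[5L])))
    } else if (row[2L] %in% c("UTR", "CDS_transcript", "protein", "gene")) {
      feats[[length(feats) + 1L]] <- data.frame(
        donor_id = row[1L], level = row[2L], label = row[3L],
        t_start = as.numeric(row[4L]), t_end = as.numeric(row[5L]),
        stringsAsFactors = FALSE)
    }
  }
  transcripts <- lapply(names(tx), function(id) {
    cd <- cds[[id]]
    transcript_model(id, gene_id = tx[[id]]$gene_id, chrom = tx[[id]]$chrom,
                     strand = tx[[id]]$strand, exons = ex[[id]],
                     cds = if (!is.null(cd)) c(min(cd[, 1L]), max(cd[, 2L])))
  })
  names(transcripts) <- names(tx)
  features <- if (length(feats) > 0L) do.call(rbind, feats) else
    data.frame(donor_id = character(0), level = character(0),
               label = character(0), t_start = numeric(0), t_end = numeric(0))
  list(transcripts = transcripts, features = features)
}

parse_gff3_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) == 2L) trimws(x[2L]) else NULL)
  names(out) <- vapply(kv, function(x) trimws(x[1L]), character(1))
  out
}

#' Write the tappAS-style GFF3
#'
#' @param transcripts Named list of `transcript_model`s.
#' @param features Optional data.frame `donor_id`/`acceptor_id` (first
#'   column), `level`, `label`, `t_start`, `t_end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tappas_gff3 <- function(transcripts, features = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (tm in transcripts) {
    writeLines(sprintf("%s\tisocurate\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
                       tm$chrom, as.integer(tm_start(tm)) + 1L,
                       as.integer(tm_end(tm)), tm$strand, tm$transcript_id,
                       tm$gene_id), con)
    for (i in seq_len(nrow(tm$exons)))
      writeLines(sprintf("%s\tisocurate\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         tm$chrom, as.integer(tm$exons[i, 1L]) + 1L,
                         as.integer(tm$exons[i, 2L]), tm$strand,
                         tm$transcript_id), con)
    if (!is.null(tm$cds)) {
      blocks <- intersect_blocks(tm$exons, tm$cds[1L], tm$cds[2L])
      for (i in seq_len(nrow(blocks)))
        writeLines(sprintf("%s\tisocurate\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                           tm$chrom, as.integer(blocks[i, 1L]) + 1L,
                           as.integer(blocks[i, 2L]), tm$strand,
                           tm$transcript_id), con)
    }
  }
  for (i in seq_len(NROW(features))) {
    fr <- features[i, ]
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t.\t.\tID=%s", fr[[1L]],
                       fr$level, fr$label, as.integer(fr$t_start),
                       as.integer(fr$t_end), fr$label), con)
  }
  invisible(path)
}

#' Emit a structural-only tappAS GFF3
#'
#' Used when no feature donors are available: valid GFF3 with transcript,
#' exon and CDS records only, enabling quantitative but not functional
#' downstream analysis.
#'
#' @param acceptors Named list of `transcript_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_structural_only <- function(acceptors, path) {
  write_tappas_gff3(acceptors, NULL, path)
}

# genomic blocks (0-based half-open) of transcript positions [ts, te], 1-based
transcript_to_genomic <- function(tm, ts, te) {
  ex <- tm$exons
  ord <- if (tm$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  blocks <- NULL
  pos <- 0
  for (i in ord) {
    len <- ex[i, 2L] - ex[i, 1L]
    lo <- max(ts, pos + 1); hi <- min(te, pos + len)
    if (lo <= hi) {
      if (tm$strand == "+") {
        blocks <- rbind(blocks, c(ex[i, 1L] + lo - 1 - pos, ex[i, 1L] + hi - pos))
      } else {
        blocks <- rbind(blocks, c(ex[i, 2L] - (hi - pos), ex[i, 2L] - (lo - 1 - pos)))
      }
    }
    pos <- pos + len
  }
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  dimnames(blocks) <- list(NULL, c("start", "end"))
  blocks
}

# 1-based transcript coordinate range covering genomic blocks
genomic_to_transcript_range <- function(tm, blocks) {
  ex <- tm$exons
  ord <- if (tm$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  tpos <- function(g) {  # transcript position of the base starting at g
    pos <- 0
    for (i in ord) {
      len <- ex[i, 2L] - ex[i, 1L]
      if (g >= ex[i, 1L] && g < ex[i, 2L]) {
        off <- if (tm$strand == "+") g - ex[i, 1L] else ex[i, 2L] - 1 - g
        return(pos + off + 1)
      }
      pos <- pos + len
    }
    NA_real_
  }
  ts <- c()
  for (i in seq_len(nrow(blocks)))
    ts <- c(ts, tpos(blocks[i, 1L]), tpos(blocks[i, 2L] - 1))
  range(ts, na.rm = TRUE)
}

blocks_within <- function(blocks, container) {
  all(vapply(seq_len(nrow(blocks)), function(i) {
    covered <- sum(pmax(0, pmin(container[, 2L], blocks[i, 2L]) -
                          pmax(container[, 1L], blocks[i, 1L])))
    covered >= blocks[i, 2L] - blocks[i, 1L]
  }, logical(1)))
}

blocks_overlap_bp <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    s <- pmin(a[i, 2L], b[, 2L]) - pmax(a[i, 1L], b[, 1L])
    tot <- tot + sum(s[s > 0])
  }
  tot
}

blocks_intersection <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    keep <- s < e
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2L) else
    out[order(out[, 1L]), , drop = FALSE]
}

tm_cds_blocks <- function(tm) {
  if (is.null(tm$cds)) return(NULL)
  intersect_blocks(tm$exons, tm$cds[1L], tm$cds[2L])
}

#' Transfer functional features from donors to acceptors
#'
#' Features are converted from donor transcript coordinates to genomic
#' blocks and transferred by coordinate matching. UTR features must lie
#' inside the acceptor's exons and outside its CDS; CDS-transcript features
#' must lie inside both exons and CDS, and a feature spanning several exons
#' transfers only when the internal exon boundaries it crosses are shared
#' by donor and acceptor; protein features transfer wholesale when donor
#' and acceptor have identical CDS exon sets, and otherwise only within the
#' shared CDS region when at least one CDS exon partially overlaps;
#' gene-level features always transfer across matching gene ids. Duplicate
#' annotations (same level, label and genomic span) are removed, which also
#' makes the transfer idempotent.
#'
#' @param acceptors Named list of `transcript_model`s (with `gene_id` and,
#'   for coding features, `cds`).
#' @param donors List as returned by [read_tappas_gff3()].
#' @param novel_mode When `TRUE` (default) every acceptor receives features
#'   from all donors of the same gene; when `FALSE`, only from the donor
#'   with the matching transcript id.
#' @return data.frame `acceptor_id`, `level`, `label`, `t_start`, `t_end`
#'   (acceptor transcript coordinates; gene level keeps the donor values).
#' @export
transfer_features <- function(acceptors, donors, novel_mode = TRUE) {
  out <- list()
  seen <- character(0)
  dtx <- donors$transcripts
  for (acc in acceptors) {
    dons <- if (novel_mode) {
      Filter(function(d) d$gene_id == acc$gene_id, dtx)
    } else {
      Filter(function(d) d$transcript_id == acc$transcript_id, dtx)
    }
    for (don in dons) {
      ff <- donors$features[donors$features$donor_id == don$transcript_id, ,
                            drop = FALSE]
      for (i in seq_len(nrow(ff))) {
        fr <- ff[i, ]
        res <- transfer_one(fr, don, acc)
        if (is.null(res)) next
        key <- paste(acc$transcript_id, fr$level, fr$label,
                     paste(res$span, collapse = ","), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(
          acceptor_id = acc$transcript_id, level = fr$level, label = fr$label,
          t_start = res$range[1L], t_end = res$range[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(acceptor_id = character(0), level = character(0),
                      label = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

transfer_one <- function(fr, don, acc) {
  if (fr$level == "gene") {
    return(list(span = "gene", range = c(fr$t_start, fr$t_end)))
  }
  g <- transcript_to_genomic(don, fr$t_start, fr$t_end)
  if (is.null(g) || nrow(g) == 0L) return(NULL)
  span <- sprintf("%d-%d", as.integer(g[, 1L]), as.integer(g[, 2L]))
  acc_cds <- tm_cds_blocks(acc)
  don_cds <- tm_cds_blocks(don)
  ok <- switch(fr$level,
    UTR = blocks_within(g, acc$exons) &&
      (is.null(acc_cds) || blocks_overlap_bp(g, acc_cds) == 0),
    CDS_transcript = {
      inside <- !is.null(acc_cds) && blocks_within(g, acc_cds)
      if (inside && nrow(g) > 1L) {
        # internal boundaries crossed by the feature must be shared junctions
        bnd <- cbind(g[-nrow(g), 2L], g[-1L, 1L])
        accj <- tm_junctions(acc)
        inside <- all(vapply(seq_len(nrow(bnd)), function(b) {
          any(accj[, 1L] == bnd[b, 1L] & accj[, 2L] == bnd[b, 2L])
        }, logical(1)))
      }
      inside
    },
    protein = {
      if (is.null(acc_cds) || is.null(don_cds)) FALSE
      else if (identical(unname(acc_cds), unname(don_cds))) TRUE
      else if (blocks_overlap_bp(acc_cds, don_cds) > 0) {
        shared <- blocks_intersection(acc_cds, don_cds)
        blocks_within(g, shared)
      } else FALSE
    },
    FALSE)
  if (!isTRUE(ok)) return(NULL)
  list(span = span, range = genomic_to_transcript_range(acc, g))
}
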