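#' Column schema of the classification table
#'
#' Types used to validate rule files: numeric columns accept interval or
#' lower-bound requisites; categorical columns (including logical columns,
#' matched as the levels `"TRUE"`/`"FALSE"`) accept sets of levels.
#'
#' @return Named character vector mapping column name to
#'   `"numeric"`/`"categorical"`.
#' @export
classification_schema <- function() {
  c(isoform = "categorical", chrom = "categorical", strand = "categorical",
    length = "numeric", exons = "numeric",
    structural_category = "categorical", subcategory = "categorical",
    associated_gene = "categorical", associated_transcript = "categorical",
    diff_to_TSS = "numeric", diff_to_TTS = "numeric",
    diff_to_gene_TSS = "numeric", diff_to_gene_TTS = "numeric",
    ratio_TSS = "numeric", perc_A_downstream_TTS = "numeric",
    intrapriming = "categorical",
    polyA_motif = "categorical", polyA_dist = "numeric",
    polyA_motif_found = "categorical",
    within_CAGE_peak = "categorical", dist_to_CAGE_peak = "numeric",
    within_polyA_site = "categorical", dist_to_polyA_site = "numeric",
    all_canonical = "categorical", min_cov = "numeric",
    RTS_stage = "categorical", POS_MLprob = "numeric")
}

#' Parse a JSON rules file
#'
#' The JSON document maps a structural category (or `"rest"`, covering all
#' categories without an explicit entry) to a list of rules; each rule is an
#' object of requisites keyed by classification-table column. A numeric
#' requisite is either a two-element array (closed interval) or a single
#' number (lower bound only); a categorical requisite is a string, boolean
#' or array of accepted levels. Within a rule, requisites combine as AND;
#' rules for the same category combine as OR.
#'
#' @param json_doc Path to a JSON file, or a JSON string.
#' @param schema Column type map, see [classification_schema()].
#' @return A `rules_spec` object.
#' @export
parse_rules <- function(json_doc, schema = classification_schema()) {
  doc <- jsonlite::fromJSON(json_doc, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(names(doc)))
    stop("rules document must be a JSON object keyed by structural category")
  spec <- lapply(names(doc), function(cat) {
    rules <- doc[[cat]]
    if (!is.list(rules)) stop("rules for '", cat, "' must be an array of rules")
    lapply(seq_along(rules), function(ri) {
      rule <- rules[[ri]]
      if (!is.list(rule) || length(rule) == 0L || is.null(names(rule)))
        stop("empty or unkeyed rule #", ri, " for category '", cat, "'")
      lapply(names(rule), function(col) {
        parse_requisite(col, rule[[col]], schema, cat)
      })
    })
  })
  names(spec) <- names(doc)
  structure(spec, class = "rules_spec")
}

parse_requisite <- function(col, val, schema, cat) {
  if (!(col %in% names(schema)))
    stop("unknown column '", col, "' in rule for category '", cat, "'")
  type <- schema[[col]]
  flat <- unlist(val, use.names = FALSE)
  if (type == "numeric") {
    if (!is.numeric(flat))
      stop("numeric column '", col, "' given non-numeric constraint")
    if (length(flat) == 1L) {
      list(column = col, type = "numeric", lo = flat, hi = Inf)
    } else if (length(flat) == 2L) {
      list(column = col, type = "numeric", lo = flat[1L], hi = flat[2L])
    } else stop("numeric constraint for '", col, "' must have 1 or 2 values")
  } else {
    if (is.numeric(flat))
      stop("categorical column '", col, "' given numeric constraint")
    list(column = col, type = "categorical",
         levels = toupper_if_logical(as.character(flat)))
  }
}

toupper_if_logical <- function(x) {
  ifelse(tolower(x) %in% c("true", "false"), toupper(x), x)
}

#' Default filtering rules
#'
#' FSM transcripts are removed solely on intrapriming. Transcripts of every
#' other category must be negative for intrapriming and reverse
#' transcriptase switching, and either have all junctions supported by at
#' least `min_junction_support` short reads or have only canonical
#' junctions.
#'
#' @param min_junction_support Minimum short-read junction support
#'   (default 3).
#' @return A `rules_spec` object.
#' @export
default_rules <- function(min_junction_support = 3) {
  doc <- sprintf('{
    "FSM":  [ {"intrapriming": "FALSE"} ],
    "rest": [ {"intrapriming": "FALSE", "RTS_stage": "FALSE", "min_cov": %g},
              {"intrapriming": "FALSE", "RTS_stage": "FALSE", "all_canonical": "TRUE"} ]
  }', min_junction_support)
  parse_rules(doc)
}

#' Apply a rules specification to classification records
#'
#' A transcript passes when any rule defined for its structural category
#' (falling back to `"rest"`, and passing vacuously when neither exists)
#' has all of its requisites satisfied. Missing values fail numeric and
#' categorical requisites alike (conservative). Every transcript receives
#' exactly one verdict.
#'
#' @param records Classification data.frame (see [compute_qc_tables()]).
#' @param spec A `rules_spec`.
#' @param drop_mono_exon Also remove all mono-exonic transcripts
#'   (default `FALSE`).
#' @return data.frame `isoform`, `verdict` (`"isoform"`/`"artifact"`),
#'   `reasons` (`;`-separated failed requisites, empty for isoforms).
#' @export
apply_rules <- function(records, spec, drop_mono_exon = FALSE) {
  stopifnot(inherits(spec, "rules_spec"))
  verdict <- character(nrow(records))
  reasons <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (drop_mono_exon && records$exons[i] == 1L) {
      verdict[i] <- "artifact"; reasons[i] <- "mono_exon"
      next
    }
    cat <- records$structural_category[i]
    rules <- spec[[cat]]
    if (is.null(rules)) rules <- spec[["rest"]]
    if (is.null(rules)) {
      verdict[i] <- "isoform"
      next
    }
    failed <- character(0)
    passed <- FALSE
    for (rule in rules) {
      bad <- Filter(Negate(is.null), lapply(rule, function(req) {
        if (requisite_ok(records[i, , drop = FALSE], req)) NULL else req$column
      }))
      if (length(bad) == 0L) { passed <- TRUE; break }
      failed <- union(failed, unlist(bad))
    }
    if (passed) {
      verdict[i] <- "isoform"
    } else {
      verdict[i] <- "artifact"
      reasons[i] <- paste(failed, collapse = ";")
    }
  }
  data.frame(isoform = records$isoform, verdict = verdict, reasons = reasons,
             stringsAsFactors = FALSE)
}

requisite_ok <- function(row, req) {
  v <- row[[req$column]]
  if (is.null(v) || length(v) != 1L || is.na(v)) return(FALSE)
  if (req$type == "numeric") {
    is.numeric(v) && v >= req$lo && v <= req$hi
  } else {
    as.character(v) %in% req$levels
  }
}

#' Write filter decisions
#'
#' @param decisions data.frame from [apply_rules()] or [score_and_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_decisions <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
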