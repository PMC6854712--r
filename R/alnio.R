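#' Hit-retention policy for alignment filtering
#'
#' The defaults are the tool's standard retention settings: keep at most
#' 20 aligned sequences per query, each with bitscore of at least 80 bits.
#'
#' @param min_bitscore minimum bitscore (bits) a hit must reach; >= 0.
#' @param max_hits maximum number of hits retained per query; >= 1.
#' @return An object of class `filter_policy`.
#' @examples
#' filter_policy()          # the defaults: 20 hits, bitscore >= 80
#' filter_policy(50, 100)   # a permissive policy
#' @export
filter_policy <- function(min_bitscore = 80, max_hits = 20L) {
  min_bitscore <- as.numeric(min_bitscore)
  max_hits <- as.integer(max_hits)
  if (is.na(min_bitscore) || min_bitscore < 0) {
    stop("filter_policy: min_bitscore must be >= 0")
  }
  if (is.na(max_hits) || max_hits < 1L) {
    stop("filter_policy: max_hits must be >= 1")
  }
  structure(list(min_bitscore = min_bitscore, max_hits = max_hits),
            class = "filter_policy")
}

#' Default column layout of tabular (outfmt-6 style) alignment files
#'
#' @param staxids if `TRUE`, append the optional trailing `staxids` column
#'   (semicolon-separated subject taxon ids).
#' @return Character vector of column names.
#' @export
outfmt6_columns <- function(staxids = FALSE) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (staxids) cols <- c(cols, "staxids")
  cols
}

#' Read tabular alignment output (BLAST/Diamond outfmt-6 dialect)
#'
#' Parses a tab-delimited alignment file into one row per hit. The column
#' layout is configurable; at minimum `qseqid`, `sseqid` and `bitscore`
#' must be named. Optional columns `evalue` and `staxids` are used when
#' present (a `staxids` cell holds semicolon-separated taxon ids and may
#' be empty). Blank lines and lines starting with `#` are skipped. Hits
#' keep their file order; `raw_rank` is the 0-based order of appearance
#' within each query's block.
#'
#' @param path path to the alignment file.
#' @param columns ordered column names, e.g. [outfmt6_columns()].
#' @return A data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `evalue` (`NA` when the layout lacks it), `subject_taxa` (list column
#'   of integer vectors, duplicates removed) and `raw_rank`.
#' @export
read_alignments <- function(path, columns = outfmt6_columns(staxids = TRUE)) {
  req <- c("qseqid", "sseqid", "bitscore")
  if (!all(req %in% columns)) {
    stop("read_alignments: columns must name at least ",
         paste(req, collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  if (!any(keep)) {
    hits <- data.frame(query_id = character(0), subject_id = character(0),
                       bitscore = numeric(0), evalue = numeric(0),
                       raw_rank = integer(0), stringsAsFactors = FALSE)
    hits$subject_taxa <- list()
    return(hits)
  }
  # sentinel keeps a trailing empty cell (e.g. blank staxids) as a field
  fields <- strsplit(paste0(lines[keep], "\t\x03"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])

  nf <- lengths(fields)
  if (any(nf < length(columns))) {
    bad <- which(nf < length(columns))[1L]
    stop("read_alignments: line ", lineno[bad], " has ", nf[bad],
         " columns, expected ", length(columns))
  }

  col <- function(nm) vapply(fields, `[[`, character(1), match(nm, columns))
  bitscore <- suppressWarnings(as.numeric(col("bitscore")))
  if (anyNA(bitscore)) {
    bad <- which(is.na(bitscore))[1L]
    stop("read_alignments: non-numeric bitscore at line ", lineno[bad])
  }
  evalue <- if ("evalue" %in% columns) {
    ev <- suppressWarnings(as.numeric(col("evalue")))
    if (anyNA(ev)) {
      bad <- which(is.na(ev))[1L]
      stop("read_alignments: non-numeric evalue at line ", lineno[bad])
    }
    ev
  } else {
    rep(NA_real_, length(fields))
  }
  subject_taxa <- if ("staxids" %in% columns) {
    lapply(col("staxids"), parse_staxids)
  } else {
    rep(list(integer(0)), length(fields))
  }

  query_id <- col("qseqid")
  hits <- data.frame(query_id = query_id,
                     subject_id = col("sseqid"),
                     bitscore = bitscore,
                     evalue = evalue,
                     raw_rank = NA_integer_,
                     stringsAsFactors = FALSE)
  hits$subject_taxa <- subject_taxa
  if (nrow(hits) > 0L) {
    hits$raw_rank <- stats::ave(seq_len(nrow(hits)), query_id,
                                FUN = seq_along) - 1L
  }
  hits
}

parse_staxids <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell) || cell %in% c("N/A", "0")) return(integer(0))
  ids <- suppressWarnings(as.integer(strsplit(cell, ";", fixed = TRUE)[[1L]]))
  unique(ids[!is.na(ids) & ids > 0L])
}

#' Apply the hit-retention filter to one query's hits
#'
#' Drops hits below the bitscore threshold, sorts the survivors by
#' descending bitscore (ties broken by ascending e-value, then file
#' order), and truncates to the per-query hit cap. Deterministic and
#' idempotent.
#'
#' @param hits data.frame of hits for a single query (as produced by
#'   [read_alignments()]).
#' @param policy a [filter_policy()].
#' @return The retained hits, same columns as the input.
#' @export
filter_hits <- function(hits, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$query_id)) > 1L) {
    stop("filter_hits: hits must belong to a single query")
  }
  kept <- hits[hits$bitscore >= policy$min_bitscore, , drop = FALSE]
  if (nrow(kept) == 0L) return(kept)
  ev <- kept$evalue
  ev[is.na(ev)] <- Inf   # missing e-value never wins a tie
  ord <- order(-kept$bitscore, ev, kept$raw_rank)
  kept <- kept[ord, , drop = FALSE]
  kept <- kept[seq_len(min(nrow(kept), policy$max_hits)), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Split an alignment table into per-query blocks and filter each
#'
#' @param hits data.frame from [read_alignments()] (any number of queries).
#' @param policy a [filter_policy()].
#' @return Named list: query id -> retained hits data.frame.
#' @export
filter_by_query <- function(hits, policy = filter_policy()) {
  if (nrow(hits) == 0L) return(stats::setNames(list(), character(0)))
  blocks <- split(hits, factor(hits$query_id, levels = unique(hits$query_id)))
  lapply(blocks, filter_hits, policy = policy)
}
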