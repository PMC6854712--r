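#' Protein sources: pluggable record retrieval by taxon or by name
#'
#' A *protein source* answers two kinds of query: all records belonging
#' to a taxon, and all records whose annotation label matches a gene or
#' protein name (optionally restricted to a taxonomic clade). Each
#' matching record is yielded exactly once per query. The package ships a
#' local implementation backed by a FASTA file plus lookup tables; a
#' remote (repository-backed) implementation is a documented extension
#' point — implement the two generics for a new class.
#'
#' @param source a protein source object.
#' @param taxon_id a single taxon id.
#' @name protein_source
NULL

#' @rdname protein_source
#' @export
source_fetch_taxon <- function(source, taxon_id) {
  UseMethod("source_fetch_taxon")
}

#' @rdname protein_source
#' @param query a gene or protein name (matched case-insensitively as a
#'   whole word against the normalized annotation label).
#' @param tree a `taxonomy_tree`, required when `taxon_restriction` given.
#' @param taxon_restriction optional clade root taxon id; only records
#'   whose taxon lies in that clade (ancestor-or-self test) are returned.
#' @export
source_fetch_name <- function(source, query, tree = NULL,
                              taxon_restriction = NULL) {
  UseMethod("source_fetch_name")
}

#' Local protein source backed by a FASTA and lookup tables
#'
#' @param records record data.frame (see [read_fasta()]), or a FASTA path.
#' @param taxon_map named integer vector: accession -> taxon id.
#' @param label_map named character vector: accession -> annotation label
#'   (recommended protein name); optional, needed for name queries.
#' @return An object of class `local_protein_source`.
#' @export
local_protein_source <- function(records, taxon_map,
                                 label_map = character(0)) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  structure(list(records = records,
                 taxon_map = taxon_map,
                 label_map = label_map),
            class = "local_protein_source")
}

#' @export
source_fetch_taxon.local_protein_source <- function(source, taxon_id) {
  taxon_id <- as.integer(taxon_id)
  acc <- names(source$taxon_map)[source$taxon_map == taxon_id]
  out <- source$records[source$records$accession %in% acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
source_fetch_name.local_protein_source <- function(source, query,
                                                   tree = NULL,
                                                   taxon_restriction = NULL) {
  labels <- normalize_label(source$label_map)
  pattern <- paste0("\\b", escape_regex(normalize_label(query)), "\\b")
  acc <- names(labels)[grepl(pattern, labels, ignore.case = TRUE,
                             perl = TRUE)]
  if (!is.null(taxon_restriction)) {
    if (is.null(tree)) {
      stop("taxon_restriction requires a taxonomy tree")
    }
    taxa <- source$taxon_map[acc]
    known <- !is.na(resolve_taxa(tree, taxa))
    inside <- logical(length(acc))
    inside[known] <- is_ancestor(tree, taxon_restriction, taxa[known])
    acc <- acc[inside]
  }
  out <- source$records[source$records$accession %in% acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

#' Build a taxonomy-scoped protein database
#'
#' Retrieves every record the source yields for each (de-duplicated)
#' taxon id. A source failure for one taxon is logged and does not abort
#' the build.
#'
#' @param taxon_ids non-empty vector of taxon ids (duplicates allowed).
#' @param source a protein source.
#' @return List with `records` (the union, in taxon order) and `log`: a
#'   data.frame with one row per distinct taxon (`taxon_id`, `n_records`,
#'   `ok`).
#' @export
build_taxonomy_db <- function(taxon_ids, source) {
  if (length(taxon_ids) == 0L) {
    stop("build_taxonomy_db: taxon_ids must be non-empty")
  }
  taxon_ids <- unique(as.integer(taxon_ids))
  parts <- vector("list", length(taxon_ids))
  log <- data.frame(taxon_id = taxon_ids,
                    n_records = 0L, ok = TRUE)
  for (k in seq_along(taxon_ids)) {
    rec <- tryCatch(source_fetch_taxon(source, taxon_ids[k]),
                    error = function(e) {
                      message("build_taxonomy_db: taxon ", taxon_ids[k],
                              " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(rec)) {
      log$ok[k] <- FALSE
    } else {
      parts[[k]] <- rec
      log$n_records[k] <- nrow(rec)
    }
  }
  records <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(records)) {
    records <- data.frame(header = character(0), accession = character(0),
                          sequence = character(0), stringsAsFactors = FALSE)
  }
  list(records = records, log = log)
}

#' Build a function-scoped protein database
#'
#' Retrieves every record whose annotation label matches one of the gene
#' or protein name queries (case-insensitive whole-word match), optionally
#' restricted to a taxonomic clade. Records matched by several queries
#' appear once.
#'
#' @param name_queries non-empty character vector of gene/protein names.
#' @param source a protein source.
#' @param tree a `taxonomy_tree` (needed with `taxon_restriction`).
#' @param taxon_restriction optional clade root taxon id.
#' @return List with `records` and `log` (one row per query:
#'   `query`, `n_records`, `ok`).
#' @export
build_functional_db <- function(name_queries, source, tree = NULL,
                                taxon_restriction = NULL) {
  if (length(name_queries) == 0L) {
    stop("build_functional_db: name_queries must be non-empty")
  }
  name_queries <- unique(name_queries)
  parts <- vector("list", length(name_queries))
  log <- data.frame(query = name_queries, n_records = 0L, ok = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(name_queries)) {
    rec <- tryCatch(
      source_fetch_name(source, name_queries[k], tree = tree,
                        taxon_restriction = taxon_restriction),
      error = function(e) {
        message("build_functional_db: query ", sQuote(name_queries[k]),
                " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(rec)) {
      log$ok[k] <- FALSE
    } else {
      parts[[k]] <- rec
      log$n_records[k] <- nrow(rec)
      if (nrow(rec) == 0L) {
        message("build_functional_db: query ", sQuote(name_queries[k]),
                " matched no records")
      }
    }
  }
  records <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(records)) {
    records <- data.frame(header = character(0), accession = character(0),
                          sequence = character(0), stringsAsFactors = FALSE)
  } else if (nrow(records) > 0L) {
    records <- records[!duplicated(records$accession), , drop = FALSE]
    rownames(records) <- NULL
  }
  list(records = records, log = log)
}
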