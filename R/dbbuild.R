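#' Read a protein FASTA into a record table
#'
#' Records keep the full description line (without `">"`), the accession
#' parsed from it, and the sequence normalized to upper case with a single
#' trailing `"*"` (stop codon) stripped.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `header`, `accession`, `sequence`.
#' @export
read_fasta <- function(path) {
  check_fasta_wellformed(path)
  set <- Biostrings::readAAStringSet(path)
  records <- data.frame(header = names(set),
                        sequence = as.character(set),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  normalize_records(records, source = path)
}

# Biostrings reports malformed FASTA without position information; this
# pre-scan provides the file+line diagnostic for sequence-before-header.
check_fasta_wellformed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    if (!startsWith(lines[i], ">")) {
      stop("malformed FASTA in ", path, " at line ", i,
           ": sequence before first header")
    }
    break
  }
  invisible(TRUE)
}

normalize_records <- function(records, source = "records") {
  records$sequence <- sub("\\*$", "", toupper(records$sequence))
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence after normalization in ", source, " (record ",
         which(!nzchar(records$sequence))[1L], ")")
  }
  if (any(!nzchar(records$header))) {
    stop("empty FASTA header in ", source)
  }
  records$accession <- parse_accession(records$header)
  records[c("header", "accession", "sequence")]
}

#' Parse the accession token from a FASTA description line
#'
#' The accession is the first whitespace-delimited token; for
#' UniProt-style `db|ACC|entry` tokens the middle field is used.
#'
#' @param header character vector of description lines.
#' @return Character vector of accessions.
#' @export
parse_accession <- function(header) {
  token <- sub("[[:space:]].*$", "", header)
  vapply(strsplit(token, "|", fixed = TRUE), function(p) {
    if (length(p) >= 3L) p[[2L]] else p[[1L]]
  }, character(1))
}

#' Write protein records as FASTA (wrapped at 60 columns)
#'
#' @param records data.frame with `header` and `sequence` columns.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                                 records$header))
  write_atomic(path, function(tmp) {
    Biostrings::writeXStringSet(set, tmp, width = 60L)
  })
  invisible(path)
}

#' Merge protein databases
#'
#' Concatenates FASTA sources in the given order into one record stream,
#' normalizing sequences (upper case, trailing `"*"` stripped). The record
#' count is preserved; nothing is deduplicated here.
#'
#' @param paths character vector of FASTA paths (possibly empty).
#' @return A record data.frame (see [read_fasta()]) with an extra `source`
#'   column naming the originating file.
#' @export
merge_databases <- function(paths) {
  if (length(paths) == 0L) {
    return(data.frame(header = character(0), accession = character(0),
                      sequence = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- lapply(paths, function(p) {
    rec <- read_fasta(p)
    rec$source <- p
    rec
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Remove duplicated protein sequences at exact (100%) identity
#'
#' Exactly identical sequences collapse onto their first occurrence in
#' stream order. With `containment = TRUE` a sequence that is a substring
#' of an already-kept longer sequence is removed as well. The report
#' accounts for every input record.
#'
#' @param records record data.frame (normalized, see [merge_databases()]).
#' @param containment also absorb sequences contained in a previously kept
#'   sequence (default off: exact identity only).
#' @return List with `records` (the kept stream) and `report`: a list with
#'   `kept`, `removed` and `clusters` (kept accession -> removed headers).
#' @export
deduplicate <- function(records, containment = FALSE) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = records,
                report = list(kept = 0L, removed = 0L, clusters = list())))
  }
  clusters <- list()
  if (!containment) {
    first_idx <- match(records$sequence, records$sequence)
    keep <- first_idx == seq_len(n)
    for (i in which(!keep)) {
      acc <- records$accession[first_idx[i]]
      clusters[[acc]] <- c(clusters[[acc]], records$header[i])
    }
  } else {
    keep <- logical(n)
    kept_seq <- character(0)
    kept_acc <- character(0)
    for (i in seq_len(n)) {
      host <- NA_integer_
      if (length(kept_seq) > 0L) {
        hit <- which(grepl(records$sequence[i], kept_seq, fixed = TRUE))
        if (length(hit) > 0L) host <- hit[[1L]]
      }
      if (is.na(host)) {
        keep[i] <- TRUE
        kept_seq <- c(kept_seq, records$sequence[i])
        kept_acc <- c(kept_acc, records$accession[i])
      } else {
        acc <- kept_acc[host]
        clusters[[acc]] <- c(clusters[[acc]], records$header[i])
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = list(kept = nrow(out), removed = n - nrow(out),
                     clusters = clusters))
}

hash_marker_regex <- "^[0-9a-f]{32}$"

#' Hash protein headers to uniform fixed-length identifiers
#'
#' Replaces each description line by the lowercase hex MD5 digest of its
#' exact bytes (no trailing newline), producing uniform headers and a much
#' smaller search database. The returned header map records the bijection
#' so original headers can always be restored. A digest collision between
#' two distinct headers is a hard error. Headers that already look like a
#' digest (32 lowercase hex characters) are left untouched with a warning,
#' so re-running the step is a no-op.
#'
#' @param records record data.frame.
#' @param algorithm digest algorithm; only `"md5"` (the default) is
#'   supported, any other name is a configuration error.
#' @return List with `records` (hashed headers, sequences untouched) and
#'   `header_map`: a data.frame with columns `hashed`, `original`.
#' @export
hash_headers <- function(records, algorithm = "md5") {
  if (!identical(tolower(algorithm), "md5")) {
    stop("unsupported hash algorithm: ", algorithm, " (supported: md5)")
  }
  already <- grepl(hash_marker_regex, records$header)
  if (any(already)) {
    warning("hash_headers: ", sum(already),
            " header(s) already hashed; leaving them untouched")
  }
  todo <- which(!already)
  originals <- unique(records$header[todo])
  digests <- md5_hex(originals)
  if (anyDuplicated(digests)) {
    d <- digests[duplicated(digests)][1L]
    clash <- originals[digests == d]
    stop("hash collision between distinct headers: ",
         paste(sQuote(clash), collapse = " and "))
  }
  map <- stats::setNames(digests, originals)
  out <- records
  out$header[todo] <- unname(map[records$header[todo]])
  list(records = out,
       header_map = data.frame(hashed = unname(digests),
                               original = originals,
                               stringsAsFactors = FALSE))
}

#' @rdname hash_headers
#' @param header_map a header-map data.frame.
#' @param path file path for the two-column (`hashed<TAB>original`) table.
#' @export
write_header_map <- function(header_map, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(header_map, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
  invisible(path)
}

#' @rdname hash_headers
#' @export
read_header_map <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Write a deduplication report as a delimited table
#'
#' Three tab-delimited columns: the kept record's accession, the number of
#' records collapsed onto it, and the removed headers (semicolon-joined).
#'
#' @param report the `report` element returned by [deduplicate()].
#' @param path output path.
#' @export
write_dedup_report <- function(report, path) {
  cl <- report$clusters
  tab <- data.frame(kept_accession = names(cl),
                    n_removed = vapply(cl, length, integer(1)),
                    removed_headers = vapply(cl, paste, character(1),
                                             collapse = ";"),
                    stringsAsFactors = FALSE)
  write_atomic(path, function(tmp) {
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
  invisible(path)
}
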