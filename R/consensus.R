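#' Read a protein-group table
#'
#' Expects a tab-delimited file with a single header line and two columns:
#' `group_id` and a comma-separated list of member protein accessions.
#'
#' @param path path to the group table.
#' @return A data.frame with columns `group_id` (character) and `members`
#'   (list column of character vectors, duplicates within a group removed).
#' @export
read_protein_groups <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("protein-group table needs two columns")
  groups <- data.frame(group_id = tab[[1L]], stringsAsFactors = FALSE)
  groups$members <- lapply(strsplit(tab[[2L]], ",", fixed = TRUE),
                           function(m) unique(trimws(m)))
  validate_groups(groups)
  groups
}

validate_groups <- function(groups) {
  if (anyDuplicated(groups$group_id)) {
    stop("duplicate group_id: ",
         groups$group_id[duplicated(groups$group_id)][1L])
  }
  if (any(lengths(groups$members) == 0L)) {
    stop("protein group with no members: ",
         groups$group_id[lengths(groups$members) == 0L][1L])
  }
  invisible(groups)
}

#' Read an accession-to-annotation lookup table
#'
#' Two tab-delimited columns with a header line: accession and annotation
#' label (a recommended protein name or a COG identifier).
#'
#' @param path path to the table.
#' @return Named character vector: accession -> label.
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation map needs two columns")
  stats::setNames(tab[[2L]], tab[[1L]])
}

# Trim, collapse internal whitespace runs. Case is preserved here; voting
# compares case-folded keys but reports the most frequent original casing.
normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Taxonomic consensus (LCA) for one protein group
#'
#' Pools the retained alignment hits of all member proteins. A hit
#' carrying several subject taxa is first collapsed to the LCA of its own
#' (resolvable) taxa, so one alignment row casts exactly one taxonomic
#' vote. Hits whose taxa cannot be resolved against the taxonomy (deleted
#' ids, or no taxon at all) are counted as unresolvable and excluded. The
#' group's annotation is the LCA of the pooled per-hit taxa, or
#' `"unassigned"` when no retained hit contributed a resolvable taxon.
#'
#' @param group list or one-row data.frame with `group_id` and `members`.
#' @param retained_hits named list: accession -> filtered hits data.frame
#'   (output of [filter_hits()]).
#' @param tree a `taxonomy_tree`.
#' @return List with `lca_taxon` (integer id or `NA` for unassigned),
#'   `lineage` (data.frame, empty when unassigned), `hits_used`,
#'   `hits_unresolvable`.
#' @export
taxonomic_consensus <- function(group, retained_hits, tree) {
  members <- unlist(group$members, use.names = FALSE)
  pooled_taxa <- integer(0)
  hits_used <- 0L
  hits_unresolvable <- 0L
  for (acc in members) {
    hits <- retained_hits[[acc]]
    if (is.null(hits) || nrow(hits) == 0L) next
    for (taxa in hits$subject_taxa) {
      idx <- if (length(taxa) > 0L) resolve_taxa(tree, taxa) else integer(0)
      resolvable <- taxa[!is.na(idx)]
      if (length(resolvable) == 0L) {
        hits_unresolvable <- hits_unresolvable + 1L
      } else {
        vote <- if (length(resolvable) == 1L) resolvable else
          taxonomy_lca(tree, resolvable)
        pooled_taxa <- c(pooled_taxa, vote)
        hits_used <- hits_used + 1L
      }
    }
  }
  if (length(pooled_taxa) == 0L) {
    return(list(lca_taxon = NA_integer_,
                lineage = data.frame(taxon_id = integer(0),
                                     rank = character(0),
                                     name = character(0)),
                hits_used = 0L, hits_unresolvable = hits_unresolvable))
  }
  lca <- taxonomy_lca(tree, unique(pooled_taxa))
  list(lca_taxon = lca, lineage = taxonomy_lineage(tree, lca),
       hits_used = hits_used, hits_unresolvable = hits_unresolvable)
}

#' Functional consensus (most frequent name) for one protein group
#'
#' Every retained hit votes with the normalized annotation label of its
#' subject accession; hits whose subject has no entry in the lookup table
#' abstain. The winner is the label with the most votes; ties are broken
#' by the highest summed bitscore among the tied labels, then by the
#' lexicographically smallest label. With no votes at all the group is
#' annotated `"hypothetical/unknown"` with support 0.
#'
#' @param group list or one-row data.frame with `group_id` and `members`.
#' @param retained_hits named list: accession -> filtered hits data.frame.
#' @param annotation named character vector: subject accession -> label.
#' @return List with `function_label`, `function_support`, `hits_used`.
#' @export
functional_consensus <- function(group, retained_hits, annotation) {
  members <- unlist(group$members, use.names = FALSE)
  labels <- character(0)
  scores <- numeric(0)
  for (acc in members) {
    hits <- retained_hits[[acc]]
    if (is.null(hits) || nrow(hits) == 0L) next
    lab <- normalize_label(unname(annotation[hits$subject_id]))
    ok <- !is.na(lab) & nzchar(lab)
    labels <- c(labels, lab[ok])
    scores <- c(scores, hits$bitscore[ok])
  }
  if (length(labels) == 0L) {
    return(list(function_label = "hypothetical/unknown",
                function_support = 0L, hits_used = 0L))
  }
  key <- tolower(labels)
  votes <- table(key)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(k) sum(scores[key == k]), numeric(1))
    top <- top[sums == max(sums)]
  }
  # report the most frequent original casing of the winning key
  winner <- sort(unname(report_casing(labels, key, top)))[1L]
  list(function_label = winner,
       function_support = as.integer(max(votes)),
       hits_used = length(labels))
}

# For each candidate key, the most frequent original casing (ties ->
# lexicographically smallest casing, for determinism).
report_casing <- function(labels, key, candidates) {
  vapply(candidates, function(k) {
    forms <- table(labels[key == k])
    sort(names(forms)[forms == max(forms)])[1L]
  }, character(1))
}

#' Consensus annotation of protein groups
#'
#' Runs the full post-identification annotation: hits are filtered per
#' query with the retention policy, pooled per group, and summarised into
#' one taxonomic (LCA) and, per functional source, one most-frequent-name
#' annotation. Alignment queries that match no group member are ignored
#' (their count is reported via `message()`).
#'
#' @param groups data.frame with `group_id` and list column `members`
#'   (see [read_protein_groups()]).
#' @param taxonomy_hits data.frame from [read_alignments()] carrying
#'   subject taxon ids, or `NULL` when no taxonomic evidence is available.
#' @param functional_sources named list of functional evidence sources;
#'   each element is `list(hits = <alignment data.frame>, annotation =
#'   <named label vector>)`. May be empty.
#' @param tree a `taxonomy_tree` (required when `taxonomy_hits` given).
#' @param policy a [filter_policy()].
#' @return A data.frame with one row per group, in input order: columns
#'   `group_id`, `lca_taxon_id` (`"unassigned"` when no evidence),
#'   `lca_rank`, `lca_name`, `lca_lineage` (semicolon-joined
#'   `rank:name`), `tax_hits_used`, `tax_hits_unresolvable`, and for each
#'   functional source `<name>_label`, `<name>_support`, `<name>_used`.
#' @export
annotate_groups <- function(groups, taxonomy_hits = NULL,
                            functional_sources = list(),
                            tree = NULL, policy = filter_policy()) {
  validate_groups(groups)
  if (!is.null(taxonomy_hits) && is.null(tree)) {
    stop("annotate_groups: taxonomy hits given but no taxonomy tree")
  }
  n <- nrow(groups)
  all_members <- unique(unlist(groups$members, use.names = FALSE))

  prepare <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0L) {
      return(stats::setNames(list(), character(0)))
    }
    unmatched <- setdiff(unique(hits$query_id), all_members)
    if (length(unmatched) > 0L) {
      message("annotate_groups: ignoring ", length(unmatched),
              " alignment query id(s) matching no group member")
    }
    filter_by_query(hits[hits$query_id %in% all_members, , drop = FALSE],
                    policy)
  }
  tax_retained <- prepare(taxonomy_hits)
  fun_retained <- lapply(functional_sources, function(s) prepare(s$hits))

  out <- data.frame(group_id = groups$group_id,
                    lca_taxon_id = rep("unassigned", n),
                    lca_rank = rep(NA_character_, n),
                    lca_name = rep(NA_character_, n),
                    lca_lineage = rep(NA_character_, n),
                    tax_hits_used = integer(n),
                    tax_hits_unresolvable = integer(n),
                    stringsAsFactors = FALSE)
  src_names <- names(functional_sources)
  if (length(functional_sources) > 0L && is.null(src_names)) {
    stop("annotate_groups: functional_sources must be a named list")
  }
  for (s in src_names) {
    out[[paste0(s, "_label")]] <- rep("hypothetical/unknown", n)
    out[[paste0(s, "_support")]] <- integer(n)
    out[[paste0(s, "_used")]] <- integer(n)
  }

  for (i in seq_len(n)) {
    grp <- list(group_id = groups$group_id[i],
                members = groups$members[[i]])
    if (!is.null(tree)) {
      tc <- taxonomic_consensus(grp, tax_retained, tree)
      out$tax_hits_used[i] <- tc$hits_used
      out$tax_hits_unresolvable[i] <- tc$hits_unresolvable
      if (!is.na(tc$lca_taxon)) {
        lin <- tc$lineage
        out$lca_taxon_id[i] <- as.character(tc$lca_taxon)
        out$lca_rank[i] <- lin$rank[nrow(lin)]
        out$lca_name[i] <- lin$name[nrow(lin)]
        out$lca_lineage[i] <- paste(paste0(lin$rank, ":", lin$name),
                                    collapse = ";")
      }
    }
    for (s in src_names) {
      fc <- functional_consensus(grp, fun_retained[[s]],
                                 functional_sources[[s]]$annotation)
      out[[paste0(s, "_label")]][i] <- fc$function_label
      out[[paste0(s, "_support")]][i] <- fc$function_support
      out[[paste0(s, "_used")]][i] <- fc$hits_used
    }
  }
  out
}

#' Write a consensus-annotation table
#'
#' Tab-delimited, single header line, `NA`-free (`"unassigned"` and empty
#' strings stand in for absent evidence), suitable for byte-identical
#' reproduction.
#'
#' @param annotations data.frame from [annotate_groups()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  tab <- annotations
  for (j in seq_along(tab)) {
    if (is.character(tab[[j]])) tab[[j]][is.na(tab[[j]])] <- ""
  }
  write_atomic(path, function(tmp) {
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
  invisible(path)
}
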