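#' Load an NCBI-style taxonomy from taxdump files
#'
#' Reads `nodes.dmp`, `names.dmp` and (optionally) `merged.dmp` in the NCBI
#' taxdump dialect (fields separated by `"\t|\t"`, rows terminated `"\t|"`)
#' and returns a `taxonomy_tree` object supporting lineage and
#' lowest-common-ancestor queries.
#'
#' Exactly one root is required: the node whose parent is itself. Taxa
#' without a `"scientific name"` row in `names.dmp` are named
#' `taxon_<id>`. Entries of `merged.dmp` redirect retired taxon ids to
#' their current id transparently at lookup time.
#'
#' @param nodes_path path to a `nodes.dmp`-style file (taxon id, parent id,
#'   rank in the first three fields).
#' @param names_path path to a `names.dmp`-style file; only rows whose name
#'   class is `"scientific name"` are used.
#' @param merged_path optional path to a `merged.dmp`-style file
#'   (old id, new id).
#' @return An object of class `taxonomy_tree`: a list with integer vector
#'   `taxon_id`, integer index vector `parent_idx`, character vectors
#'   `rank` and `name`, integer `depth` (root = 0), `root_idx`, and the
#'   `merged` redirection map.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' generate_taxonomy(3, 4, seed = 1, dir = dir)
#' tree <- load_taxonomy(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
#' taxonomy_lca(tree, tree$taxon_id[c(3, 5)])
#' @export
load_taxonomy <- function(nodes_path, names_path, merged_path = NULL) {
  nodes <- read_taxdump_rows(nodes_path)
  if (length(nodes) == 0L) {
    stop("taxonomy structural error: no root (empty nodes source)")
  }
  taxon_id <- vapply(nodes, function(f) as.integer(f[[1L]]), integer(1))
  parent_id <- vapply(nodes, function(f) as.integer(f[[2L]]), integer(1))
  rank <- vapply(nodes, function(f) if (length(f) >= 3L) f[[3L]] else "no rank",
                 character(1))
  if (anyNA(taxon_id) || anyNA(parent_id) || any(taxon_id <= 0L)) {
    stop("taxonomy structural error: non-numeric or non-positive taxon id")
  }
  if (anyDuplicated(taxon_id)) {
    dup <- taxon_id[duplicated(taxon_id)][1L]
    stop("taxonomy structural error: duplicate taxon_id ", dup)
  }

  idx_of <- make_id_index(taxon_id)
  parent_idx <- id_to_idx(idx_of, parent_id)
  if (anyNA(parent_idx)) {
    missing_parent <- parent_id[is.na(parent_idx)][1L]
    stop("taxonomy structural error: parent refers to unknown taxon ",
         missing_parent)
  }
  roots <- which(taxon_id == parent_id)
  if (length(roots) == 0L) stop("taxonomy structural error: no root")
  if (length(roots) > 1L) {
    stop("taxonomy structural error: multiple roots (",
         paste(taxon_id[roots], collapse = ", "), ")")
  }
  root_idx <- roots[[1L]]

  depth <- compute_depths(parent_idx, root_idx, taxon_id)

  name <- paste0("taxon_", taxon_id)
  sci <- read_scientific_names(names_path)
  hit <- id_to_idx(idx_of, sci$taxon_id)
  keep <- !is.na(hit)
  name[hit[keep]] <- sci$name[keep]

  merged <- integer(0)
  if (!is.null(merged_path) && file.exists(merged_path)) {
    mrows <- read_taxdump_rows(merged_path)
    if (length(mrows) > 0L) {
      old <- vapply(mrows, function(f) as.integer(f[[1L]]), integer(1))
      new <- vapply(mrows, function(f) as.integer(f[[2L]]), integer(1))
      if (anyNA(id_to_idx(idx_of, new))) {
        bad <- new[is.na(id_to_idx(idx_of, new))][1L]
        stop("taxonomy structural error: merged target ", bad,
             " is not a loaded taxon")
      }
      merged <- new
      names(merged) <- as.character(old)
    }
  }

  structure(
    list(taxon_id = taxon_id, parent_idx = parent_idx, rank = rank,
         name = name, depth = depth, root_idx = root_idx,
         idx_of = idx_of, merged = merged),
    class = "taxonomy_tree")
}

# Split taxdump rows on "\t|\t"; strip the "\t|" terminator. Blank lines
# are ignored.
read_taxdump_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

read_scientific_names <- function(path) {
  rows <- read_taxdump_rows(path)
  if (length(rows) == 0L) {
    return(list(taxon_id = integer(0), name = character(0)))
  }
  cls <- vapply(rows, function(f) if (length(f) >= 4L) f[[4L]] else "",
                character(1))
  rows <- rows[trimws(cls) == "scientific name"]
  list(taxon_id = vapply(rows, function(f) as.integer(f[[1L]]), integer(1)),
       name = vapply(rows, function(f) trimws(f[[2L]]), character(1)))
}

# Direct-index id -> position map. NCBI taxon ids are dense enough that a
# plain integer vector of length max(id) is cheap at any realistic scale.
make_id_index <- function(taxon_id) {
  if (max(taxon_id) > 1e8) {
    stop("taxon ids above 1e8 are not supported")
  }
  idx <- integer(max(taxon_id))
  idx[taxon_id] <- seq_along(taxon_id)
  idx
}

id_to_idx <- function(idx_of, ids) {
  out <- rep(NA_integer_, length(ids))
  ok <- !is.na(ids) & ids >= 1L & ids <= length(idx_of)
  hit <- idx_of[ids[ok]]
  hit[hit == 0L] <- NA_integer_
  out[ok] <- hit
  out
}

# Level-order depth assignment; a node never reached from the root lies on
# a cycle (or in a detached component), which the taxdump contract forbids.
compute_depths <- function(parent_idx, root_idx, taxon_id) {
  n <- length(parent_idx)
  depth <- rep(NA_integer_, n)
  depth[root_idx] <- 0L
  frontier <- root_idx
  children <- split(seq_len(n)[-root_idx], parent_idx[-root_idx])
  while (length(frontier) > 0L) {
    kids <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (is.null(kids) || length(kids) == 0L) break
    depth[kids] <- depth[parent_idx[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(depth)) {
    stop("taxonomy structural error: cycle detected involving taxon ",
         taxon_id[which(is.na(depth))[1L]])
  }
  depth
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", length(x$taxon_id), "nodes, root",
      x$taxon_id[x$root_idx], "\n")
  cat("  max depth:", max(x$depth), "; merged redirects:",
      length(x$merged), "\n")
  invisible(x)
}

#' Resolve taxon ids against a taxonomy, following merged redirects
#'
#' @param tree a `taxonomy_tree`.
#' @param ids integer vector of taxon ids.
#' @return Integer vector of internal node indices; `NA` where an id is
#'   neither loaded nor redirected by the merged map (a deleted taxon).
#' @export
resolve_taxa <- function(tree, ids) {
  ids <- as.integer(ids)
  idx <- id_to_idx(tree$idx_of, ids)
  if (length(tree$merged) > 0L && anyNA(idx)) {
    miss <- which(is.na(idx))
    redirect <- tree$merged[as.character(ids[miss])]
    idx[miss] <- id_to_idx(tree$idx_of, unname(redirect))
  }
  idx
}

#' Root-to-taxon lineage
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon_id a single taxon id (merged ids are redirected).
#' @return A data.frame with columns `taxon_id`, `rank`, `name`, ordered
#'   from the root (first row) to the queried taxon (last row).
#' @export
taxonomy_lineage <- function(tree, taxon_id) {
  idx <- resolve_taxa(tree, taxon_id)
  if (length(idx) != 1L || is.na(idx)) {
    stop("unknown taxon_id: ", taxon_id)
  }
  path <- integer(tree$depth[idx] + 1L)
  i <- idx
  for (k in seq_along(path)) {
    path[length(path) - k + 1L] <- i
    i <- tree$parent_idx[i]
  }
  data.frame(taxon_id = tree$taxon_id[path], rank = tree$rank[path],
             name = tree$name[path], stringsAsFactors = FALSE)
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' taxon (the strict LCA over all inputs, with no minimum-support or
#' score-window relaxation). Merged ids are redirected before the walk.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxa non-empty vector of taxon ids.
#' @return The LCA's taxon id (a single integer).
#' @export
taxonomy_lca <- function(tree, taxa) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("taxonomy_lca: empty taxon set")
  idx <- resolve_taxa(tree, taxa)
  if (anyNA(idx)) {
    stop("unknown taxon_id: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  acc <- idx[[1L]]
  for (j in idx[-1L]) {
    acc <- lca_pair_idx(tree, acc, j)
    if (acc == tree$root_idx) break
  }
  tree$taxon_id[acc]
}

# Depth-equalised parent climb on internal indices.
lca_pair_idx <- function(tree, a, b) {
  da <- tree$depth[a]; db <- tree$depth[b]
  while (da > db) { a <- tree$parent_idx[a]; da <- da - 1L }
  while (db > da) { b <- tree$parent_idx[b]; db <- db - 1L }
  while (a != b) {
    a <- tree$parent_idx[a]
    b <- tree$parent_idx[b]
  }
  a
}

#' Test ancestor-or-self relationships
#'
#' @param tree a `taxonomy_tree`.
#' @param ancestor candidate ancestor taxon id.
#' @param taxa vector of taxon ids to test.
#' @return Logical vector: `TRUE` where `ancestor` lies on the root path
#'   of the taxon (including the taxon itself).
#' @export
is_ancestor <- function(tree, ancestor, taxa) {
  anc_idx <- resolve_taxa(tree, ancestor)
  if (length(anc_idx) != 1L || is.na(anc_idx)) {
    stop("unknown taxon_id: ", ancestor)
  }
  idx <- resolve_taxa(tree, taxa)
  if (anyNA(idx)) {
    stop("unknown taxon_id: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  target_depth <- tree$depth[anc_idx]
  vapply(idx, function(i) {
    while (tree$depth[i] > target_depth) i <- tree$parent_idx[i]
    i == anc_idx
  }, logical(1))
}
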