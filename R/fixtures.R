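# Synthetic data with planted ground truth: random taxonomies in taxdump
# dialect, protein FASTAs, protein groups, annotation maps, and alignment
# tables whose consensus annotation is known by construction.

# Run expr under a fixed, fully specified RNG state, restoring the
# caller's stream afterwards. Full specification (kind + sample.kind)
# makes identical seeds give byte-identical files across sessions.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

rank_ladder <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Generate a random taxonomy in NCBI taxdump dialect
#'
#' Writes `nodes.dmp`, `names.dmp`, an empty `merged.dmp` and a root-path
#' index (`rootpaths.tsv`: taxon id and its semicolon-joined root-to-self
#' id path) into `dir`. Node ids are 1 (root), then internal nodes, then
#' leaves; every non-root node's parent is drawn among the nodes created
#' before it, so the tree is acyclic by construction. Ranks are assigned
#' top-down from the standard ladder (superkingdom ... species), deeper
#' nodes get `"no rank"`. The same seed reproduces byte-identical files.
#'
#' @param n_internal number of internal (non-root, non-leaf) nodes; >= 0.
#' @param n_leaves number of leaves; >= 2.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `nodes` table
#'   (taxon_id, parent_id, rank, name) and the leaf ids `leaves`.
#' @export
generate_taxonomy <- function(n_internal, n_leaves, seed, dir) {
  stopifnot(n_internal >= 0L, n_leaves >= 2L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_seed(seed, {
    n <- 1L + n_internal + n_leaves
    parent <- integer(n)
    parent[1L] <- 1L
    if (n_internal > 0L) {
      for (i in seq_len(n_internal) + 1L) {
        parent[i] <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      }
    }
    leaf_ids <- seq_len(n_leaves) + 1L + n_internal
    parent[leaf_ids] <- if (n_internal == 0L) 1L else
      sample.int(n_internal + 1L, n_leaves, replace = TRUE)

    depth <- integer(n)
    for (i in seq_len(n)[-1L]) depth[i] <- depth[parent[i]] + 1L
    rank <- ifelse(depth == 0L, "no rank",
                   ifelse(depth <= length(rank_ladder),
                          rank_ladder[pmax(depth, 1L)], "no rank"))
    nodes <- data.frame(taxon_id = seq_len(n), parent_id = parent,
                        rank = rank,
                        name = ifelse(depth == 0L, "root",
                                      paste0("Taxon ", seq_len(n))),
                        stringsAsFactors = FALSE)

    paths <- list(nodes = file.path(dir, "nodes.dmp"),
                  names = file.path(dir, "names.dmp"),
                  merged = file.path(dir, "merged.dmp"),
                  rootpaths = file.path(dir, "rootpaths.tsv"))
    writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nodes$taxon_id,
                       nodes$parent_id, nodes$rank), paths$nodes)
    writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                       nodes$taxon_id, nodes$name), paths$names)
    writeLines(character(0), paths$merged)

    root_path <- function(i) {
      p <- i
      while (i != 1L) { i <- parent[i]; p <- c(i, p) }
      paste(p, collapse = ";")
    }
    writeLines(c("taxon_id\troot_path",
                 sprintf("%d\t%s", seq_len(n),
                         vapply(seq_len(n), root_path, character(1)))),
               paths$rootpaths)
    invisible(list(paths = paths, nodes = nodes, leaves = leaf_ids))
  })
}

#' Describe the planted truth of a synthetic annotation scenario
#'
#' @param group_id character vector of group ids.
#' @param taxon_id planted taxon per group (must exist in the tree handed
#'   to [generate_scenario()]).
#' @param label planted function label per group.
#' @param noise fraction in `[0, 1)` of off-target hits per group; below
#'   0.5 the planted label is guaranteed a strict majority.
#' @param seed integer seed for scenario generation.
#' @param decoy_only logical per group: if `TRUE` the group receives only
#'   sub-threshold decoy hits (bitscore < 80) and must come out
#'   unassigned/unknown.
#' @return A `scenario_truth` data.frame.
#' @export
scenario_truth <- function(group_id, taxon_id, label, noise = 0,
                           seed = 1L, decoy_only = FALSE) {
  stopifnot(length(group_id) == length(taxon_id),
            length(group_id) == length(label),
            noise >= 0, noise < 1)
  truth <- data.frame(group_id = as.character(group_id),
                      taxon_id = as.integer(taxon_id),
                      label = as.character(label),
                      decoy_only = rep_len(decoy_only, length(group_id)),
                      stringsAsFactors = FALSE)
  attr(truth, "noise") <- noise
  attr(truth, "seed") <- as.integer(seed)
  class(truth) <- c("scenario_truth", "data.frame")
  truth
}

#' Generate a planted-truth annotation scenario
#'
#' Emits, into `dir`, every input the annotation pipeline consumes:
#' `proteins.fasta` (random amino-acid sequences for all group members,
#' plus optional planted exact duplicates), `groups.tsv`,
#' `functional_map.tsv`, `taxonomy_hits.tsv` (13-column tabular alignment
#' with a trailing `staxids` column), `functional_hits.tsv` (12-column),
#' and `truth.tsv`.
#'
#' Per group, `hits_per_group` scoring hits are spread round-robin over
#' the members: `floor(noise * hits_per_group)` off-target hits (taxon
#' from a clade disjoint from the planted one, all sharing that group's
#' single wrong label, bitscore uniform in 80–150) and the rest on-target
#' (taxon equal to the planted taxon or one of its descendants — the
#' first on-target hit always carries the planted taxon itself — label
#' equal to the planted label, bitscore uniform in 90–200). Additional
#' sub-threshold decoy hits (bitscore < 80) exercise the retention
#' filter; `decoy_only` groups receive nothing else.
#'
#' @param truth a [scenario_truth()] table.
#' @param tree the `taxonomy_tree` the planted taxa live in.
#' @param dir output directory.
#' @param members_per_group proteins per group.
#' @param hits_per_group scoring (above-threshold) hits per group.
#' @param decoys_per_group sub-threshold hits added per group.
#' @param n_duplicates planted exact-duplicate FASTA records.
#' @return Invisibly, a list of output `paths` and the `truth` table.
#' @export
generate_scenario <- function(truth, tree, dir, members_per_group = 2L,
                              hits_per_group = 10L, decoys_per_group = 2L,
                              n_duplicates = 0L) {
  stopifnot(inherits(truth, "scenario_truth"))
  bad <- is.na(resolve_taxa(tree, truth$taxon_id))
  if (any(bad)) {
    stop("planted taxon absent from tree: ",
         paste(truth$taxon_id[bad], collapse = ", "))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  noise <- attr(truth, "noise")

  with_seed(attr(truth, "seed"), {
    all_ids <- tree$taxon_id
    members <- lapply(truth$group_id, function(g)
      sprintf("%s_P%d", g, seq_len(members_per_group)))

    fasta <- data.frame(header = character(0), sequence = character(0),
                        stringsAsFactors = FALSE)
    for (m in unlist(members)) {
      len <- sample(80:300, 1L)
      seqc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                           len, replace = TRUE), collapse = "")
      fasta <- rbind(fasta, data.frame(
        header = paste(m, "synthetic protein"), sequence = seqc,
        stringsAsFactors = FALSE))
    }
    if (n_duplicates > 0L) {
      src <- sample.int(nrow(fasta), n_duplicates, replace = TRUE)
      fasta <- rbind(fasta, data.frame(
        header = sprintf("DUP%d synthetic duplicate of %s",
                         seq_len(n_duplicates),
                         sub(" .*$", "", fasta$header[src])),
        sequence = fasta$sequence[src], stringsAsFactors = FALSE))
    }

    ann_acc <- character(0); ann_label <- character(0)
    tax_rows <- character(0); fun_rows <- character(0)

    aln_row <- function(q, s, bits, taxa = NULL) {
      ev <- 10^-stats::runif(1, 5, 30)
      base <- sprintf(
        "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
        q, s, stats::runif(1, 30, 100), sample(50:250, 1L), sample(0:20, 1L),
        sample(0:5, 1L), 1L, 100L, 1L, 100L, ev, bits)
      if (is.null(taxa)) base else
        paste0(base, "\t", paste(taxa, collapse = ";"))
    }

    for (gi in seq_len(nrow(truth))) {
      g <- truth$group_id[gi]
      planted <- truth$taxon_id[gi]
      mems <- members[[gi]]

      clade <- all_ids[is_ancestor(tree, planted, all_ids)]
      disjoint <- all_ids[!is_ancestor(tree, planted, all_ids) &
                            !vapply(all_ids, function(t)
                              is_ancestor(tree, t, planted), logical(1))]
      if (length(disjoint) == 0L && noise > 0 && !truth$decoy_only[gi]) {
        stop("no clade disjoint from planted taxon ", planted,
             " (is it the root?)")
      }

      sub_on <- paste0("SUBT_", g); sub_off <- paste0("SUBN_", g)
      sub_dec <- paste0("SUBD_", g)
      wrong_label <- paste("off-target function", g)
      ann_acc <- c(ann_acc, sub_on, sub_off)
      ann_label <- c(ann_label, truth$label[gi], wrong_label)

      if (!truth$decoy_only[gi]) {
        n_off <- floor(noise * hits_per_group)
        n_on <- hits_per_group - n_off
        on_q <- rep_len(mems, n_on)
        off_q <- if (n_off > 0L) rep_len(rev(mems), n_off) else character(0)
        for (k in seq_len(n_on)) {
          taxon <- if (k == 1L) planted else
            clade[sample.int(length(clade), 1L)]
          bits <- stats::runif(1, 90, 200)
          tax_rows <- c(tax_rows, aln_row(on_q[k], sub_on, bits, taxon))
          fun_rows <- c(fun_rows, aln_row(on_q[k], sub_on,
                                          stats::runif(1, 90, 200)))
        }
        for (k in seq_len(n_off)) {
          taxon <- disjoint[sample.int(length(disjoint), 1L)]
          tax_rows <- c(tax_rows, aln_row(off_q[k], sub_off,
                                          stats::runif(1, 80, 150), taxon))
          fun_rows <- c(fun_rows, aln_row(off_q[k], sub_off,
                                          stats::runif(1, 80, 150)))
        }
      }
      n_dec <- if (truth$decoy_only[gi]) max(decoys_per_group, 2L) else
        decoys_per_group
      dec_q <- rep_len(mems, n_dec)
      for (k in seq_len(n_dec)) {
        taxon <- all_ids[sample.int(length(all_ids), 1L)]
        tax_rows <- c(tax_rows, aln_row(dec_q[k], sub_dec,
                                        stats::runif(1, 40, 79.4), taxon))
        fun_rows <- c(fun_rows, aln_row(dec_q[k], sub_dec,
                                        stats::runif(1, 40, 79.4)))
      }
    }

    paths <- list(fasta = file.path(dir, "proteins.fasta"),
                  groups = file.path(dir, "groups.tsv"),
                  annotation = file.path(dir, "functional_map.tsv"),
                  tax_aln = file.path(dir, "taxonomy_hits.tsv"),
                  fun_aln = file.path(dir, "functional_hits.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    writeLines(paste0(">", fasta$header, "\n",
                      gsub("(.{60})", "\\1\n", fasta$sequence)) |>
                 sub(pattern = "\n$", replacement = ""),
               paths$fasta)
    writeLines(c("group_id\tmembers",
                 sprintf("%s\t%s", truth$group_id,
                         vapply(members, paste, character(1),
                                collapse = ","))), paths$groups)
    writeLines(c("accession\tlabel",
                 sprintf("%s\t%s", ann_acc, ann_label)), paths$annotation)
    writeLines(tax_rows, paths$tax_aln)
    writeLines(fun_rows, paths$fun_aln)
    writeLines(c("group_id\ttaxon_id\tlabel\tnoise\tdecoy_only",
                 sprintf("%s\t%d\t%s\t%.3f\t%s", truth$group_id,
                         truth$taxon_id, truth$label, noise,
                         truth$decoy_only)), paths$truth)
    invisible(list(paths = paths, truth = truth))
  })
}
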