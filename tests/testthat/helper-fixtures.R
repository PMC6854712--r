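# Shared test fixtures: a hand-written toy NCBI-style taxonomy, builders
# for alignment-hit tables, and a brute-force LCA oracle independent of
# the package's climbing implementation.

# 7-node toy taxonomy:
#   1 root; 2 Bacteria; 1224 Proteobacteria (<-2); 1236 Gammaproteobacteria
#   (<-1224); 562 E. coli (<-1236); 1239 Firmicutes (<-2); 1423 B. subtilis
#   (<-1239)
write_toy_taxdump <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              merged = NULL, drop_name_for = integer(0)) {
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t1\t|\tsuperkingdom\t|",
             "1224\t|\t2\t|\tphylum\t|",
             "1236\t|\t1224\t|\tclass\t|",
             "562\t|\t1236\t|\tspecies\t|",
             "1239\t|\t2\t|\tphylum\t|",
             "1423\t|\t1239\t|\tspecies\t|")
  nm <- rbind(c(1, "root"), c(2, "Bacteria"), c(1224, "Proteobacteria"),
              c(1236, "Gammaproteobacteria"), c(562, "Escherichia coli"),
              c(1239, "Firmicutes"), c(1423, "Bacillus subtilis"))
  nm <- nm[!nm[, 1] %in% as.character(drop_name_for), , drop = FALSE]
  names_rows <- sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|",
                        nm[, 1], nm[, 2])
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names_rows, file.path(dir, "names.dmp"))
  merged_rows <- if (is.null(merged)) character(0) else
    sprintf("%d\t|\t%d\t|", merged[, 1], merged[, 2])
  writeLines(merged_rows, file.path(dir, "merged.dmp"))
  dir
}

toy_tree <- function(...) {
  dir <- write_toy_taxdump(...)
  load_taxonomy(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
                file.path(dir, "merged.dmp"))
}

# Build a hit table shaped like read_alignments() output.
make_hits <- function(bitscore, evalue = rep(1e-10, length(bitscore)),
                      query_id = "q1",
                      subject_id = sprintf("s%d", seq_along(bitscore)),
                      subject_taxa = rep(list(integer(0)),
                                         length(bitscore))) {
  n <- length(bitscore)
  q <- rep_len(query_id, n)
  df <- data.frame(query_id = q,
                   subject_id = rep_len(subject_id, n),
                   bitscore = bitscore,
                   evalue = rep_len(evalue, n),
                   raw_rank = stats::ave(seq_len(n), q,
                                         FUN = seq_along) - 1L,
                   stringsAsFactors = FALSE)
  df$subject_taxa <- subject_taxa
  df
}

# Brute-force LCA oracle: intersect explicit root paths read straight
# from a parent table (no depth tricks, no index structures).
oracle_root_path <- function(parent_of, id) {
  path <- id
  while (parent_of[[as.character(id)]] != id) {
    id <- parent_of[[as.character(id)]]
    path <- c(id, path)
  }
  path
}

oracle_lca <- function(parent_of, a, b) {
  pa <- oracle_root_path(parent_of, a)
  pb <- oracle_root_path(parent_of, b)
  k <- min(length(pa), length(pb))
  common <- which(pa[seq_len(k)] == pb[seq_len(k)])
  pa[max(common)]
}

# parent table of a generated taxonomy, from its raw nodes.dmp
read_parent_table <- function(nodes_path) {
  rows <- strsplit(sub("\t\\|$", "", readLines(nodes_path)), "\t\\|\t")
  ids <- vapply(rows, function(f) as.integer(f[[1]]), integer(1))
  stats::setNames(vapply(rows, function(f) as.integer(f[[2]]), integer(1)),
                  as.character(ids))
}

# One-call scenario: taxonomy + planted-truth files in a temp dir.
make_scenario <- function(n_groups = 5L, noise = 0, seed = 42L,
                          decoy_only = FALSE, n_internal = 10L,
                          n_leaves = 15L, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  taxo <- generate_taxonomy(n_internal, n_leaves, seed, dir)
  tree <- load_taxonomy(taxo$paths$nodes, taxo$paths$names,
                        taxo$paths$merged)
  planted <- taxo$leaves[(seq_len(n_groups) - 1L) %% length(taxo$leaves) + 1L]
  truth <- scenario_truth(sprintf("G%02d", seq_len(n_groups)), planted,
                          sprintf("Planted function %d", seq_len(n_groups)),
                          noise = noise, seed = seed,
                          decoy_only = decoy_only)
  sc <- generate_scenario(truth, tree, file.path(dir, "scenario"), ...)
  list(dir = dir, tree = tree, taxo = taxo, truth = truth,
       paths = sc$paths)
}

run_annotation <- function(sc, policy = filter_policy()) {
  groups <- read_protein_groups(sc$paths$groups)
  tax <- read_alignments(sc$paths$tax_aln,
                         columns = outfmt6_columns(staxids = TRUE))
  fun <- read_alignments(sc$paths$fun_aln,
                         columns = outfmt6_columns(staxids = FALSE))
  amap <- read_annotation_map(sc$paths$annotation)
  annotate_groups(groups, taxonomy_hits = tax,
                  functional_sources = list(fn = list(hits = fun,
                                                      annotation = amap)),
                  tree = sc$tree, policy = policy)
}
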