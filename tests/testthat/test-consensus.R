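grp <- function(id = "g1", members = c("p1", "p2")) {
  list(group_id = id, members = members)
}

test_that("taxonomic consensus pools member hits and takes the LCA", {
  tree <- toy_tree()
  retained <- list(
    p1 = make_hits(150, query_id = "p1", subject_taxa = list(562L)),
    p2 = make_hits(120, query_id = "p2", subject_taxa = list(1236L)))
  tc <- taxonomic_consensus(grp(), retained, tree)
  expect_identical(tc$lca_taxon, 1236L)
  expect_identical(tc$hits_used, 2L)
  expect_identical(tc$hits_unresolvable, 0L)
  expect_identical(tc$lineage$taxon_id, c(1L, 2L, 1224L, 1236L))

  # singleton identity
  tc1 <- taxonomic_consensus(
    grp(members = "p1"),
    list(p1 = make_hits(100, query_id = "p1", subject_taxa = list(1423L))),
    tree)
  expect_identical(tc1$lca_taxon, 1423L)
})

test_that("hits without resolvable taxa are excluded and counted", {
  tree <- toy_tree()
  retained <- list(
    p1 = make_hits(c(150, 140), query_id = "p1",
                   subject_taxa = list(integer(0), 4242L)))
  tc <- taxonomic_consensus(grp(members = "p1"), retained, tree)
  expect_identical(tc$lca_taxon, NA_integer_)   # unassigned
  expect_identical(tc$hits_used, 0L)
  expect_identical(tc$hits_unresolvable, 2L)
  expect_identical(nrow(tc$lineage), 0L)
})

test_that("a multi-taxon hit casts a single pre-collapsed vote", {
  tree <- toy_tree()
  # one row listing E. coli and B. subtilis collapses to Bacteria (2)
  retained <- list(
    p1 = make_hits(150, query_id = "p1", subject_taxa = list(c(562L, 1423L))))
  tc <- taxonomic_consensus(grp(members = "p1"), retained, tree)
  expect_identical(tc$lca_taxon, 2L)
  expect_identical(tc$hits_used, 1L)

  # partially resolvable list: unresolvable member ignored, hit still votes
  retained2 <- list(
    p1 = make_hits(150, query_id = "p1", subject_taxa = list(c(562L, 4242L))))
  tc2 <- taxonomic_consensus(grp(members = "p1"), retained2, tree)
  expect_identical(tc2$lca_taxon, 562L)
  expect_identical(tc2$hits_unresolvable, 0L)
})

test_that("functional consensus elects the most frequent label", {
  ann <- c(s1 = "DnaK", s2 = "DnaK", s3 = "GroEL")
  retained <- list(p1 = make_hits(c(100, 95, 90), query_id = "p1",
                                  subject_id = c("s1", "s2", "s3")))
  fc <- functional_consensus(grp(members = "p1"), retained, ann)
  expect_identical(fc$function_label, "DnaK")
  expect_identical(fc$function_support, 2L)
  expect_identical(fc$hits_used, 3L)
})

test_that("functional ties break by summed bitscore then label order", {
  # A: 100 + 50 = 150; B: 110 + 100 = 210 -> B wins despite equal votes
  ann <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  retained <- list(p1 = make_hits(c(100, 50, 110, 100), query_id = "p1",
                                  subject_id = c("s1", "s2", "s3", "s4")))
  fc <- functional_consensus(grp(members = "p1"), retained, ann)
  expect_identical(fc$function_label, "B")
  expect_identical(fc$function_support, 2L)
  expect_identical(fc$hits_used, 4L)

  # equal votes and equal summed bitscore -> lexicographically smallest
  ann2 <- c(s1 = "zeta", s2 = "alpha")
  retained2 <- list(p1 = make_hits(c(90, 90), query_id = "p1",
                                   subject_id = c("s1", "s2")))
  fc2 <- functional_consensus(grp(members = "p1"), retained2, ann2)
  expect_identical(fc2$function_label, "alpha")
})

test_that("label voting normalizes whitespace and case but keeps casing", {
  ann <- c(s1 = "  heat  shock\tprotein ", s2 = "Heat shock protein",
           s3 = "Heat shock protein")
  retained <- list(p1 = make_hits(c(90, 90, 90), query_id = "p1",
                                  subject_id = c("s1", "s2", "s3")))
  fc <- functional_consensus(grp(members = "p1"), retained, ann)
  expect_identical(fc$function_label, "Heat shock protein")
  expect_identical(fc$function_support, 3L)
})

test_that("abstentions and empty evidence are handled", {
  # s2 missing from the map: abstains, excluded from hits_used
  ann <- c(s1 = "DnaK")
  retained <- list(p1 = make_hits(c(100, 90), query_id = "p1",
                                  subject_id = c("s1", "s2")))
  fc <- functional_consensus(grp(members = "p1"), retained, ann)
  expect_identical(fc$hits_used, 1L)
  expect_identical(fc$function_support, 1L)

  fc0 <- functional_consensus(grp(), list(), c(s1 = "X"))
  expect_identical(fc0$function_label, "hypothetical/unknown")
  expect_identical(fc0$function_support, 0L)
  expect_identical(fc0$hits_used, 0L)
})

test_that("vote bookkeeping is conserved per group", {
  withr::local_seed(7)
  labels <- c("A", "B", "C")
  for (case in 1:25) {
    n <- sample(1:30, 1)
    subj <- sprintf("s%d", seq_len(n))
    # ~1/4 of subjects missing from the map -> abstentions
    mapped <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(3, 1))
    ann <- stats::setNames(sample(labels, sum(mapped), replace = TRUE),
                           subj[mapped])
    retained <- list(p1 = make_hits(runif(n, 80, 200), query_id = "p1",
                                    subject_id = subj))
    fc <- functional_consensus(grp(members = "p1"), retained, ann)
    abstained <- n - fc$hits_used
    losers <- fc$hits_used - fc$function_support
    expect_identical(fc$function_support + abstained + losers, n)
    expect_lte(fc$function_support, fc$hits_used)
  }
})

test_that("annotate_groups recovers planted truth on a noise-free scenario", {
  sc <- make_scenario(n_groups = 5, noise = 0, seed = 42)
  ann <- run_annotation(sc)
  expect_identical(ann$group_id, sc$truth$group_id)
  expect_identical(ann$lca_taxon_id, as.character(sc$truth$taxon_id))
  expect_identical(ann$fn_label, sc$truth$label)
  expect_true(all(ann$fn_support == ann$fn_used))  # no contradicting votes
})

test_that("annotate_groups handles degenerate inputs", {
  tree <- toy_tree()
  empty <- data.frame(group_id = character(0))
  empty$members <- list()
  out <- annotate_groups(empty, NULL, list(), tree)
  expect_identical(nrow(out), 0L)

  # taxonomy evidence only: functional columns absent; with a functional
  # source but no hits for the group, the label defaults
  g <- data.frame(group_id = "g1")
  g$members <- list("p1")
  tax <- make_hits(120, query_id = "p1", subject_taxa = list(562L))
  out2 <- annotate_groups(g, tax, list(up = list(hits = make_hits(numeric(0)),
                                                 annotation = character(0))),
                          tree)
  expect_identical(out2$lca_taxon_id, "562")
  expect_identical(out2$up_label, "hypothetical/unknown")
  expect_identical(out2$up_support, 0L)

  dup <- data.frame(group_id = c("g1", "g1"))
  dup$members <- list("p1", "p2")
  expect_error(annotate_groups(dup, NULL, list(), tree), "duplicate group_id")
})

test_that("alignment queries matching no group member are ignored loudly", {
  tree <- toy_tree()
  g <- data.frame(group_id = "g1")
  g$members <- list("p1")
  tax <- rbind(make_hits(120, query_id = "p1", subject_taxa = list(562L)),
               make_hits(150, query_id = "stray", subject_taxa = list(1423L)))
  expect_message(out <- annotate_groups(g, tax, list(), tree),
                 "1 alignment query")
  expect_identical(out$lca_taxon_id, "562")
})

test_that("annotation output is deterministic byte for byte", {
  sc <- make_scenario(n_groups = 4, noise = 0.2, seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotations(run_annotation(sc), f1)
  write_annotations(run_annotation(sc), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(length(readLines(f1)) == nrow(sc$truth) + 1L)
})

test_that("LCA moves toward the root only under disjoint evidence", {
  tree <- toy_tree()
  base <- list(p1 = make_hits(c(150, 140), query_id = "p1",
                              subject_taxa = list(562L, 1236L)))
  lca0 <- taxonomic_consensus(grp(members = "p1"), base, tree)$lca_taxon
  expect_identical(lca0, 1236L)

  # ancestor-or-self of the current LCA: no change
  anc <- base
  anc$p1 <- rbind(anc$p1, make_hits(130, query_id = "p1",
                                    subject_taxa = list(1236L)))
  expect_identical(taxonomic_consensus(grp(members = "p1"), anc, tree)$lca_taxon,
                   lca0)

  # disjoint clade: strictly toward the root
  dis <- base
  dis$p1 <- rbind(dis$p1, make_hits(130, query_id = "p1",
                                    subject_taxa = list(1423L)))
  lca2 <- taxonomic_consensus(grp(members = "p1"), dis, tree)$lca_taxon
  expect_identical(lca2, 2L)
  expect_lt(tree$depth[tree$taxon_id == lca2],
            tree$depth[tree$taxon_id == lca0])
})
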