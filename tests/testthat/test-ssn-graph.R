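# helpers to fabricate alignment tables directly
fake_alignments <- function(from, to, evalue) {
  n <- length(from)
  data.frame(query_id = from, subject_id = to,
             raw_score = rep(0, n), bit_score = -log2(evalue),
             evalue = evalue, identity = rep(0.5, n),
             aligned_columns = rep(100L, n),
             stringsAsFactors = FALSE)
}

test_that("SSN thresholding keeps exactly the passing edges", {
  al <- fake_alignments(c("a", "b", "c"), c("b", "c", "d"),
                        c(1e-60, 1e-60, 1e-60))
  g <- build_ssn(al, 10^-51.5)
  expect_equal(nrow(g$edges), 3L)
  g0 <- build_ssn(al, 1e-70)
  expect_equal(nrow(g0$edges), 0L)
  expect_equal(nrow(g0$nodes), 4L)  # nodes survive at any cutoff

  expect_error(build_ssn(al, -1), "positive")

  # mixed E-values: kept set equals an independent one-line filter
  set.seed(41)
  ev <- 10^-runif(30, 20, 80)
  pairs <- t(combn(sprintf("n%02d", 1:9), 2))[1:30, ]
  al2 <- fake_alignments(pairs[, 1], pairs[, 2], ev)
  ct <- 1e-45
  g2 <- build_ssn(al2, ct)
  expect_equal(nrow(g2$edges), sum(ev <= ct))
  expect_setequal(paste(g2$edges$from, g2$edges$to),
                  paste(pmin(pairs[ev <= ct, 1], pairs[ev <= ct, 2]),
                        pmax(pairs[ev <= ct, 1], pairs[ev <= ct, 2])))
})

test_that("self-edges and duplicate undirected edges are dropped", {
  al <- fake_alignments(c("a", "a", "b"), c("a", "b", "a"),
                        c(1e-60, 1e-60, 1e-60))
  g <- build_ssn(al, 1e-50)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "a")
  expect_equal(g$edges$to, "b")
})

test_that("components match the transitive-closure oracle on random graphs", {
  set.seed(42)
  for (k in 1:30) {
    n <- sample(5:50, 1)
    ids <- sprintf("v%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    from <- sample(ids, m, replace = TRUE)
    to <- sample(ids, m, replace = TRUE)
    keep <- from != to
    al <- fake_alignments(from[keep], to[keep],
                          rep(1e-60, sum(keep)))
    g <- build_ssn(al, 1e-50, singletons = ids)
    cl <- ssn_components(g)
    oracle <- oracle_components(ids, from[keep], to[keep])
    # same partition: cluster ids co-occur identically
    expect_equal(length(unique(cl$membership)), length(unique(oracle)))
    expect_true(all(tapply(oracle, cl$membership[ids],
                           function(x) length(unique(x))) == 1))
  }
})

test_that("edgeless graphs give singleton clusters", {
  g <- build_ssn(fake_alignments(character(), character(), numeric()),
                 1e-50, singletons = letters[1:5])
  cl <- ssn_components(g)
  expect_equal(length(cl$clusters), 5L)
  expect_true(all(lengths(cl$clusters) == 1L))
})

test_that("cluster numbering is invariant to input order", {
  set.seed(43)
  ids <- sprintf("v%02d", 1:12)
  al <- fake_alignments(c("v01", "v02", "v05", "v06", "v07"),
                        c("v02", "v03", "v06", "v07", "v08"),
                        rep(1e-60, 5))
  g1 <- build_ssn(al, 1e-50, singletons = ids)
  perm <- sample(nrow(al))
  g2 <- build_ssn(al[perm, ], 1e-50, singletons = sample(ids))
  c1 <- ssn_components(g1)
  c2 <- ssn_components(g2)
  expect_equal(c1$membership[sort(names(c1$membership))],
               c2$membership[sort(names(c2$membership))])
  expect_equal(c1$clusters, c2$clusters)
})

test_that("planted two-family data resolve into exactly the two families", {
  fs <- make_family_set(family_spec(n_families = 2, members_per_family = 6,
                                    substitution_rate = 0.1, rng_seed = 44))
  al <- all_vs_all(fs$records, evalue_cutoff = Inf)
  g <- build_ssn(al, 10^-51.5, singletons = fs$records$id)
  cl <- ssn_components(g)
  expect_equal(length(cl$clusters), 2L)
  fam <- setNames(fs$truth$family, fs$truth$id)
  for (cluster in cl$clusters) {
    expect_equal(length(unique(fam[cluster])), 1L)
  }
  expect_equal(
    mclust::adjustedRandIndex(cl$membership[fs$truth$id],
                              fs$truth$family), 1)
})

test_that("threshold sweep is consistent and nested across cutoffs", {
  fs <- make_family_set(family_spec(n_families = 3, members_per_family = 4,
                                    substitution_rate = 0.12, rng_seed = 45))
  al <- all_vs_all(fs$records, evalue_cutoff = Inf)
  cutoffs <- 10^seq(-20, -110, by = -10)
  sweep_tab <- threshold_sweep(al, cutoffs)
  # independent per-cutoff recomputation
  for (i in seq_along(cutoffs)) {
    g <- build_ssn(al, cutoffs[i])
    cl <- ssn_components(g)
    expect_equal(sweep_tab$n_edges[i], nrow(g$edges))
    expect_equal(sweep_tab$n_clusters[i], length(cl$clusters))
    expect_equal(sweep_tab$largest_cluster_size[i],
                 max(lengths(cl$clusters)))
  }
  # loosening the cutoff cannot split clusters or remove edges
  ord <- order(sweep_tab$cutoff)  # increasing cutoff = loosening
  expect_true(all(diff(sweep_tab$n_edges[ord]) >= 0))
  expect_true(all(diff(sweep_tab$n_clusters[ord]) <= 0))
})

test_that("clusters at a looser cutoff are unions of stricter clusters", {
  fs <- make_family_set(family_spec(n_families = 2, members_per_family = 5,
                                    substitution_rate = 0.12, rng_seed = 46))
  al <- all_vs_all(fs$records, evalue_cutoff = Inf)
  strict <- ssn_components(build_ssn(al, 10^-51.5,
                                     singletons = fs$records$id))
  loose <- ssn_components(build_ssn(al, 1e-25,
                                    singletons = fs$records$id))
  for (cluster in strict$clusters) {
    expect_equal(length(unique(loose$membership[cluster])), 1L)
  }
})

test_that("query assignment reports co-membership, best neighbor, unclustered", {
  al <- fake_alignments(c("a", "c"), c("b", "d"), c(1e-60, 1e-60))
  g <- build_ssn(al, 1e-50,
                 labels = c(a = "polyamine/amine", c = "shikimate-type"))
  qa <- fake_alignments(c("q", "q"), c("a", "b"), c(1e-70, 1e-55))
  asg <- assign_query(g, qa, "q")
  expect_equal(asg$status, "clustered")
  expect_setequal(asg$cluster_members, c("a", "b"))
  expect_equal(asg$labels, "polyamine/amine")
  expect_equal(asg$best_neighbor$id, "a")

  none <- assign_query(g, fake_alignments("q", "a", 1e-10), "q")
  expect_equal(none$status, "unclustered")

  expect_error(assign_query(g, qa, "a"), "already present")
})

test_that("synthetic queries assign to their own planted family", {
  fs <- make_family_set(family_spec(n_families = 2, members_per_family = 5,
                                    substitution_rate = 0.1, rng_seed = 47))
  # hold out one member of family 1 as the query
  qid <- fs$records$id[fs$records$family == "fam01"][1]
  rest <- fs$records[fs$records$id != qid, ]
  al <- all_vs_all(rest, evalue_cutoff = Inf)
  g <- build_ssn(al, 10^-51.5, singletons = rest$id,
                 labels = setNames(rest$family, rest$id))
  qa <- all_vs_all(fs$records, evalue_cutoff = Inf)
  qa <- qa[qa$query_id == qid | qa$subject_id == qid, ]
  asg <- assign_query(g, qa, qid)
  expect_equal(asg$status, "clustered")
  expect_equal(unique(asg$labels), "fam01")
})

test_that("GraphML and edge-TSV exports round-trip the graph", {
  al <- fake_alignments(c("a", "b"), c("b", "c"), c(1e-60, 1e-55))
  g <- build_ssn(al, 1e-50, singletons = c("a", "b", "c", "lonely"),
                 labels = c(a = "polyamine/amine"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_ssn(g, gml, "graphml")
  g2 <- import_ssn(gml, "graphml")
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$nodes$label, g$nodes$label)
  expect_equal(g2$edges$from, g$edges$from)
  expect_equal(g2$edges$evalue, g$edges$evalue, tolerance = 1e-9)
  expect_equal(g2$evalue_cutoff, g$evalue_cutoff, tolerance = 1e-9)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_ssn(g, tsv, "edge-tsv")
  g3 <- import_ssn(tsv, "edge-tsv")
  expect_equal(g3$nodes$id, g$nodes$id)  # singletons retained
  expect_equal(g3$edges$evalue, g$edges$evalue)
  expect_equal(g3$evalue_cutoff, g$evalue_cutoff)

  # empty graph still exports validly
  g0 <- build_ssn(fake_alignments(character(), character(), numeric()),
                  1e-50, singletons = "only")
  export_ssn(g0, gml, "graphml")
  expect_equal(nrow(import_ssn(gml, "graphml")$edges), 0L)
})

test_that("cluster membership TSV lists every node with its labels", {
  al <- fake_alignments("a", "b", 1e-60)
  g <- build_ssn(al, 1e-50, singletons = c("a", "b", "c"),
                 labels = c(a = "polyamine/amine"))
  cl <- ssn_components(g)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_tsv(cl, tf)
  tab <- read.table(tf, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_setequal(tab$id, c("a", "b", "c"))
  expect_equal(tab$labels[tab$id == "b"], "polyamine/amine")
})
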