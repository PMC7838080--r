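test_that("identity distances: zero for identical, definitional p-distance", {
  rec <- protein_records(c("a", "b", "c"),
                         c("MKHLDMKHLD", "MKHLDMKHLD", "MKHLDAAAAA"))
  D <- identity_distance_matrix(rec)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.5)  # 5 of 10 columns differ, no gaps
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 3), rec$id))
})

test_that("distance matrix equals element-wise global_align recomputation", {
  set.seed(51)
  rec <- evolve_family(make_seed_sequence(150), 5,
                       substitution_rate = 0.2, family_id = "dm")
  D <- identity_distance_matrix(rec)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j],
                 1 - global_align(rec[i, ], rec[j, ])$identity,
                 tolerance = 1e-12)
  }
})

test_that("Poisson correction applies -ln(identity) with a cap near zero", {
  rec <- protein_records(c("a", "b", "c"),
                         c("MKHLDMKHLD", "MKHLDMKHLE", "MKHLDAAAAA"))
  Dp <- identity_distance_matrix(rec, model = "p")
  Dc <- identity_distance_matrix(rec, model = "poisson")
  expect_equal(Dc["a", "b"], -log(1 - Dp["a", "b"]), tolerance = 1e-12)
  # forced zero identity between unalignable extremes hits the cap
  rec2 <- protein_records(c("a", "b", "c"),
                          c("WWWWWWWWWW", "PPPPPPPPPP", "GGGGGGGGGG"))
  expect_warning(D2 <- identity_distance_matrix(rec2, model = "poisson",
                                                max_distance = 5))
  expect_true(all(D2[upper.tri(D2)] <= 5))
})

test_that("three-taxon NJ solves the closed-form star", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(length(tr$tip.label), 3L)
  # terminal branch lengths a:1, b:1, c:3
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
})

test_that("NJ input validation rejects malformed matrices", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(D), "3 taxa")
  D3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "symmetric")
  D4 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D4), "non-negative")
})

test_that("NJ exactly recovers additive matrices (topology and lengths)", {
  # hand-built additive 4-taxon case: ((a:1,b:2):1.5,c:3,d:4) unrooted
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5.5
  D["a", "d"] <- D["d", "a"] <- 6.5
  D["b", "c"] <- D["c", "b"] <- 6.5
  D["b", "d"] <- D["d", "b"] <- 7.5
  D["c", "d"] <- D["d", "c"] <- 7
  tr <- nj_tree(D)
  C <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(C, D, tolerance = 1e-10)

  set.seed(52)
  for (k in 1:20) {
    gen <- random_additive_matrix(sample(4:8, 1))
    tr <- nj_tree(gen$D)
    expect_true(same_topology(tr, gen$tree))
    C <- ape::cophenetic.phylo(tr)
    C <- C[rownames(gen$D), colnames(gen$D)]
    expect_equal(C, gen$D, tolerance = 1e-8)
  }
})

test_that("only the generating topology fits an additive matrix exactly", {
  # exhaustive scoring over all unrooted 6-taxon topologies: least-squares
  # residual is zero only at the NJ topology
  set.seed(53)
  gen <- random_additive_matrix(6)
  njt <- nj_tree(gen$D)
  taxa <- rownames(gen$D)
  topos <- phangorn::allTrees(6, rooted = FALSE, tip.label = taxa)
  resid_of <- function(topo) {
    n_edge <- nrow(topo$edge)
    pairs <- t(combn(seq_along(taxa), 2))
    X <- matrix(0, nrow(pairs), n_edge)
    # edge-incidence: which edges lie on the path between each tip pair
    for (r in seq_len(nrow(pairs))) {
      pth <- ape::nodepath(topo, pairs[r, 1], pairs[r, 2])
      on_path <- apply(topo$edge, 1, function(e)
        all(e %in% pth) &&
          abs(match(e[1], pth) - match(e[2], pth)) == 1)
      X[r, ] <- as.numeric(on_path)
    }
    y <- gen$D[cbind(taxa[pairs[, 1]], taxa[pairs[, 2]])]
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  res <- vapply(topos, resid_of, numeric(1))
  best <- which(res < 1e-12)
  expect_equal(length(best), 1L)
  expect_true(same_topology(topos[[best]], njt))
})

test_that("NJ splits are invariant under leaf permutation", {
  set.seed(54)
  gen <- random_additive_matrix(7)
  tr1 <- nj_tree(gen$D)
  perm <- sample(7)
  Dp <- gen$D[perm, perm]
  tr2 <- nj_tree(Dp)
  expect_true(same_topology(tr1, tr2))
  expect_equal(sort(round(tr1$edge.length, 10)),
               sort(round(tr2$edge.length, 10)))
})

test_that("negative NJ branch lengths are clamped with a record", {
  # strongly non-additive matrix known to drive a branch negative
  D <- matrix(c(0, 5, 9, 9, 5, 0, 1, 1, 9, 1, 0, 8, 9, 1, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
  clamped <- attr(tr, "clamped_branch_lengths")
  expect_gt(nrow(clamped), 0)
  expect_true(all(clamped$original < 0))
})

test_that("Newick writer emits fixed 6-decimal lengths and quotes labels", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s <- write_newick(nj_tree(D))
  expect_match(s, "^\\(.*\\);$")
  expect_match(s, "a:1\\.000000")
  expect_match(s, "b:1\\.000000")
  expect_match(s, "c:3\\.000000")

  tr <- nj_tree(D)
  tr$tip.label[1] <- "taxon one (A)"
  s2 <- write_newick(tr)
  expect_match(s2, "'taxon one \\(A\\)'", fixed = FALSE)
  back <- read_newick(s2)
  expect_true("taxon one (A)" %in% back$tip.label)
})

test_that("Newick round trip preserves topology and branch lengths", {
  set.seed(55)
  tr <- ape::rtree(10)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(round(tr$edge.length, 6)),
               tolerance = 1e-9)
  expect_setequal(back$tip.label, tr$tip.label)
})

test_that("malformed Newick is rejected with a position", {
  expect_error(read_newick("((a:1,b:2):1,c:1;"), "unclosed")
  expect_error(read_newick("(a:1,b:2)):1;"), "position")
  expect_error(read_newick("(a:1,b:2)"), "';'")
})
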