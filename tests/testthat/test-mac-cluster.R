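test_that("Heron areas match closed forms and clamp non-metric triples", {
  expect_equal(as.numeric(heron_area(1, 1, 1)), sqrt(3) / 4)
  expect_equal(as.numeric(heron_area(3, 4, 5)), 6)
  expect_equal(as.numeric(heron_area(2, 1, 1)), 0)  # collinear
  a <- heron_area(3, 1, 1)              # violates triangle inequality
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "nonmetric"))
  expect_error(heron_area(-1, 1, 1), "non-negative")
})

test_that("triangle filtering drops edges living only in outlier triangles", {
  m <- two_pair_matrix(within = 0.1, across = 0.9)
  # brute-force expectation: 4 triangles, each has two long sides and one
  # short side; the filter at sigma = 1 can only drop edges if some
  # triangle area exceeds mean + sd
  tri <- combn(4, 3)
  areas <- apply(tri, 2, function(ix) {
    heron_area(m[ix[1], ix[2]], m[ix[2], ix[3]], m[ix[3], ix[1]])
  })
  expect_equal(length(unique(round(areas, 12))), 1L)  # all congruent
  # congruent triangles: zero variance, nothing dropped
  G <- triangle_filter(m, sigma_filter = 1)
  expect_true(all(G[upper.tri(G)]))

  # an asymmetric configuration: 5th point far away makes deformed
  # triangles; its edges must only survive via non-outlier triangles
  labs <- letters[1:5]
  m5 <- matrix(0.9, 5, 5, dimnames = list(labs, labs))
  m5["a", "b"] <- m5["b", "a"] <- 0.1
  m5["c", "d"] <- m5["d", "c"] <- 0.1
  m5[, "e"] <- m5["e", ] <- 3
  diag(m5) <- 0
  G5 <- triangle_filter(m5, sigma_filter = 1)
  # brute-force oracle over all 10 triangles
  tri5 <- combn(5, 3)
  areas5 <- apply(tri5, 2, function(ix) {
    heron_area(m5[ix[1], ix[2]], m5[ix[2], ix[3]], m5[ix[3], ix[1]])
  })
  keep <- areas5 <= mean(areas5) + sd(areas5)
  expected <- matrix(FALSE, 5, 5, dimnames = list(labs, labs))
  for (t in which(keep)) {
    ix <- tri5[, t]
    expected[ix[1], ix[2]] <- expected[ix[2], ix[1]] <- TRUE
    expected[ix[2], ix[3]] <- expected[ix[3], ix[2]] <- TRUE
    expected[ix[3], ix[1]] <- expected[ix[1], ix[3]] <- TRUE
  }
  expect_identical(unclass(G5)[labs, labs], expected,
                   ignore_attr = TRUE)
  expect_equal(G5[labs, labs], expected, ignore_attr = TRUE)

  expect_warning(G2 <- triangle_filter(two_pair_matrix()[1:2, 1:2]),
                 "fewer than 3")
  expect_true(G2["a", "b"])

  # sigma -> infinity retains the complete graph
  Ginf <- triangle_filter(m5, sigma_filter = 1e9)
  expect_true(all(Ginf[upper.tri(Ginf)]))
})

test_that("mutual-kNN pruning keeps every node's nearest edge", {
  # chain of 3 equidistant nodes: both chain edges survive with knn = 1
  labs <- c("a", "b", "c")
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(labs, labs))
  G <- matrix(TRUE, 3, 3, dimnames = list(labs, labs))
  diag(G) <- FALSE
  P <- first_of_first_prune(G, m, knn = 1)
  expect_true(P["a", "b"] && P["b", "c"])
  expect_false(P["a", "c"])

  # two tight pairs: exactly the within-pair edges remain
  m4 <- two_pair_matrix()
  G4 <- triangle_filter(m4, 1)
  P4 <- first_of_first_prune(G4, m4, knn = 1)
  expect_true(P4["a", "b"] && P4["c", "d"])
  expect_equal(sum(P4), 4)  # two undirected edges

  # knn >= n-1 keeps the graph unchanged
  P_all <- first_of_first_prune(G4, m4, knn = 3)
  expect_identical(unname(P_all), unname(G4 & TRUE))
})

test_that("local minima partitioning splits dumbbells but not centred blobs", {
  # single clear centre: unchanged
  labs <- c("a", "b", "c")
  m <- matrix(c(0, 1, 1, 1, 0, 1.5, 1, 1.5, 0), 3, 3,
              dimnames = list(labs, labs))
  G <- matrix(TRUE, 3, 3, dimnames = list(labs, labs)); diag(G) <- FALSE
  parts <- local_minima_partition(G, m)
  expect_equal(parts, list(c("a", "b", "c")))

  # dumbbell: two tight centred triangles joined by one long bridge edge;
  # a1 and b1 are the blob centres and become the two local minima
  labs <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m6 <- matrix(1, 6, 6, dimnames = list(labs, labs))
  m6["a1", "a2"] <- m6["a1", "a3"] <- 0.1
  m6["a2", "a3"] <- 0.3
  m6["b1", "b2"] <- m6["b1", "b3"] <- 0.1
  m6["b2", "b3"] <- 0.3
  m6[lower.tri(m6)] <- t(m6)[lower.tri(m6)]
  diag(m6) <- 0
  G6 <- matrix(FALSE, 6, 6, dimnames = list(labs, labs))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    G6[e[1], e[2]] <- G6[e[2], e[1]] <- TRUE
  }
  # brute-force oracle: component means, strict minima, shortest paths
  means <- sapply(labs, function(u) mean(m6[u, setdiff(labs, u)]))
  expect_setequal(labs[sapply(labs, function(u) {
    nb <- labs[G6[u, ]]
    !any(means[nb] < means[u])
  })], c("a1", "b1"))
  parts6 <- local_minima_partition(G6, m6)
  expect_equal(parts6, list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  # singleton component maps to itself
  G1 <- matrix(FALSE, 1, 1, dimnames = list("x", "x"))
  m1 <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_equal(local_minima_partition(G1, m1), list("x"))
})

test_that("representative multisets pool exact and near ties", {
  labs <- c("a", "b", "c")
  m <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
              dimnames = list(labs, labs))
  expect_equal(best_representative(labs, m), "a")  # strict medoid

  m2 <- two_pair_matrix()
  expect_equal(best_representative(c("a", "b"), m2), c("a", "b"))  # tie

  # near-tied medoids pooled when tie_tol spans the gap
  labs5 <- paste0("p", 1:5)
  m5 <- matrix(1, 5, 5, dimnames = list(labs5, labs5))
  diag(m5) <- 0
  m5["p1", "p3"] <- m5["p3", "p1"] <- 0.5
  m5["p2", "p4"] <- m5["p4", "p2"] <- 0.5 + 1e-12
  sums <- rowSums(m5)
  expect_equal(best_representative(labs5, m5, tie_tol = 1e-9),
               c("p1", "p2", "p3", "p4"))
  expect_equal(best_representative(labs5, m5, tie_tol = 0),
               c("p1", "p3"))
})

test_that("forward pass recovers planted structure stage by stage", {
  C <- forward_pass(two_pair_matrix())
  expect_equal(lapply(C$clusters, `[[`, "members"),
               list(c("a", "b"), c("c", "d")))
  expect_equal(C$singletons, character(0))

  # all mutually equidistant: one cluster holding everything
  labs <- paste0("e", 1:5)
  meq <- matrix(0.7, 5, 5, dimnames = list(labs, labs)); diag(meq) <- 0
  Ceq <- forward_pass(meq)
  expect_equal(length(Ceq$clusters), 1L)
  expect_equal(Ceq$clusters[[1]]$members, labs)

  # far outlier next to a tight cluster: its edges only ever appear in
  # deformed (outlier) triangles, so it ends up a singleton
  labs <- c("t1", "t2", "t3", "t4", "out")
  mo <- matrix(0.1, 5, 5, dimnames = list(labs, labs))
  mo[, "out"] <- mo["out", ] <- 5
  diag(mo) <- 0
  Co <- forward_pass(mo, mac_params(sigma_filter = 0.5))
  expect_equal(length(Co$clusters), 1L)
  expect_equal(Co$clusters[[1]]$members, c("t1", "t2", "t3", "t4"))
  expect_equal(Co$singletons, "out")

  expect_error(forward_pass(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
})

test_that("clusters and singletons always partition the label set", {
  set.seed(303)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    labs <- paste0("n", seq_len(n))
    m <- matrix(runif(n * n), n, n, dimnames = list(labs, labs))
    m <- (m + t(m)) / 2; diag(m) <- 0
    C <- suppressWarnings(mac_cluster(m))
    got <- sort(c(unlist(lapply(C$clusters, `[[`, "members")),
                  C$singletons))
    expect_equal(got, labs[order(labs)])
  }
})

test_that("clustering is deterministic and permutation-equivariant", {
  set.seed(99)
  n <- 9
  labs <- paste0("q", 1:n)
  m <- matrix(runif(n * n), n, n, dimnames = list(labs, labs))
  m <- (m + t(m)) / 2; diag(m) <- 0
  C1 <- suppressWarnings(mac_cluster(m))
  C2 <- suppressWarnings(mac_cluster(m))
  expect_identical(C1, C2)
  perm <- sample(n)
  C3 <- suppressWarnings(mac_cluster(m[perm, perm]))
  expect_identical(cluster_assignments(C1), cluster_assignments(C3))
})

test_that("clustering is invariant under global rescaling of distances", {
  m <- two_pair_matrix()
  C1 <- mac_cluster(m)
  C2 <- mac_cluster(m * 37.5)
  expect_identical(lapply(C1$clusters, `[[`, "members"),
                   lapply(C2$clusters, `[[`, "members"))
  expect_identical(C1$singletons, C2$singletons)
})

test_that("auto-correction dissolves overgrown multisets", {
  m <- two_pair_matrix()
  C <- forward_pass(m)
  # no cluster over threshold: fixpoint
  expect_identical(auto_correct(C, m)$clusters, C$clusters)

  # multiset_max = 1 dissolves the exact-tie pair clusters; with no
  # survivors their members fall back to singletons
  C1 <- auto_correct(C, m, mac_params(multiset_max = 1))
  expect_equal(length(C1$clusters), 0L)
  expect_equal(C1$singletons, c("a", "b", "c", "d"))
  expect_gt(length(C1$cycles), length(C$cycles))

  # a diffuse tied cluster redistributes into surviving tight clusters
  labs <- c("a", "b", "c", "d", "x", "y")
  m6 <- matrix(0.9, 6, 6, dimnames = list(labs, labs))
  m6["a", "b"] <- m6["b", "a"] <- 0.05
  m6["c", "d"] <- m6["d", "c"] <- 0.05
  m6["x", "y"] <- m6["y", "x"] <- 0.4
  m6["x", "a"] <- m6["a", "x"] <- 0.5
  m6["y", "c"] <- m6["c", "y"] <- 0.5
  diag(m6) <- 0
  C6 <- structure(list(
    clusters = list(
      list(members = c("a", "b"), representatives = c("a", "b"),
           mean_radius = 0.025),
      list(members = c("c", "d"), representatives = c("c", "d"),
           mean_radius = 0.025),
      list(members = c("x", "y"), representatives = c("x", "y"),
           mean_radius = 0.2)),
    singletons = character(0), cycles = list()), class = "mac_clustering")
  C6b <- auto_correct(C6, m6, mac_params(multiset_max = 2))
  expect_identical(C6b$clusters, C6$clusters)  # all within threshold
})

test_that("newick export produces valid trees with expected topology", {
  m <- two_pair_matrix()
  C <- forward_pass(m)
  nwk <- clusters_to_newick(C, m)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), c("a", "b", "c", "d"))
  # the two pairs must be sister cherries
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("a", "b")))

  # single cluster of 3: internal average-linkage heights
  labs <- c("a", "b", "c")
  m3 <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.9, 0.8, 0.9, 0), 3, 3,
               dimnames = list(labs, labs))
  C3 <- structure(list(
    clusters = list(list(members = labs, representatives = "a",
                         mean_radius = 0.3)),
    singletons = character(0), cycles = list()), class = "mac_clustering")
  t3 <- ape::read.tree(text = clusters_to_newick(C3, m3))
  expect_true(ape::is.monophyletic(t3, c("a", "b")))

  # singleton-only clustering collapses to a single leaf
  C1 <- structure(list(clusters = list(), singletons = "only",
                       cycles = list()), class = "mac_clustering")
  m1 <- matrix(0, 1, 1, dimnames = list("only", "only"))
  expect_equal(clusters_to_newick(C1, m1), "only;")
})
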