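# Forbidden catalog, recognition, root reconstruction, allele assignments.

test_that("catalog members are minimal non-line graphs (claw first)", {
  cat9 <- forbidden_catalog()
  expect_length(cat9, 9)
  claw <- igraph::make_star(4, mode = "undirected")
  expect_true(igraph::isomorphic(cat9[[1]], claw))
  for (f in cat9) {
    expect_false(is_line_graph(f, method = "krausz"))
    for (v in seq_len(igraph::vcount(f))) {
      expect_true(is_line_graph(igraph::delete_vertices(f, v),
                                method = "krausz"))
    }
  }
  expect_equal(anyDuplicated(vapply(cat9, function(g)
    paste(igraph::vcount(g), igraph::ecount(g),
          paste(igraph::degree(g)[order(igraph::degree(g))], collapse = ",")),
    "")), 0)
})

test_that("even/odd triangle classification counts outside neighbors", {
  k3 <- graph_from_pairs(3, c(1,2, 1,3, 2,3))
  expect_true(is_even_triangle(k3, c("1", "2", "3")))
  g <- graph_from_pairs(4, c(1,2, 1,3, 2,3, 1,4))   # node 4 sees 1 corner
  expect_false(is_even_triangle(g, c("1", "2", "3")))
  g2 <- graph_from_pairs(4, c(1,2, 1,3, 2,3, 1,4, 2,4)) # node 4 sees 2 corners
  expect_true(is_even_triangle(g2, c("1", "2", "3")))
  expect_error(is_even_triangle(g, c("1", "2", "4")), "triangle")
  set.seed(21)
  for (i in 1:20) {
    g <- rand_graph(7, 0.5)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    tri <- which(A == 1, arr.ind = TRUE)
    tris <- utils::combn(7, 3, simplify = FALSE)
    for (t3 in tris) {
      if (!(A[t3[1], t3[2]] && A[t3[1], t3[3]] && A[t3[2], t3[3]])) next
      outside <- setdiff(1:7, t3)
      want <- all(rowSums(A[outside, t3, drop = FALSE]) %in% c(0, 2))
      expect_equal(is_even_triangle(g, as.character(t3)), want)
    }
  }
})

test_that("known small graphs are recognised correctly by both methods", {
  claw <- named_graph(igraph::make_star(4, mode = "undirected"))
  k3 <- named_graph(igraph::make_full_graph(3))
  for (method in c("catalog", "krausz")) {
    expect_false(is_line_graph(claw, method = method))
    expect_true(is_line_graph(k3, method = method))
  }
})

test_that("forbidden occurrences are exhaustive and deduplicated", {
  claw <- named_graph(igraph::make_star(4, mode = "undirected"))
  occ <- find_forbidden_occurrences(claw)
  expect_length(occ, 1)
  expect_setequal(occ[[1]], as.character(1:4))
  expect_length(find_forbidden_occurrences(named_graph(igraph::make_full_graph(3))), 0)
  k14 <- named_graph(igraph::make_star(5, mode = "undirected"))
  occ4 <- find_forbidden_occurrences(k14)
  expect_length(occ4, 4)   # center plus each leaf triple
  expect_true(all(vapply(occ4, function(s) "1" %in% s, logical(1))))
  # brute-force cross-check on a random graph: every 4-subset inducing a claw
  set.seed(5)
  g <- rand_graph(8, 0.35)
  occ <- find_forbidden_occurrences(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  claw_sets <- Filter(function(s) {
    sub <- A[s, s]
    any(vapply(1:4, function(c) {
      leaves <- setdiff(1:4, c)
      all(sub[c, leaves] == 1) && all(sub[leaves, leaves][upper.tri(diag(3))] == 0)
    }, logical(1)))
  }, utils::combn(8, 4, simplify = FALSE))
  keys <- vapply(occ, function(s) paste(sort(s), collapse = ","), "")
  for (s in claw_sets)
    expect_true(paste(sort(as.character(s)), collapse = ",") %in% keys)
})

test_that("root reconstruction inverts line-graph construction (round trip)", {
  # fixed cases
  p3 <- graph_from_pairs(3, c(1,2, 2,3))
  expect_equal(reconstruct_root(p3)$n_haplotypes, 4)     # root is P4
  iso <- graph_from_pairs(1, integer(0))
  r <- reconstruct_root(iso)
  expect_equal(r$n_haplotypes, 2)
  expect_equal(igraph::ecount(r$root), 1)
  k3 <- graph_from_pairs(3, c(1,2, 1,3, 2,3))
  expect_equal(reconstruct_root(k3)$n_haplotypes, 3)     # ambiguous case: K3 root
  expect_error(reconstruct_root(named_graph(igraph::make_star(4, mode = "undirected"))),
               "forbidden")
  # property: reconstruct_root(L(G)) isomorphic to G (isolated nodes of G
  # dropped; K3 components of L(G) excepted)
  set.seed(31)
  tried <- 0
  while (tried < 200) {
    n <- sample(2:8, 1)
    g <- rand_graph(n, stats::runif(1, 0.25, 0.8))
    lg <- line_of(g)
    if (igraph::vcount(lg) == 0) next
    tried <- tried + 1
    has_k3_comp <- any(vapply(igraph::decompose(lg), function(cmp)
      igraph::vcount(cmp) == 3 && igraph::ecount(cmp) == 3, logical(1)))
    r <- reconstruct_root(lg)
    expect_true(igraph::isomorphic(line_of(r$root), lg))
    if (!has_k3_comp) {
      g_clean <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
      expect_true(igraph::isomorphic(r$root, g_clean))
    }
  }
})

test_that("catalog scan and Krausz reconstruction agree on random graphs", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:300) {
    n <- sample(3:7, 1)
    g <- rand_graph(n, stats::runif(1, 0.2, 0.9))
    expect_equal(is_line_graph(g, "catalog"), is_line_graph(g, "krausz"),
                 info = paste("graph", i))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 300)
})

test_that("node deletion never creates new forbidden occurrences (hereditary)", {
  set.seed(51)
  for (i in 1:25) {
    g <- rand_graph(7, 0.45)
    occ <- find_forbidden_occurrences(g)
    v <- sample(igraph::V(g)$name, 1)
    occ_after <- find_forbidden_occurrences(igraph::delete_vertices(g, v))
    keys_before <- vapply(occ, paste, "", collapse = ",")
    for (s in occ_after)
      expect_true(paste(s, collapse = ",") %in% keys_before)
  }
})

test_that("allele assignments from roots verify and count haplotypes", {
  # single isolated genotype: two fresh colors
  iso <- graph_from_pairs(1, integer(0))
  a <- allele_assignment_from_root(reconstruct_root(iso))
  expect_length(a[["1"]], 2)
  expect_equal(count_haplotypes(a), 2)
  # P3: root P4, middle genotype shares one color with each neighbor
  p3 <- graph_from_pairs(3, c(1,2, 2,3))
  a3 <- allele_assignment_from_root(reconstruct_root(p3))
  expect_equal(count_haplotypes(a3), 4)
  expect_length(intersect(a3[["1"]], a3[["2"]]), 1)
  expect_length(intersect(a3[["2"]], a3[["3"]]), 1)
  expect_length(intersect(a3[["1"]], a3[["3"]]), 0)
  expect_true(verify_allelable(p3, a3))
  # n isolated genotypes use 2n colors
  g5 <- graph_from_pairs(5, integer(0))
  expect_equal(count_haplotypes(allele_assignment_from_root(reconstruct_root(g5))), 10)
  # single shared edge: 3 haplotypes
  e1 <- graph_from_pairs(2, c(1, 2))
  expect_equal(count_haplotypes(allele_assignment_from_root(reconstruct_root(e1))), 3)
  # by construction, every root-derived assignment verifies
  set.seed(61)
  for (i in 1:30) {
    g <- rand_graph(sample(2:7, 1), 0.5)
    lg <- line_of(g)
    if (igraph::vcount(lg) == 0) next
    expect_true(verify_allelable(lg,
      allele_assignment_from_root(reconstruct_root(lg))))
  }
})

test_that("verify_allelable rejects broken assignments", {
  k3 <- graph_from_pairs(3, c(1,2, 1,3, 2,3))
  good <- list(`1` = c(1L, 2L), `2` = c(2L, 3L), `3` = c(1L, 3L))
  expect_true(verify_allelable(k3, good))
  two_shared <- list(`1` = c(1L, 2L), `2` = c(1L, 2L), `3` = c(1L, 3L))
  expect_false(verify_allelable(k3, two_shared))
  p2 <- graph_from_pairs(3, c(1, 2))
  nonadj_shared <- list(`1` = c(1L, 2L), `2` = c(2L, 3L), `3` = c(3L, 4L))
  expect_false(verify_allelable(p2, nonadj_shared))
  expect_error(verify_allelable(k3, good[1:2]), "missing")
})
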