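# Seeding, extension, cut generation and the full phasing loop.

# verify a phasing result against the genotypes at all fixed sites
phasing_sound <- function(ph, m) {
  for (id in names(ph$pairs)) {
    hp <- ph$haplotypes[ph$pairs[[id]]]
    h1 <- strsplit(hp[1], "")[[1]]
    h2 <- strsplit(hp[2], "")[[1]]
    gg <- unclass(m)[id, ]
    for (s in seq_along(gg)) {
      if (is.na(gg[s])) next
      a1 <- h1[s]; a2 <- h2[s]
      if (a1 == "?" || a2 == "?") next
      if (as.integer(a1) + as.integer(a2) != gg[s]) return(FALSE)
    }
  }
  TRUE
}

test_that("seeding fixes the shared haplotype at homozygous sites", {
  m <- genotype_matrix(rbind(g1 = c(0L, 1L), g2 = c(1L, 1L)))
  st <- seed_set(c("g1", "g2"), m)
  p <- st$haps[[intersect(st$node_haps[["g1"]], st$node_haps[["g2"]])]]
  expect_equal(p[1], 0L)        # forced by g1's homozygote
  expect_true(is.na(p[2]))
  # g1's private haplotype complements at its heterozygous fixed sites
  o1 <- st$haps[[setdiff(st$node_haps[["g1"]], st$node_haps[["g2"]])]]
  expect_equal(o1[1], 0L)
  m2 <- genotype_matrix(rbind(g1 = c(1L, 1L), g2 = c(1L, 1L)))
  st2 <- seed_set(c("g1", "g2"), m2)
  shared2 <- intersect(st2$node_haps[["g1"]], st2$node_haps[["g2"]])
  expect_true(all(is.na(st2$haps[[shared2]])))
  m3 <- genotype_matrix(rbind(g1 = c(0L, 1L), g2 = c(0L, 1L)))
  st3 <- seed_set(c("g1", "g2"), m3)
  expect_true(all(vapply(st3$haps, function(h) h[1] == 0L, logical(1))))
  m4 <- genotype_matrix(rbind(g1 = c(0L, 1L), g2 = c(2L, 1L)))
  expect_error(seed_set(c("g1", "g2"), m4), "consistent")
})

test_that("extension detects contradictions and returns a cut witness", {
  # C4 sharing cycle whose simultaneous sharings are unphasable:
  # g4 closes the cycle but is homozygous-ref where both candidate shared
  # haplotypes are already fixed to the alternate allele
  m <- genotype_matrix(rbind(
    g1 = c(1L, 1L, 0L, 1L),
    g2 = c(1L, 0L, 1L, 0L),
    g3 = c(1L, 1L, 2L, 1L),
    g4 = c(1L, 0L, 1L, 2L)))
  g <- build_cc_graph(m)
  expect_equal(igraph::ecount(g), 4)           # exactly the 4-cycle
  expect_false(igraph::are_adjacent(g, "g1", "g3"))
  expect_false(igraph::are_adjacent(g, "g2", "g4"))
  I <- igraph::as_edgelist(g)
  st <- seed_set(c("g1", "g2"), m)
  r3 <- extend(st, "g3", I, m)
  expect_true(r3$ok)
  r4 <- extend(r3$state, "g4", I, m)
  expect_false(r4$ok)
  expect_equal(nrow(r4$witness), 4)            # all cycle edges implicated
  cut <- generate_cut(r4$state, I)
  expect_equal(nrow(cut), 4)
  # the cut tightens the parsimony program: objective cannot decrease
  base <- solve_min_haplotypes(g)
  cutted <- solve_min_haplotypes(g, cuts = list(cut))
  expect_gte(cutted$objective, base$objective)
  expect_lt(nrow(cutted$sharing), 4)           # incumbent sharing outlawed
})

test_that("an all-heterozygous node always extends", {
  m <- genotype_matrix(rbind(g1 = c(0L, 1L, 1L),
                             g2 = c(1L, 0L, 1L),
                             g3 = c(1L, 1L, 1L)))
  I <- rbind(c("g1", "g2"), c("g2", "g3"))
  st <- seed_set(c("g1", "g2"), m)
  r <- extend(st, "g3", I, m)
  expect_true(r$ok)
})

test_that("phasing recovers known haplotypes exactly when sharings are unique", {
  haps <- rbind(h1 = c(1L, 0L, 0L, 0L, 0L),
                h2 = c(0L, 1L, 0L, 0L, 0L),
                h3 = c(0L, 0L, 1L, 0L, 1L),
                h4 = c(0L, 0L, 0L, 1L, 1L))
  m <- geno_from_haps(haps, list(c(1, 2), c(2, 3), c(3, 4)))
  g <- build_cc_graph(m)
  expect_equal(igraph::ecount(g), 2)           # the sharing path, no extras
  ph <- phase(m, seed = 1)
  expect_equal(ph$status, "complete")
  expect_equal(ph$n_haplotypes, 4)
  expect_equal(ph$cuts, 0)
  expect_setequal(unname(ph$haplotypes),
                  apply(haps, 1, paste, collapse = ""))
  expect_true(phasing_sound(ph, m))
})

test_that("a single genotype phases into two haplotypes with unknown het sites", {
  m <- genotype_matrix(rbind(g1 = c(0L, 1L, 2L, 1L)))
  ph <- phase(m)
  expect_equal(ph$status, "complete")
  expect_equal(ph$n_haplotypes, 2)
  expect_equal(unname(ph$haplotypes), c("0?1?", "0?1?"))
})

test_that("the constraint-generation loop cuts its way out of unphasable sharings", {
  m <- genotype_matrix(rbind(
    g1 = c(1L, 1L, 0L, 1L),
    g2 = c(1L, 0L, 1L, 0L),
    g3 = c(1L, 1L, 2L, 1L),
    g4 = c(1L, 0L, 1L, 2L)))
  first <- solve_min_haplotypes(build_cc_graph(m))
  ph <- phase(m, seed = 1)
  expect_equal(ph$status, "complete")
  expect_gte(ph$cuts, 1)
  expect_gte(ph$rounds, 2)
  expect_true(phasing_sound(ph, m))
  expect_gte(ph$n_haplotypes, first$count)     # cuts only tighten
  expect_gte(ph$n_haplotypes, brute_min_phasing_haplotypes(m))
})

test_that("phasing is sound on random instances built from known haplotypes", {
  set.seed(113)
  for (i in 1:6) {
    nh <- sample(3:6, 1)
    haps <- matrix(sample(0:1, nh * 12, replace = TRUE), nh, 12)
    haps <- haps[!duplicated(haps), , drop = FALSE]
    if (nrow(haps) < 2) next
    pairing <- lapply(1:5, function(j) sample(nrow(haps), 2))
    m <- geno_from_haps(haps, pairing)
    m <- preprocess_genotypes(m)$matrix
    ph <- phase(m, seed = 1)
    expect_true(ph$status %in% c("complete", "max_rounds_reached"))
    expect_true(phasing_sound(ph, m))
    expect_lte(ph$n_haplotypes, 2 * nrow(m))
  }
})
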