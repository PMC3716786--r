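# Simulators for the two validation scenarios, with ground truth. Genotype
# codes are the site-wise sum of the two binary haplotypes, so a genotype
# is 0/2 where both haplotypes agree and 1 where they differ.

new_ground_truth <- function(pool, pairing, ids, genotypes) {
  hap_str <- apply(pool, 1, paste, collapse = "")
  used <- sort(unique(as.vector(pairing)))
  # sharing edges: genotypes whose haplotype index sets intersect
  edges <- list()
  for (h in used) {
    who <- which(pairing[, 1] == h | pairing[, 2] == h)
    if (length(who) > 1) {
      prs <- t(utils::combn(who, 2))
      edges[[length(edges) + 1L]] <- cbind(ids[prs[, 1]], ids[prs[, 2]])
    }
  }
  edges <- unique(do.call(rbind, edges) %||% matrix(character(0), 0, 2))
  structure(list(haplotype_pool = hap_str,
                 pairing = `rownames<-`(pairing, ids),
                 true_count = length(used),
                 true_sharing_edges = edges,
                 genotypes = genotypes),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", nrow(x$pairing), "genotypes drawn from",
      length(x$haplotype_pool), "pool haplotypes;",
      x$true_count, "distinct sampled;",
      nrow(x$true_sharing_edges), "true sharing pairs\n")
  invisible(x)
}

# Sites for one neutral no-recombination genealogy: placed on an rcoal
# tree with probability proportional to branch length and carried by the
# clade below, giving the coalescent allele frequency spectrum.
coalescent_tree_sites <- function(k, n_sites) {
  tree <- ape::rcoal(k)
  desc <- ape::prop.part(tree)   # tip sets of the clades below internal nodes
  attr(desc, "labels") <- NULL
  tips_below <- lapply(seq_len(nrow(tree$edge)), function(i) {
    node <- tree$edge[i, 2]
    if (node <= k) node else desc[[node - k]]
  })
  site_edge <- sample(nrow(tree$edge), n_sites, replace = TRUE,
                      prob = tree$edge.length)
  pool <- matrix(0L, k, n_sites)
  for (s in seq_len(n_sites)) pool[tips_below[[site_edge[s]]], s] <- 1L
  # rcoal tip indices follow the tree shape (low indices cluster together);
  # relabel uniformly so haplotype ids are exchangeable
  pool[sample.int(k), , drop = FALSE]
}

# k distinct ancestral haplotypes over a long (multi-cM) locus. Ancestral
# recombination decorrelates markers along such a region, so sites are
# drawn from an independent genealogy per block of `block_sites` markers
# (a single shared tree would leave most random pairs consistent by state,
# which is not what long multi-block haplotypes do). Sampled individuals
# still inherit whole pool haplotypes: present-day sharing is strictly
# identity by descent. One private marker per haplotype guarantees the
# pool is distinct.
coalescent_pool <- function(k, n_sites, seed, block_sites = 10L,
                            distinct = TRUE) {
  set.seed(seed)
  if (distinct && n_sites < k)
    stop("need at least k sites for k distinct haplotypes")
  n_free <- if (distinct) n_sites - k else n_sites
  blocks <- list()
  left <- n_free
  while (left > 0L) {
    b <- min(block_sites, left)
    blocks[[length(blocks) + 1L]] <- coalescent_tree_sites(k, b)
    left <- left - b
  }
  pool <- do.call(cbind, blocks) %||% matrix(0L, k, 0)
  if (distinct) {
    priv <- matrix(0L, k, k)
    diag(priv) <- 1L
    pool <- cbind(pool, priv)[, sample.int(n_sites), drop = FALSE]
  }
  pool
}

#' Simulate a bottleneck population sample
#'
#' An ancestral pool of `k` distinct haplotypes (neutral genealogy, no
#' recombination: long-range sharing is identity by descent only) is
#' sampled with replacement into genotype pairs; pairs drawing the same
#' haplotype twice are redrawn, enforcing the assumption that every
#' individual is heterozygous somewhere. Coverage, in the sense of the
#' expected number of times each ancestral haplotype is sampled, is
#' `2 * n_genotypes / k`.
#'
#' @param k ancestral pool size (number of haplotypes, >= 2).
#' @param n_genotypes sample size.
#' @param n_sites markers per haplotype (default 3000, a long region over
#'   which no recombination is assumed).
#' @param seed integer; fixed seed gives identical output.
#' @return list with `genotypes` (a `genotype_matrix`) and `truth`
#'   (a `ground_truth`).
#' @export
simulate_bottleneck <- function(k, n_genotypes, n_sites = 3000L, seed = 1L) {
  if (k < 2) stop("need an ancestral pool of at least 2 haplotypes")
  pool <- coalescent_pool(k, n_sites, seed)
  pairs <- matrix(sample.int(k, 2L * n_genotypes, replace = TRUE),
                  ncol = 2L)
  same <- pairs[, 1] == pairs[, 2]
  while (any(same)) {
    pairs[same, 2] <- sample.int(k, sum(same), replace = TRUE)
    same <- pairs[, 1] == pairs[, 2]
  }
  ids <- sprintf("g%03d", seq_len(n_genotypes))
  calls <- pool[pairs[, 1], , drop = FALSE] + pool[pairs[, 2], , drop = FALSE]
  rownames(calls) <- ids
  colnames(calls) <- sprintf("s%04d", seq_len(n_sites))
  gm <- genotype_matrix(calls)
  list(genotypes = gm, truth = new_ground_truth(pool, pairs, ids, gm))
}

# ---- recombinant scenario ---------------------------------------------------

# n_hap haplotypes from a recombining coalescent with pairwise diversity
# 4*N0*mu*L (haploid samples, population size 2*N0 under ploidy-1 scaling)
msprime_haplotypes <- function(n_hap, N0, region_bp, mutation_rate,
                               recombination_rate, seed) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("python not found; use engine = 'windows'")
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".txt")
  writeLines(c(
    "import sys, msprime",
    "n, N0, L, mu, r, seed, out = sys.argv[1:8]",
    "ts = msprime.sim_ancestry(samples=int(n), ploidy=1,",
    "    population_size=2 * float(N0), sequence_length=float(L),",
    "    recombination_rate=float(r), random_seed=int(seed))",
    "mts = msprime.sim_mutations(ts, rate=float(mu), random_seed=int(seed)+1,",
    "    model=msprime.BinaryMutationModel())",
    "G = mts.genotype_matrix()",
    "keep = [i for i in range(G.shape[0]) if 0 < (G[i] != 0).sum() < G.shape[1]]",
    "with open(out, 'w') as fh:",
    "    fh.write(str(len(keep)) + '\\n')",
    "    pos = [int(v.site.position) for i, v in enumerate(mts.variants()) if i in set(keep)]",
    "    fh.write(' '.join(map(str, pos)) + '\\n')",
    "    for s in range(G.shape[1]):",
    "        fh.write(''.join('1' if G[i, s] != 0 else '0' for i in keep) + '\\n')"
  ), script)
  on.exit(unlink(c(script, out)), add = TRUE)
  res <- system2(py, c(script, n_hap, N0, region_bp, mutation_rate,
                       recombination_rate, seed, out),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(out) || length(readLines(out, n = 1)) == 0)
    stop("msprime simulation failed:\n", paste(res, collapse = "\n"))
  lines <- readLines(out)
  S <- as.integer(lines[1])
  if (S == 0L) return(NULL)
  H <- do.call(rbind, lapply(lines[-(1:2)], function(x)
    as.integer(strsplit(x, "")[[1]])))
  list(H = H, positions = as.numeric(strsplit(lines[2], " ")[[1]]))
}

# crude offline fallback: the region is cut into windows, each window gets
# an independent no-recombination genealogy (over-dispersing recombination),
# with mutations Poisson-distributed at the coalescent expectation.
windows_haplotypes <- function(n_hap, N0, region_bp, mutation_rate,
                               recombination_rate, seed) {
  set.seed(seed)
  ns <- as.integer(n_hap)
  a <- sum(1 / seq_len(ns - 1L))
  W <- max(1L, min(100L, stats::rpois(1, 4 * N0 * recombination_rate *
                                         region_bp * a / 10)))
  theta_w <- 4 * N0 * mutation_rate * region_bp / W
  H <- NULL
  for (w in seq_len(W)) {
    Sw <- stats::rpois(1, theta_w * a)
    if (Sw == 0) next
    H <- cbind(H, coalescent_pool(ns, Sw, seed + w, block_sites = Sw,
                                  distinct = FALSE))
  }
  if (is.null(H)) return(NULL)
  list(H = H, positions = seq_len(ncol(H)))
}

#' Simulate a recombinant population sample
#'
#' `2 * n_genotypes` haplotypes are drawn from a coalescent with
#' recombination over `region_bp` base pairs (ancestral population size
#' `N0`, pairwise diversity `4 N0 mu L`) and paired sequentially into
#' genotypes. Haplotypes in this scenario are not all distinct: recently
#' related samples carry identical marker haplotypes, so true sharing is
#' defined on sequences - two genotypes share iff they carry an identical
#' marker haplotype - and the true haplotype count is the number of
#' distinct sequences sampled. The default engine delegates to msprime;
#' `"windows"` is a built-in approximation that draws an independent
#' genealogy per recombination window.
#'
#' @param N0 ancestral (effective, diploid-scaled) population size.
#' @param n_genotypes number of individuals sampled.
#' @param region_bp region length in bp (default 1 Mb).
#' @param mutation_rate per-bp per-generation (default 1e-8).
#' @param recombination_rate per-bp per-generation (default 1e-7).
#' @param seed integer seed; determinism per engine.
#' @param engine `"msprime"` (default) or `"windows"`.
#' @param max_retries extra attempts if a draw has no segregating site.
#' @return list with `genotypes` and `truth` as in [simulate_bottleneck()].
#' @export
simulate_recombinant <- function(N0, n_genotypes, region_bp = 1e6,
                                 mutation_rate = 1e-8,
                                 recombination_rate = 1e-7,
                                 seed = 1L,
                                 engine = c("msprime", "windows"),
                                 max_retries = 5L) {
  engine <- match.arg(engine)
  fun <- switch(engine, msprime = msprime_haplotypes,
                windows = windows_haplotypes)
  hs <- NULL
  for (att in 0:max_retries) {
    hs <- fun(2L * n_genotypes, N0, region_bp, mutation_rate,
              recombination_rate, seed + 7919L * att)
    if (!is.null(hs)) break
    warning("no segregating sites; retrying with a shifted seed")
  }
  if (is.null(hs)) stop("no segregating sites after ", max_retries, " retries")
  # collapse identical-by-state rows; sequence identity defines sharing
  key <- apply(hs$H, 1, paste, collapse = "")
  pool_keys <- unique(key)
  pool <- hs$H[match(pool_keys, key), , drop = FALSE]
  hap_idx <- match(key, pool_keys)
  pairs <- cbind(hap_idx[seq(1, length(hap_idx), 2)],
                 hap_idx[seq(2, length(hap_idx), 2)])
  ids <- sprintf("g%03d", seq_len(n_genotypes))
  calls <- pool[pairs[, 1], , drop = FALSE] + pool[pairs[, 2], , drop = FALSE]
  rownames(calls) <- ids
  colnames(calls) <- sprintf("s%04d", seq_len(ncol(pool)))
  gm <- genotype_matrix(calls)
  list(genotypes = gm, truth = new_ground_truth(pool, pairs, ids, gm))
}

#' Mask a subset of individuals to a fraction of their markers
#'
#' Emulates partially observed genotypes: a uniformly random
#' `1 - observed_fraction` share of the sites is set to missing for each
#' target individual. By default all targets lose the *same* marker
#' subset, as when partially genotyped samples were run on one reduced
#' panel; this keeps pairs of partial genotypes mutually informative at
#' their common observed markers, so extra consistency edges grow roughly
#' linearly with the number of masked individuals. With `shared = FALSE`
#' each target loses an independent random subset. Since missing calls
#' are compatible with anything, masking can only add edges.
#'
#' @param m a `genotype_matrix`.
#' @param targets individual ids to mask.
#' @param observed_fraction fraction of markers left observed (default 0.3).
#' @param seed integer seed.
#' @param shared one common masked site subset for all targets (default)
#'   or an independent subset per target.
#' @return the masked `genotype_matrix`.
#' @export
mask_partial <- function(m, targets, observed_fraction = 0.3, seed = 1L,
                         shared = TRUE) {
  stopifnot(inherits(m, "genotype_matrix"),
            observed_fraction > 0, observed_fraction <= 1)
  if (!all(targets %in% rownames(m))) stop("unknown target ids")
  if (!length(targets)) return(m)
  set.seed(seed)
  n_mask <- round((1 - observed_fraction) * ncol(m))
  out <- unclass(m)
  if (shared) {
    hide <- sample.int(ncol(m), n_mask)
    out[targets, hide] <- NA_integer_
  } else {
    for (id in targets)
      out[id, sample.int(ncol(m), n_mask)] <- NA_integer_
  }
  genotype_matrix(out)
}
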