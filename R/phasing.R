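# Constraint-generation haplotype phasing on top of the parsimony program.
# The ILP proposes a sharing set I; partial phasings are grown over each
# I-connected set S, propagating allele constraints through the shared
# haplotypes; an unphasable node yields a cut outlawing that sharing
# pattern, and the ILP is re-solved. Haplotype alleles are 0/1 with NA for
# not-yet-determined; a fixed site never flips - a contradiction is a
# conflict, not an update.

new_phasing_state <- function(m) {
  st <- new.env(parent = emptyenv())
  st$m <- m
  st$haps <- list()            # pool of partial haplotypes (integer, NA=unknown)
  st$node_haps <- list()       # node -> c(pool id, pool id)
  st$S <- character(0)
  st$conflict <- FALSE
  class(st) <- "phasing_state"
  st
}

ph_new_hap <- function(st) {
  st$haps[[length(st$haps) + 1L]] <- rep(NA_integer_, ncol(st$m))
  length(st$haps)
}

# fix site of pool hap h to val, propagating through genotypes of all
# members of S carrying h; sets st$conflict on contradiction
ph_set <- function(st, h, site, val) {
  if (st$conflict) return(invisible())
  cur <- st$haps[[h]][site]
  if (!is.na(cur)) {
    if (cur != val) st$conflict <- TRUE
    return(invisible())
  }
  st$haps[[h]][site] <- val
  for (w in st$S) {
    hw <- st$node_haps[[w]]
    if (!(h %in% hw)) next
    gg <- st$m[w, site]
    if (is.na(gg)) next
    other <- if (hw[1] == h) hw[2] else hw[1]
    if (gg == 1L) {
      ph_set(st, other, site, 1L - val)
    } else {
      a <- as.integer(gg / 2L)
      if (a != val) { st$conflict <- TRUE; return(invisible()) }
      ph_set(st, other, site, a)
    }
  }
  invisible()
}

# impose node w's genotype on its two haplotypes
ph_apply_node <- function(st, w) {
  hw <- st$node_haps[[w]]
  gg <- st$m[w, ]
  for (site in which(!is.na(gg) & gg != 1L)) {
    a <- as.integer(gg[site] / 2L)
    ph_set(st, hw[1], site, a)
    if (st$conflict) return(invisible())
    ph_set(st, hw[2], site, a)
    if (st$conflict) return(invisible())
  }
  for (site in which(!is.na(gg) & gg == 1L)) {
    v1 <- st$haps[[hw[1]]][site]; v2 <- st$haps[[hw[2]]][site]
    if (!is.na(v1) && is.na(v2)) ph_set(st, hw[2], site, 1L - v1)
    else if (!is.na(v2) && is.na(v1)) ph_set(st, hw[1], site, 1L - v2)
    else if (!is.na(v1) && !is.na(v2) && v1 == v2) st$conflict <- TRUE
    if (st$conflict) return(invisible())
  }
  invisible()
}

#' Seed a phasing state from one sharing edge
#'
#' Initialises `S` with the endpoints of a sharing edge: both receive a
#' common shared haplotype plus one private haplotype each. At every site
#' where either endpoint is homozygous, the shared haplotype is forced to
#' that homozygote's allele (the only allele consistent with sharing), and
#' complements propagate through heterozygous sites.
#'
#' @param e character vector of two individual ids (a sharing edge).
#' @param m a `genotype_matrix`.
#' @return a `phasing_state`.
#' @export
seed_set <- function(e, m) {
  stopifnot(length(e) == 2, all(e %in% rownames(m)))
  if (!genotypes_consistent(m[e[1], ], m[e[2], ]))
    stop("endpoints of a sharing edge must have consistent genotypes")
  st <- new_phasing_state(m)
  p <- ph_new_hap(st)
  st$node_haps[[e[1]]] <- c(p, ph_new_hap(st))
  st$node_haps[[e[2]]] <- c(p, ph_new_hap(st))
  st$S <- e
  ph_apply_node(st, e[1])
  ph_apply_node(st, e[2])
  st
}

# pool hap that u currently shares with w (integer(0) if none)
ph_shared_hap <- function(st, u, w) {
  intersect(st$node_haps[[u]], st$node_haps[[w]])
}

i_neighbors <- function(I, v, within = NULL) {
  hit <- I[, 1] == v | I[, 2] == v
  nb <- setdiff(unique(c(I[hit, 1], I[hit, 2])), v)
  if (!is.null(within)) nb <- intersect(nb, within)
  nb
}

i_has_edge <- function(I, a, b) {
  any((I[, 1] == a & I[, 2] == b) | (I[, 1] == b & I[, 2] == a))
}

#' Extend a phasing state by one node
#'
#' Adds node `v` (an I-neighbor of the current set `S`) to the partial
#' phasing. For each I-neighbor `u` of `v` inside `S`, the haplotype `v`
#' shares with `u` is identified by the triangle rule: if some `w` in `S`
#' shares a haplotype with `u` and `I` also links `v` and `w`, then `v`
#' shares that same haplotype; otherwise `v` shares `u`'s other haplotype.
#' All I-connections of `v` into `S` must agree (at most two distinct
#' shared haplotypes); `v`'s genotype constraints are then merged and
#' propagated to a fixed point. On contradiction the state is returned
#' flagged with the witnessing sharing edges, from which a cut is built.
#'
#' @param state a `phasing_state`.
#' @param v node to add.
#' @param I sharing edge set (2-column character matrix).
#' @param m the `genotype_matrix` (same as in the state).
#' @return list with `ok`; if `ok` is `FALSE`, `witness` holds the I-edges
#'   within `S + v` whose simultaneous sharing is unphasable.
#' @export
extend <- function(state, v, I, m) {
  st <- state
  stopifnot(!(v %in% st$S))
  us <- sort(i_neighbors(I, v, within = st$S))
  if (!length(us)) stop("node has no I-neighbor in S")
  witness <- function() {
    inside <- unique(c(st$S, v))
    keep <- I[, 1] %in% inside & I[, 2] %in% inside
    st$witness <- I[keep, , drop = FALSE]
    st$witness
  }
  shared_haps <- integer(0)
  hap_of_u <- list()
  for (u in us) {
    cands <- integer(0)
    for (w in sort(setdiff(st$S, u))) {
      p <- ph_shared_hap(st, u, w)
      if (!length(p)) next
      h <- if (i_has_edge(I, v, w)) p[1]
           else setdiff(st$node_haps[[u]], p[1])[1]
      cands <- union(cands, h)
    }
    if (length(cands) == 0L)  # u's sharings are only with v itself
      cands <- st$node_haps[[u]][1]
    if (length(cands) > 1L)
      return(list(ok = FALSE, witness = witness(), state = st))
    hap_of_u[[u]] <- cands
    shared_haps <- union(shared_haps, cands)
  }
  if (length(shared_haps) > 2L)
    return(list(ok = FALSE, witness = witness(), state = st))
  pair <- if (length(shared_haps) == 2L) shared_haps
          else c(shared_haps, ph_new_hap(st))
  st$node_haps[[v]] <- pair
  st$S <- c(st$S, v)
  ph_apply_node(st, v)
  if (st$conflict) {
    w <- witness()
    st$S <- setdiff(st$S, v)
    st$node_haps[[v]] <- NULL
    st$conflict <- FALSE
    return(list(ok = FALSE, witness = w, state = st))
  }
  list(ok = TRUE, state = st)
}

#' Build a cut from an unphasable sharing pattern
#'
#' The returned edge set `C` enters the parsimony program as
#' `sum_{e in C} sum_j s_{e,j} <= |C| - 1`: not all of those sharings can
#' hold at once. The incumbent sharing set that produced the conflict
#' violates the cut by construction, so each cut strictly shrinks the
#' feasible set of sharing patterns.
#'
#' @param state a `phasing_state` (after a failed [extend()]).
#' @param I the sharing edge set of the incumbent solution.
#' @return a 2-column character matrix of edges (the cut set).
#' @export
generate_cut <- function(state, I) {
  if (!is.null(state$witness)) return(state$witness)
  inside <- state$S
  keep <- I[, 1] %in% inside & I[, 2] %in% inside
  I[keep, , drop = FALSE]
}

hap_string <- function(h) {
  paste(ifelse(is.na(h), "?", h), collapse = "")
}

#' Phase genotypes by iterative parsimony optimisation
#'
#' Alternates between the parsimony sharing program and combinatorial
#' growth of partial phasings: each round solves the ILP (with all
#' accumulated cuts), proposes a sharing set, and attempts to phase every
#' sharing-connected set; any conflict adds a cut and triggers a re-solve.
#' On completion every genotype equals the site-wise sum of its two output
#' haplotypes at all fixed sites; undetermined sites are reported as `?`.
#'
#' @param m a `genotype_matrix`.
#' @param max_rounds cap on ILP re-solves per component.
#' @param time_limit solver cap in seconds per solve.
#' @param seed recorded; deterministic.
#' @return list of class `phasing_result`: `haplotypes` (character vector,
#'   `?` marks unphased sites), `pairs` (named list individual ->
#'   haplotype ids), `n_haplotypes`, `rounds`, `cuts`, `status` (one of
#'   `complete`, `max_rounds_reached`, `stalled`).
#' @export
phase <- function(m, max_rounds = 20L, time_limit = 60, seed = 1L) {
  stopifnot(inherits(m, "genotype_matrix"))
  pp <- preprocess_genotypes(m)
  mm <- pp$matrix
  g <- build_cc_graph(mm)
  comps <- igraph::decompose(g)
  haplotypes <- character(0)
  pairs <- list()
  total_rounds <- 0L
  n_cuts <- 0L
  status <- "complete"
  emit <- function(st) {
    base <- length(haplotypes)
    haplotypes <<- c(haplotypes, vapply(st$haps, hap_string, ""))
    for (w in names(st$node_haps))
      pairs[[w]] <<- paste0("h", base + st$node_haps[[w]])
  }
  emit_isolated <- function(ids) {
    for (w in ids) {
      st <- new_phasing_state(mm)
      st$node_haps[[w]] <- c(ph_new_hap(st), ph_new_hap(st))
      st$S <- w
      ph_apply_node(st, w)
      emit(st)
    }
  }
  for (cmp in comps) {
    nm <- V(cmp)$name
    if (length(nm) == 1L || ecount(cmp) == 0L) { emit_isolated(nm); next }
    cuts <- list()
    done <- FALSE
    for (round in seq_len(max_rounds)) {
      total_rounds <- total_rounds + 1L
      sol <- solve_min_haplotypes(cmp, cuts = if (length(cuts)) cuts else NULL,
                                  time_limit = time_limit, seed = seed)
      if (sol$status == "infeasible") { status <- "stalled"; done <- TRUE; break }
      I <- sol$sharing
      if (!nrow(I)) { emit_isolated(nm); done <- TRUE; break }
      gi <- as_simple_graph(I, nodes = nm)
      isub <- igraph::decompose(gi)
      states <- list()
      failed <- FALSE
      for (sub in isub) {
        snm <- sort(V(sub)$name)
        if (length(snm) == 1L) next
        sel <- igraph::as_edgelist(sub)
        sel <- cbind(pmin(sel[, 1], sel[, 2]), pmax(sel[, 1], sel[, 2]))
        sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
        st <- seed_set(sel[1, ], mm)
        if (st$conflict) stop("seed edge endpoints inconsistent")
        repeat {
          rest <- setdiff(snm, st$S)
          if (!length(rest)) break
          nbs <- sort(unlist(lapply(rest, function(x)
            if (length(i_neighbors(I, x, within = st$S))) x else NULL)))
          v <- nbs[1]
          ext <- extend(st, v, I, mm)
          if (!ext$ok) {
            cuts[[length(cuts) + 1L]] <- ext$witness
            n_cuts <- n_cuts + 1L
            failed <- TRUE
            break
          }
          st <- ext$state
        }
        if (failed) break
        states[[length(states) + 1L]] <- st
      }
      if (!failed) {
        for (st in states) emit(st)
        emit_isolated(setdiff(nm, unlist(lapply(states, function(s) s$S))))
        done <- TRUE
        break
      }
    }
    if (!done) status <- "max_rounds_reached"
  }
  names(haplotypes) <- paste0("h", seq_along(haplotypes))
  structure(list(haplotypes = haplotypes, pairs = pairs,
                 n_haplotypes = length(haplotypes),
                 rounds = total_rounds, cuts = n_cuts, status = status,
                 preprocess = pp$report),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("Phasing result (", x$status, "): ", x$n_haplotypes,
      " haplotypes for ", length(x$pairs), " genotypes; ",
      x$rounds, " ILP rounds, ", x$cuts, " cuts\n", sep = "")
  invisible(x)
}
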