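#' @importFrom igraph V E vcount ecount gorder gsize
NULL

# Internal: coerce to a validated simple undirected igraph with character
# vertex names. Accepts an igraph or a 2-column edge matrix/data.frame.
as_simple_graph <- function(g, nodes = NULL) {
  if (!igraph::is_igraph(g)) {
    el <- as.matrix(g)
    if (ncol(el) != 2 && !(nrow(el) == 0))
      stop("edge input must have two columns")
    verts <- unique(c(as.character(el), as.character(nodes)))
    g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(verts, V(g)$name)),
                              name = setdiff(verts, V(g)$name))
  }
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(V(g)$name))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(vcount(g))))
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    g <- igraph::simplify(g)
  g
}

#' Test whether a triangle is even
#'
#' A triangle in a graph is *even* if every node outside it is adjacent to 0
#' or 2 of its corners, and *odd* otherwise. Line graphs never contain two
#' odd triangles sharing an edge; the parity of triangles drives the
#' forbidden-subgraph characterisation of line graphs.
#'
#' @param g an igraph (simple, undirected).
#' @param triple character or numeric vector of three vertices inducing a
#'   triangle in `g`.
#' @return `TRUE` if the triangle is even, `FALSE` if odd.
#' @export
is_even_triangle <- function(g, triple) {
  g <- as_simple_graph(g)
  idx <- as.integer(V(g)[triple])
  if (length(unique(idx)) != 3) stop("need three distinct vertices")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  if (!all(A[idx[1], idx[2]], A[idx[1], idx[3]], A[idx[2], idx[3]]))
    stop("the given triple does not induce a triangle")
  others <- setdiff(seq_len(vcount(g)), idx)
  if (!length(others)) return(TRUE)
  cnt <- rowSums(A[others, idx, drop = FALSE])
  all(cnt %in% c(0L, 2L))
}

# ---- Krausz partition -------------------------------------------------------

# Partition the edges of a connected graph into cliques such that every
# vertex lies in at most two cliques. Returns a list of integer vertex
# vectors (the cells), or NULL if no such partition exists (i.e. the graph
# is not a line graph). Backtracking over edge assignments; cells grow by
# absorbing one vertex at a time, which forces all edges between the new
# vertex and the cell into that cell.
krausz_partition <- function(adj, edges) {
  m <- nrow(edges)
  if (m == 0L) return(list())
  assigned <- integer(m)            # 0 = unassigned, else cell id
  cells <- list()                   # each: integer vertex vector
  ncell <- integer(length(adj))     # cliques per vertex
  # fast edge lookup: key u*K+v
  K <- length(adj) + 1L
  ekey <- function(u, v) ifelse(u < v, u * K + v, v * K + u)
  eid <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(as.character(ekey(edges[i, 1], edges[i, 2])), i, envir = eid)
  get_eid <- function(u, v) {
    k <- as.character(ekey(u, v))
    if (exists(k, envir = eid, inherits = FALSE)) get(k, envir = eid) else 0L
  }

  bt <- function() {
    e <- which(assigned == 0L)[1]
    if (is.na(e)) return(TRUE)
    u <- edges[e, 1]; v <- edges[e, 2]
    # Option A: absorb the edge into an existing cell containing u or v
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      for (ord in list(c(u, v), c(v, u))) {
        a <- ord[1]; b <- ord[2]      # a in cell, b joins
        if (!(a %in% cell) || (b %in% cell)) next
        if (ncell[b] >= 2L) next
        if (!all(adj[[b]][cell])) next          # b adjacent to whole cell?
        ids <- vapply(cell, function(w) get_eid(b, w), integer(1))
        if (any(assigned[ids] != 0L)) next      # some b-cell edge taken
        assigned[ids] <<- ci
        cells[[ci]] <<- c(cell, b)
        ncell[b] <<- ncell[b] + 1L
        if (bt()) return(TRUE)
        assigned[ids] <<- 0L
        cells[[ci]] <<- cell
        ncell[b] <<- ncell[b] - 1L
      }
    }
    # Option B: open a new cell {u, v}
    if (ncell[u] < 2L && ncell[v] < 2L) {
      cells[[length(cells) + 1L]] <<- c(u, v)
      ci <- length(cells)
      assigned[e] <<- ci
      ncell[u] <<- ncell[u] + 1L; ncell[v] <<- ncell[v] + 1L
      if (bt()) return(TRUE)
      cells[[ci]] <<- NULL
      assigned[e] <<- 0L
      ncell[u] <<- ncell[u] - 1L; ncell[v] <<- ncell[v] - 1L
    }
    FALSE
  }
  if (bt()) cells else NULL
}

# adjacency-list-of-logical helper used by krausz_partition
adj_logical <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  lapply(seq_len(nrow(A)), function(i) A[i, ])
}

#' Line-graph recognition
#'
#' A graph is a line graph iff it contains none of the nine minimal
#' forbidden induced subgraphs (the claw first among them), or equivalently
#' iff its edges admit a Krausz partition into cliques with every vertex in
#' at most two cliques. Both routes are implemented and agree; `method`
#' selects one.
#'
#' @param g an igraph.
#' @param method `"catalog"` scans for forbidden induced subgraphs;
#'   `"krausz"` attempts the clique partition component-wise.
#' @return logical.
#' @export
is_line_graph <- function(g, method = c("catalog", "krausz")) {
  method <- match.arg(method)
  g <- as_simple_graph(g)
  if (method == "catalog") {
    for (f in forbidden_catalog()) {
      if (vcount(g) < vcount(f)) next
      if (igraph::subgraph_isomorphic(f, g, induced = TRUE, method = "lad"))
        return(FALSE)
    }
    return(TRUE)
  }
  comps <- igraph::decompose(g)
  for (cmp in comps) {
    if (ecount(cmp) == 0L) next
    if (is.null(krausz_partition(adj_logical(cmp), igraph::as_edgelist(cmp, names = FALSE))))
      return(FALSE)
  }
  TRUE
}

#' Enumerate forbidden induced subgraph occurrences
#'
#' Lists every vertex subset of `g` that induces one of the nine minimal
#' non-line graphs. Occurrences are deduplicated by vertex set and returned
#' in lexicographic order of their sorted vertex names. The list is empty
#' iff `g` is a line graph; it feeds the hitting-set (node-deletion) integer
#' program.
#'
#' @param g an igraph.
#' @return list of character vectors (sorted vertex names).
#' @export
find_forbidden_occurrences <- function(g) {
  g <- as_simple_graph(g)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (f in forbidden_catalog()) {
    if (vcount(g) < vcount(f)) next
    maps <- igraph::subgraph_isomorphisms(f, g, induced = TRUE, method = "lad")
    for (mp in maps) {
      vs <- sort(V(g)$name[as.integer(mp)])
      key <- paste(vs, collapse = "\r")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- vs
      }
    }
  }
  ord <- order(vapply(out, function(v) paste(v, collapse = "\r"), ""))
  out[ord]
}

#' Reconstruct the root graph of a line graph
#'
#' Given a line graph `H`, returns the (Whitney-unique) root graph `G` with
#' `L(G)` isomorphic to `H`: each vertex of `H` becomes an edge of `G`, and
#' the vertices of `G` are the haplotypes. Isolated vertices of `H` map to a
#' pendant root edge between two fresh haplotype nodes. A `K3` component is
#' the one ambiguous case (roots `K3` and `K1,3` both work); the `K3` root
#' (3 haplotypes rather than 4) is chosen so that the haplotype count stays
#' a lower bound.
#'
#' @param g an igraph that is a line graph.
#' @return a list of class `root_graph` with elements `root` (igraph whose
#'   vertices are haplotype labels `h1, h2, ...`), `edge_to_individual`
#'   (character vector naming, for each root edge, the `g`-vertex it
#'   represents), and `n_haplotypes`.
#' @export
reconstruct_root <- function(g) {
  g <- as_simple_graph(g)
  comps <- igraph::decompose(g, mode = "weak")
  hap <- 0L
  root_edges <- list()   # pairs of haplotype ids
  owners <- character(0) # g-vertex per root edge
  new_hap <- function() { hap <<- hap + 1L; hap }

  for (cmp in comps) {
    nms <- V(cmp)$name
    nv <- vcount(cmp); ne <- ecount(cmp)
    if (ne == 0L) {               # isolated genotype: two fresh haplotypes
      a <- new_hap(); b <- new_hap()
      root_edges[[length(root_edges) + 1L]] <- c(a, b)
      owners <- c(owners, nms)
      next
    }
    if (nv == 3L && ne == 3L) {   # K3: ambiguous; take the K3 root
      cells <- lapply(1:3, function(i) setdiff(1:3, i)) # 3 single-edge cells
    } else {
      cells <- krausz_partition(adj_logical(cmp), igraph::as_edgelist(cmp, names = FALSE))
      if (is.null(cells)) {
        occ <- find_forbidden_occurrences(cmp)
        stop("not a line graph; forbidden induced subgraph on {",
             paste(occ[[1]], collapse = ", "), "}")
      }
    }
    cell_hap <- vapply(seq_along(cells), function(i) new_hap(), integer(1))
    # vertex -> cells containing it
    memb <- lapply(seq_len(nv), function(v)
      which(vapply(cells, function(cl) v %in% cl, logical(1))))
    for (v in seq_len(nv)) {
      cs <- memb[[v]]
      ends <- if (length(cs) == 2L) cell_hap[cs]
              else c(cell_hap[cs], new_hap())
      root_edges[[length(root_edges) + 1L]] <- ends
      owners <- c(owners, nms[v])
    }
  }
  el <- do.call(rbind, root_edges)
  root <- igraph::make_empty_graph(n = hap, directed = FALSE)
  root <- igraph::set_vertex_attr(root, "name", value = paste0("h", seq_len(hap)))
  root <- igraph::add_edges(root, t(el))
  root <- igraph::set_edge_attr(root, "individual", value = owners)
  structure(list(root = root,
                 edge_to_individual = stats::setNames(owners, apply(el, 1, function(p)
                   paste0("h", min(p), "|h", max(p)))),
                 n_haplotypes = hap),
            class = "root_graph")
}

#' @export
print.root_graph <- function(x, ...) {
  cat("Root graph:", x$n_haplotypes, "haplotypes,",
      ecount(x$root), "genotypes (edges)\n")
  invisible(x)
}

#' Allele (color-pair) assignment from a root graph
#'
#' Labels every individual (line-graph vertex) with the pair of haplotype
#' labels at the endpoints of its root edge. Adjacent individuals then share
#' exactly one label and non-adjacent ones share none, witnessing that the
#' graph is allelable.
#'
#' @param r a `root_graph`.
#' @return named list: individual -> integer pair of color ids.
#' @export
allele_assignment_from_root <- function(r) {
  stopifnot(inherits(r, "root_graph"))
  el <- igraph::as_edgelist(r$root, names = FALSE)
  out <- lapply(seq_len(nrow(el)), function(i) sort(as.integer(el[i, ])))
  stats::setNames(out, E(r$root)$individual)
}

#' Verify an allele assignment
#'
#' Checks the two allelability clauses over all vertex pairs: adjacent
#' vertices share exactly one color; non-adjacent vertices share no color.
#'
#' @param g an igraph.
#' @param a named list vertex -> integer color pair.
#' @return logical.
#' @export
verify_allelable <- function(g, a) {
  g <- as_simple_graph(g)
  nms <- V(g)$name
  if (!all(nms %in% names(a))) stop("assignment missing for some vertices")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- length(nms)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(a[[nms[i]]], a[[nms[j]]]))
    if (A[i, j] && shared != 1L) return(FALSE)
    if (!A[i, j] && shared != 0L) return(FALSE)
  }
  TRUE
}

#' Count haplotypes in an allele assignment
#'
#' The estimated haplotype population size is the number of distinct colors
#' used across all individuals.
#'
#' @param a named list vertex -> color pair.
#' @return positive integer.
#' @export
count_haplotypes <- function(a) {
  length(unique(unlist(a, use.names = FALSE)))
}
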