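# The five integer programs over a sharing graph. Colors are indexed
# 1..2n in a fixed node order (descending degree, ties by name); node i
# "owns" colors 2i-1 and 2i. Variable name scheme: x|v|j (node v uses
# color j), s|u|v|j (edge {u,v} shares color j, u<v as order positions),
# d|u|v (edge deleted), t|v (node deleted), r|u|v (edge removed for any
# reason), c|u|v (edge inserted). All indices are order positions.

ilp_node_order <- function(g) {
  deg <- igraph::degree(g)
  V(g)$name[order(-deg, V(g)$name)]
}

# shared precomputation: order, adjacency in order space, ordered edge list
ilp_graph_ctx <- function(g) {
  g <- as_simple_graph(g)
  ord <- ilp_node_order(g)
  n <- length(ord)
  pos <- stats::setNames(seq_len(n), ord)
  A <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    iu <- pos[el[, 1]]; iv <- pos[el[, 2]]
    A[cbind(iu, iv)] <- TRUE; A[cbind(iv, iu)] <- TRUE
    edges <- cbind(pmin(iu, iv), pmax(iu, iv))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else edges <- matrix(integer(0), 0, 2)
  list(g = g, ord = ord, n = n, pos = pos, A = A, edges = edges)
}

xn <- function(v, j) paste0("x|", v, "|", j)
sn <- function(u, v, j) paste0("s|", u, "|", v, "|", j)
dn <- function(u, v) paste0("d|", u, "|", v)
tn <- function(v) paste0("t|", v)
rn <- function(u, v) paste0("r|", u, "|", v)
cn <- function(u, v) paste0("c|", u, "|", v)

#' Build the basic edge-deletion integer program
#'
#' Minimise the number of deleted edges so that the surviving graph admits
#' a two-colors-per-node assignment in which adjacent nodes share exactly
#' one color and non-adjacent nodes share none (i.e. is a line graph).
#' Binary variables: `d_e` (edge deleted), `x_{v,j}` (node v uses color j,
#' j in 1..2n), `s_{e,j}` (edge e shares color j). This is the full model
#' without symmetry breaking or variable pruning; see
#' [add_symmetry_breaking()] and [prune_variables()], and
#' [solve_edge_deletion()] for the end-to-end solver.
#'
#' @param g an igraph.
#' @return an `ilp_model`.
#' @export
build_edge_deletion_ilp <- function(g) {
  ctx <- ilp_graph_ctx(g)
  n <- ctx$n; A <- ctx$A; edges <- ctx$edges
  model <- new_ilp_model(meta = list(kind = "edge", ctx = ctx, ncolors = 2L * n))
  nc <- 2L * n
  for (v in seq_len(n)) for (j in seq_len(nc)) ilp_add_var(model, xn(v, j))
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ilp_add_var(model, dn(edges[k, 1], edges[k, 2]), obj = 1)
    for (j in seq_len(nc)) ilp_add_var(model, sn(edges[k, 1], edges[k, 2], j))
  }
  # (1) two colors per node
  for (v in seq_len(n))
    ilp_add_con(model, vapply(seq_len(nc), function(j) ilp_var(model, xn(v, j)), 1L),
                rep(1, nc), "=", 2)
  # (2) non-adjacent nodes never share a color
  if (n >= 2) for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (ctx$A[u, v]) next
    for (j in seq_len(nc))
      ilp_add_con(model, c(ilp_var(model, xn(u, j)), ilp_var(model, xn(v, j))),
                  c(1, 1), "<=", 1)
  }
  # (3-5) sharing variables tied to deletion and coloring
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    sidx <- vapply(seq_len(nc), function(j) ilp_var(model, sn(u, v, j)), 1L)
    ilp_add_con(model, c(sidx, ilp_var(model, dn(u, v))), c(rep(1, nc), 1), "=", 1)
    for (j in seq_len(nc)) {
      xu <- ilp_var(model, xn(u, j)); xv <- ilp_var(model, xn(v, j))
      ilp_add_con(model, c(xu, xv, sidx[j]), c(1, 1, -1), "<=", 1)
      ilp_add_con(model, c(sidx[j], xu), c(1, -1), "<=", 0)
      ilp_add_con(model, c(sidx[j], xv), c(1, -1), "<=", 0)
    }
  }
  model
}

#' Add symmetry-breaking constraints
#'
#' Node `i` owns colors `2i-1` and `2i`; a color may only be used if its
#' owner uses it first, and an owner uses its odd color before its even
#' one: `x_{v,2v} <= x_{v,2v-1}`; `x_{j,2i-1} <= x_{i,2i-1}` and
#' `x_{j,2i} <= x_{i,2i}` for `j > i`. Eliminates color-permutation
#' symmetry without changing the optimum.
#'
#' @param model an `ilp_model` with `x` variables.
#' @return the model, modified in place (and returned).
#' @export
add_symmetry_breaking <- function(model) {
  n <- model$meta$ctx$n
  for (v in seq_len(n))
    if (ilp_has_var(model, xn(v, 2 * v)))
      ilp_add_con(model, c(ilp_var(model, xn(v, 2 * v)),
                           ilp_var(model, xn(v, 2 * v - 1))), c(1, -1), "<=", 0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) for (jc in c(2 * i - 1, 2 * i)) {
    if (ilp_has_var(model, xn(j, jc)) && ilp_has_var(model, xn(i, jc)))
      ilp_add_con(model, c(ilp_var(model, xn(j, jc)), ilp_var(model, xn(i, jc))),
                  c(1, -1), "<=", 0)
  }
  model$meta$symmetry <- TRUE
  model
}

#' Prune provably-zero variables
#'
#' After symmetry breaking, `x_{j,2i-1} = x_{j,2i} = 0` whenever
#' `(i,j)` is a non-edge with `i < j` (a node cannot share its owner's
#' color without sharing an edge with the owner), and `s_{e,j} = 0` unless
#' both endpoints of `e` are adjacent to (or equal to) the owner of color
#' `j`. Fixing these to zero preserves the solution set.
#'
#' @param model an `ilp_model` after [add_symmetry_breaking()].
#' @param g the graph the model was built from.
#' @return the model, modified in place (and returned).
#' @export
prune_variables <- function(model, g = NULL) {
  ctx <- model$meta$ctx
  n <- ctx$n; A <- ctx$A
  if (is.null(model$meta$symmetry) || !model$meta$symmetry)
    stop("apply add_symmetry_breaking() before pruning")
  fix <- character(0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!A[i, j]) fix <- c(fix, xn(j, 2 * i - 1), xn(j, 2 * i))
  }
  if (nrow(ctx$edges)) for (k in seq_len(nrow(ctx$edges))) {
    u <- ctx$edges[k, 1]; v <- ctx$edges[k, 2]
    for (i in seq_len(n)) {
      ok <- (i == u || A[i, u]) && (i == v || A[i, v])
      if (!ok) fix <- c(fix, sn(u, v, 2 * i - 1), sn(u, v, 2 * i))
    }
  }
  ilp_fix_zero(model, fix)
  model$meta$pruned <- TRUE
  model
}

# ---- sparse generators used by the solvers ---------------------------------
# Direct construction of the symmetry-broken, pruned model, materialising
# only variables that can be nonzero. Additionally each node v is limited
# to colors 1..2v (a node's colors are either owned by it or introduced by
# an earlier owner), which is implied by the symmetry-breaking scheme.

# existence rule for x|v|j with owner i: i == v, or (A[i,v] and i < v)
x_exists_owner <- function(A, v, i) i == v || (i < v && A[i, v])

edge_deletion_model_sparse <- function(ctx, relax_sharing = FALSE,
                                       parsimony = FALSE) {
  n <- ctx$n; A <- ctx$A; edges <- ctx$edges
  model <- new_ilp_model(meta = list(kind = if (parsimony) "parsimony" else "edge",
                                     ctx = ctx, ncolors = 2L * n,
                                     symmetry = TRUE, pruned = TRUE))
  # x variables; objective counts first-use colors in parsimony mode
  for (v in seq_len(n)) for (i in seq_len(v)) {
    if (!x_exists_owner(A, v, i)) next
    w <- if (parsimony && i == v) 1 else 0
    ilp_add_var(model, xn(v, 2 * i - 1), obj = w)
    ilp_add_var(model, xn(v, 2 * i), obj = w)
  }
  scols <- vector("list", nrow(edges))
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    js <- integer(0)
    for (i in seq_len(u)) {   # owner must be <= min(u,v) = u
      if (x_exists_owner(A, u, i) && x_exists_owner(A, v, i))
        js <- c(js, 2 * i - 1, 2 * i)
    }
    scols[[k]] <- js
    for (j in js) ilp_add_var(model, sn(u, v, j))
    if (!relax_sharing) ilp_add_var(model, dn(u, v), obj = 1)
  }
  # (1) two colors per node
  for (v in seq_len(n)) {
    idx <- integer(0)
    for (i in seq_len(v)) if (x_exists_owner(A, v, i))
      idx <- c(idx, ilp_var(model, xn(v, 2 * i - 1)), ilp_var(model, xn(v, 2 * i)))
    ilp_add_con(model, idx, rep(1, length(idx)), "=", 2)
  }
  # (2) non-adjacent pairs within an owner's closed neighborhood
  for (i in seq_len(n)) {
    users <- which(vapply(seq_len(n), function(v) v >= i && x_exists_owner(A, v, i),
                          logical(1)))
    if (length(users) < 2) next
    for (a in seq_len(length(users) - 1)) for (b in (a + 1):length(users)) {
      u <- users[a]; v <- users[b]
      if (A[u, v]) next
      for (j in c(2 * i - 1, 2 * i))
        ilp_add_con(model, c(ilp_var(model, xn(u, j)), ilp_var(model, xn(v, j))),
                    c(1, 1), "<=", 1)
    }
  }
  # (3-5)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    js <- scols[[k]]
    sidx <- vapply(js, function(j) ilp_var(model, sn(u, v, j)), 1L)
    if (relax_sharing) {
      ilp_add_con(model, sidx, rep(1, length(sidx)), "<=", 1)
    } else {
      ilp_add_con(model, c(sidx, ilp_var(model, dn(u, v))),
                  c(rep(1, length(sidx)), 1), "=", 1)
    }
    for (q in seq_along(js)) {
      j <- js[q]
      xu <- ilp_var(model, xn(u, j)); xv <- ilp_var(model, xn(v, j))
      ilp_add_con(model, c(xu, xv, sidx[q]), c(1, 1, -1), "<=", 1)
      ilp_add_con(model, c(sidx[q], xu), c(1, -1), "<=", 0)
      ilp_add_con(model, c(sidx[q], xv), c(1, -1), "<=", 0)
    }
  }
  # symmetry breaking on the existing variables
  for (v in seq_len(n))
    ilp_add_con(model, c(ilp_var(model, xn(v, 2 * v)),
                         ilp_var(model, xn(v, 2 * v - 1))), c(1, -1), "<=", 0)
  if (n >= 2) for (i in seq_len(n - 1)) for (v in (i + 1):n) {
    if (!x_exists_owner(A, v, i)) next
    for (j in c(2 * i - 1, 2 * i))
      ilp_add_con(model, c(ilp_var(model, xn(v, j)), ilp_var(model, xn(i, j))),
                  c(1, -1), "<=", 0)
  }
  model
}

combined_model_sparse <- function(ctx, alpha) {
  model <- edge_deletion_model_sparse(ctx)
  model$meta$kind <- "combined"
  n <- ctx$n; edges <- ctx$edges
  for (v in seq_len(n)) ilp_add_var(model, tn(v), obj = alpha)
  if (nrow(edges)) for (k in seq_len(nrow(edges)))
    ilp_add_var(model, rn(edges[k, 1], edges[k, 2]))
  # (1) becomes sum_j x = 2 - 2 t_v; the n color-count rows are the first
  # n constraints by construction, so patch them in place.
  for (v in seq_len(n)) {
    cc <- model$cons[[v]]
    model$cons[[v]] <- list(idx = c(cc$idx, ilp_var(model, tn(v))),
                            coefs = c(cc$coefs, 2), sense = "=", rhs = 2)
  }
  # sharing rows: sum_j s + d = 1 becomes sum_j s + r = 1 with
  # r <= t_u + t_v + d, d <= r, t_u <= r, t_v <= r
  if (nrow(edges)) {
    # locate the sharing rows: they are the rows with sense "=" and rhs 1
    krow <- which(vapply(model$cons[seq_len(model$ncons)],
                         function(cc) cc$sense == "=" && cc$rhs == 1, logical(1)))
    stopifnot(length(krow) == nrow(edges))
    for (k in seq_len(nrow(edges))) {
      u <- edges[k, 1]; v <- edges[k, 2]
      dv <- ilp_var(model, dn(u, v)); rv <- ilp_var(model, rn(u, v))
      tu <- ilp_var(model, tn(u)); tv <- ilp_var(model, tn(v))
      cc <- model$cons[[krow[k]]]
      cc$idx[cc$idx == dv] <- rv
      model$cons[[krow[k]]] <- cc
      ilp_add_con(model, c(rv, tu, tv, dv), c(1, -1, -1, -1), "<=", 0)
      ilp_add_con(model, c(dv, rv), c(1, -1), "<=", 0)
      ilp_add_con(model, c(tu, rv), c(1, -1), "<=", 0)
      ilp_add_con(model, c(tv, rv), c(1, -1), "<=", 0)
    }
  }
  model
}
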