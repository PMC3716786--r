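# End-to-end solvers for the graph-modification programs. Large sharing
# graphs decompose into connected components: line-graph modification and
# coloring are component-wise, so each component is solved on its own and
# color labels are offset when merging. Components that already are line
# graphs bypass the ILP entirely (objective 0) and take their coloring from
# the reconstructed root, which also resolves the K3 ambiguity toward 3
# haplotypes.

names_of <- function(ctx, idx) ctx$ord[idx]

# turn a solved sparse model into the component's solution pieces
extract_component_solution <- function(model, res) {
  ctx <- model$meta$ctx
  vals <- res$values
  pick <- function(prefix) {
    nm <- names(vals)[startsWith(names(vals), prefix) & vals > 0.5]
    nm
  }
  parse_pair <- function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    c(names_of(ctx, as.integer(parts[2])), names_of(ctx, as.integer(parts[3])))
  }
  deleted_edges <- t(vapply(pick("d|"), parse_pair, character(2)))
  if (!length(deleted_edges)) deleted_edges <- matrix(character(0), 0, 2)
  inserted_edges <- t(vapply(pick("c|"), parse_pair, character(2)))
  if (!length(inserted_edges)) inserted_edges <- matrix(character(0), 0, 2)
  removed_nodes <- vapply(pick("t|"), function(nm)
    names_of(ctx, as.integer(strsplit(nm, "|", fixed = TRUE)[[1]][2])), "")
  xs <- pick("x|")
  assignment <- list()
  if (length(xs)) {
    parts <- do.call(rbind, strsplit(xs, "|", fixed = TRUE))
    v <- as.integer(parts[, 2]); j <- as.integer(parts[, 3])
    for (vv in unique(v))
      assignment[[names_of(ctx, vv)]] <- sort(j[v == vv])
  }
  shared <- pick("s|")
  sharing <- if (length(shared)) {
    prs <- unique(t(vapply(shared, parse_pair, character(2))))
    prs
  } else matrix(character(0), 0, 2)
  list(deleted_edges = deleted_edges, inserted_edges = inserted_edges,
       deleted_nodes = unname(removed_nodes), assignment = assignment,
       sharing = sharing,
       objective = res$objective, status = res$status, seconds = res$seconds)
}

# coloring of a line-graph component via its root (no ILP needed)
line_component_assignment <- function(cmp) {
  r <- reconstruct_root(cmp)
  a <- allele_assignment_from_root(r)
  lapply(a, as.integer)
}

offset_assignment <- function(a, off) lapply(a, function(p) p + off)

merge_component_solutions <- function(parts) {
  off <- 0L
  assignment <- list()
  del_e <- list(); ins_e <- list(); del_n <- character(0); shr <- list()
  objective <- 0; seconds <- 0
  statuses <- character(0)
  for (p in parts) {
    aa <- offset_assignment(p$assignment, off)
    assignment[names(aa)] <- aa
    off <- off + if (length(aa)) max(unlist(aa)) - off else 0L
    del_e[[length(del_e) + 1L]] <- p$deleted_edges
    ins_e[[length(ins_e) + 1L]] <- p$inserted_edges
    shr[[length(shr) + 1L]] <- p$sharing
    del_n <- c(del_n, p$deleted_nodes)
    objective <- objective + p$objective
    seconds <- seconds + (p$seconds %||% 0)
    statuses <- c(statuses, p$status)
  }
  status <- if (all(statuses == "optimal")) "optimal"
            else if (any(statuses == "infeasible")) "infeasible"
            else if (any(statuses == "timeout")) "timeout" else "feasible"
  list(deleted_edges = do.call(rbind, del_e),
       inserted_edges = do.call(rbind, ins_e),
       deleted_nodes = del_n,
       assignment = assignment,
       sharing = do.call(rbind, shr),
       objective = objective, status = status, seconds = seconds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_solution <- function(sol, g, verify = TRUE) {
  g2 <- igraph::delete_vertices(g, intersect(sol$deleted_nodes, V(g)$name))
  if (nrow(sol$deleted_edges) > 0) {
    keep <- sol$deleted_edges[, 1] %in% V(g2)$name &
            sol$deleted_edges[, 2] %in% V(g2)$name
    if (any(keep))
      g2 <- igraph::delete_edges(g2, igraph::get_edge_ids(
        g2, t(sol$deleted_edges[keep, , drop = FALSE])))
  }
  if (nrow(sol$inserted_edges) > 0)
    g2 <- igraph::add_edges(g2, t(sol$inserted_edges))
  sol$surviving_graph <- g2
  sol$estimated_haplotypes <- count_haplotypes(sol$assignment)
  if (verify) {
    if (!is_line_graph(g2))
      warning("surviving graph failed line-graph verification")
    if (length(sol$assignment) &&
        !verify_allelable(g2, sol$assignment))
      warning("allele assignment failed verification")
  }
  class(sol) <- "deletion_solution"
  sol
}

#' @export
print.deletion_solution <- function(x, ...) {
  cat("Line-graph modification solution (", x$status, ")\n", sep = "")
  cat("  deleted edges:   ", nrow(x$deleted_edges), "\n")
  cat("  deleted nodes:   ", length(x$deleted_nodes), "\n")
  cat("  inserted edges:  ", nrow(x$inserted_edges), "\n")
  cat("  est. haplotypes: ", x$estimated_haplotypes, "\n")
  invisible(x)
}

solve_coloring_modes <- function(g, mode, alpha = NULL, time_limit = 600,
                                 seed = 1L, verify = TRUE) {
  g <- as_simple_graph(g)
  comps <- igraph::decompose(g)
  parts <- lapply(comps, function(cmp) {
    if (is_line_graph(cmp)) {
      return(list(deleted_edges = matrix(character(0), 0, 2),
                  inserted_edges = matrix(character(0), 0, 2),
                  deleted_nodes = character(0),
                  assignment = line_component_assignment(cmp),
                  sharing = igraph::as_edgelist(cmp),
                  objective = 0, status = "optimal", seconds = 0))
    }
    ctx <- ilp_graph_ctx(cmp)
    model <- if (mode == "edge") edge_deletion_model_sparse(ctx)
             else combined_model_sparse(ctx, alpha)
    res <- solve_ilp(model, time_limit = time_limit, seed = seed)
    if (is.null(res$values)) {
      if (res$status != "timeout")
        stop("solver returned no incumbent (status ", res$status, ")")
      # no incumbent within the cap: fall back to deleting every edge of
      # the component (always feasible), flagged as a timeout
      warning("time limit hit with no incumbent; falling back to full edge deletion")
      el <- igraph::as_edgelist(cmp)
      nm <- V(cmp)$name
      return(list(deleted_edges = el,
                  inserted_edges = matrix(character(0), 0, 2),
                  deleted_nodes = character(0),
                  assignment = stats::setNames(lapply(seq_along(nm), function(i)
                    c(2L * i - 1L, 2L * i)), nm),
                  sharing = matrix(character(0), 0, 2),
                  objective = nrow(el), status = "timeout",
                  seconds = res$seconds))
    }
    extract_component_solution(model, res)
  })
  finish_solution(merge_component_solutions(parts), g, verify = verify)
}

#' Solve minimum edge deletion to a line graph
#'
#' Removes the fewest edges so that the graph becomes a line graph, and
#' extracts the witnessing color (haplotype) assignment. Solved exactly per
#' connected component with GLPK; components that already are line graphs
#' are colored directly from their root graph.
#'
#' @param g an igraph.
#' @param time_limit solver wall-clock cap in seconds per component.
#' @param seed recorded; the solver is deterministic.
#' @param verify check the surviving graph and assignment (default TRUE).
#' @return a `deletion_solution` with `deleted_edges`, `assignment`,
#'   `estimated_haplotypes`, `objective`, `status`.
#' @export
solve_edge_deletion <- function(g, time_limit = 600, seed = 1L, verify = TRUE) {
  solve_coloring_modes(g, "edge", time_limit = time_limit, seed = seed,
                       verify = verify)
}

#' Build the node-deletion (hitting set) integer program
#'
#' Every forbidden induced subgraph occurrence must lose at least one node:
#' minimise the number of deleted nodes subject to one covering constraint
#' per occurrence. Node deletion never creates new forbidden occurrences,
#' so hitting all of them suffices.
#'
#' @param g an igraph.
#' @param occurrences optional precomputed [find_forbidden_occurrences()] list.
#' @return an `ilp_model` over `t_v` variables.
#' @export
build_node_deletion_ilp <- function(g, occurrences = NULL) {
  ctx <- ilp_graph_ctx(g)
  if (is.null(occurrences)) occurrences <- find_forbidden_occurrences(ctx$g)
  model <- new_ilp_model(meta = list(kind = "node", ctx = ctx))
  for (v in seq_len(ctx$n)) ilp_add_var(model, tn(v), obj = 1)
  for (occ in occurrences) {
    idx <- vapply(unname(ctx$pos[occ]), function(v) ilp_var(model, tn(v)), 1L)
    ilp_add_con(model, idx, rep(1, length(idx)), ">=", 1)
  }
  model
}

#' Solve minimum node deletion to a line graph
#'
#' @inheritParams solve_edge_deletion
#' @return a `deletion_solution`; the haplotype estimate comes from the
#'   root graph of the surviving line graph.
#' @export
solve_node_deletion <- function(g, time_limit = 600, seed = 1L, verify = TRUE) {
  g <- as_simple_graph(g)
  model <- build_node_deletion_ilp(g)
  res <- solve_ilp(model, time_limit = time_limit, seed = seed)
  if (is.null(res$values))
    stop("solver returned no incumbent (status ", res$status, ")")
  ctx <- model$meta$ctx
  deleted <- names_of(ctx, as.integer(vapply(
    names(res$values)[startsWith(names(res$values), "t|") & res$values > 0.5],
    function(nm) strsplit(nm, "|", fixed = TRUE)[[1]][2], "")))
  g2 <- igraph::delete_vertices(g, deleted)
  assignment <- lapply(line_component_assignment_all(g2), as.integer)
  sol <- list(deleted_edges = matrix(character(0), 0, 2),
              inserted_edges = matrix(character(0), 0, 2),
              deleted_nodes = deleted,
              assignment = assignment,
              sharing = igraph::as_edgelist(g2),
              objective = res$objective, status = res$status,
              seconds = res$seconds)
  finish_solution(sol, g, verify = verify)
}

# root-based coloring across all components with color offsets
line_component_assignment_all <- function(g) {
  parts <- lapply(igraph::decompose(g), function(cmp)
    list(assignment = line_component_assignment(cmp),
         deleted_edges = matrix(character(0), 0, 2),
         inserted_edges = matrix(character(0), 0, 2),
         deleted_nodes = character(0), sharing = igraph::as_edgelist(cmp),
         objective = 0, status = "optimal", seconds = 0))
  merge_component_solutions(parts)$assignment
}

#' Build the combined node-and-edge deletion integer program
#'
#' The coloring program of [build_edge_deletion_ilp()] extended with node
#' deletion variables `t_v` at relative cost `alpha`: a deleted node needs
#' no colors, every edge incident to it counts as removed, and the removal
#' indicator `r_e` is tied to `t_u + t_v + d_e`. Symmetry breaking is
#' included.
#'
#' @param g an igraph.
#' @param alpha relative cost of a node deletion versus an edge deletion.
#' @return an `ilp_model`.
#' @export
build_combined_ilp <- function(g, alpha) {
  stopifnot(alpha > 0)
  combined_model_sparse(ilp_graph_ctx(g), alpha)
}

#' Solve the combined node-and-edge deletion problem
#'
#' @inheritParams solve_edge_deletion
#' @param alpha relative node-deletion cost (`> 0`).
#' @return a `deletion_solution`.
#' @export
solve_combined <- function(g, alpha = 1.5, time_limit = 600, seed = 1L,
                           verify = TRUE) {
  stopifnot(alpha > 0)
  solve_coloring_modes(g, "combined", alpha = alpha, time_limit = time_limit,
                       seed = seed, verify = verify)
}

#' Build the edge-editing integer program
#'
#' Generalises edge deletion to editing: edges may be deleted (weight
#' `w_e`) and non-edges inserted (weight `w_e`), so that the edited graph
#' is a line graph. Insertion candidates default to all non-adjacent pairs;
#' when a genotype matrix is supplied they are restricted to pairs whose
#' genotypes conflict at no more than `insert_cap` sites, with insertion
#' weight equal to that conflict count (the number of miscalls needed for
#' the edge to be real).
#'
#' @param g an igraph.
#' @param genotypes optional `genotype_matrix` aligned with `g`'s vertices.
#' @param insert_cap max incompatibility count for a candidate insertion
#'   (used only with `genotypes`).
#' @param all_pairs force the full V x V candidate set.
#' @return an `ilp_model`.
#' @export
build_edit_ilp <- function(g, genotypes = NULL, insert_cap = 2L,
                           all_pairs = is.null(genotypes)) {
  ctx <- ilp_graph_ctx(g)
  n <- ctx$n; A <- ctx$A; edges <- ctx$edges
  # candidate insertions and weights (order positions, u < v)
  cand <- matrix(integer(0), 0, 2); cw <- numeric(0)
  dw <- rep(1, nrow(edges))
  if (n >= 2) for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (A[u, v]) next
    if (all_pairs) { cand <- rbind(cand, c(u, v)); cw <- c(cw, 1); next }
    if (!is.null(genotypes)) {
      ic <- incompatibility_count(genotypes[names_of(ctx, u), ],
                                  genotypes[names_of(ctx, v), ])
      if (ic <= insert_cap) { cand <- rbind(cand, c(u, v)); cw <- c(cw, ic) }
    }
  }
  A2 <- A
  if (nrow(cand)) A2[rbind(cand, cand[, 2:1, drop = FALSE])] <- TRUE
  model <- new_ilp_model(meta = list(kind = "edit", ctx = ctx,
                                     symmetry = TRUE, pruned = TRUE))
  for (v in seq_len(n)) for (i in seq_len(v)) {
    if (!(i == v || (i < v && A2[i, v]))) next
    ilp_add_var(model, xn(v, 2 * i - 1)); ilp_add_var(model, xn(v, 2 * i))
  }
  pair_rows <- function(u, v, svar_edge, extra_idx, extra_coefs, rhs) {
    # sharing bookkeeping rows for one (possibly editable) pair
    js <- integer(0)
    for (i in seq_len(u)) {
      if ((i == u || A2[i, u]) && (i == v || A2[i, v]))
        js <- c(js, 2 * i - 1, 2 * i)
    }
    for (j in js) ilp_add_var(model, sn(u, v, j))
    sidx <- vapply(js, function(j) ilp_var(model, sn(u, v, j)), 1L)
    ilp_add_con(model, c(sidx, extra_idx), c(rep(1, length(sidx)), extra_coefs),
                "=", rhs)
    for (q in seq_along(js)) {
      j <- js[q]
      xu <- ilp_var(model, xn(u, j)); xv <- ilp_var(model, xn(v, j))
      ilp_add_con(model, c(xu, xv, sidx[q]), c(1, 1, -1), "<=", 1)
      ilp_add_con(model, c(sidx[q], xu), c(1, -1), "<=", 0)
      ilp_add_con(model, c(sidx[q], xv), c(1, -1), "<=", 0)
    }
  }
  for (v in seq_len(n)) {
    idx <- integer(0)
    for (i in seq_len(v)) if (i == v || (i < v && A2[i, v]))
      idx <- c(idx, ilp_var(model, xn(v, 2 * i - 1)), ilp_var(model, xn(v, 2 * i)))
    ilp_add_con(model, idx, rep(1, length(idx)), "=", 2)
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    ilp_add_var(model, dn(u, v), obj = dw[k])
    pair_rows(u, v, TRUE, ilp_var(model, dn(u, v)), 1, 1)
  }
  if (nrow(cand)) for (k in seq_len(nrow(cand))) {
    u <- cand[k, 1]; v <- cand[k, 2]
    ilp_add_var(model, cn(u, v), obj = cw[k])
    pair_rows(u, v, FALSE, ilp_var(model, cn(u, v)), -1, 0)
  }
  # non-adjacent, non-candidate pairs sharing nothing
  for (i in seq_len(n)) {
    users <- which(vapply(seq_len(n), function(v)
      v >= i && (i == v || A2[i, v]), logical(1)))
    if (length(users) < 2) next
    for (a in seq_len(length(users) - 1)) for (b in (a + 1):length(users)) {
      u <- users[a]; v <- users[b]
      if (A2[u, v]) next
      for (j in c(2 * i - 1, 2 * i))
        ilp_add_con(model, c(ilp_var(model, xn(u, j)), ilp_var(model, xn(v, j))),
                    c(1, 1), "<=", 1)
    }
  }
  for (v in seq_len(n))
    ilp_add_con(model, c(ilp_var(model, xn(v, 2 * v)),
                         ilp_var(model, xn(v, 2 * v - 1))), c(1, -1), "<=", 0)
  if (n >= 2) for (i in seq_len(n - 1)) for (v in (i + 1):n) {
    if (!(A2[i, v])) next
    for (j in c(2 * i - 1, 2 * i))
      ilp_add_con(model, c(ilp_var(model, xn(v, j)), ilp_var(model, xn(i, j))),
                  c(1, -1), "<=", 0)
  }
  model
}

#' Solve the edge-editing problem
#'
#' @inheritParams build_edit_ilp
#' @inheritParams solve_edge_deletion
#' @return a `deletion_solution` with `inserted_edges` populated.
#' @export
solve_edit <- function(g, genotypes = NULL, insert_cap = 2L,
                       all_pairs = is.null(genotypes), time_limit = 600,
                       seed = 1L, verify = TRUE) {
  g <- as_simple_graph(g)
  model <- build_edit_ilp(g, genotypes = genotypes, insert_cap = insert_cap,
                          all_pairs = all_pairs)
  res <- solve_ilp(model, time_limit = time_limit, seed = seed)
  if (is.null(res$values))
    stop("solver returned no incumbent (status ", res$status, ")")
  finish_solution(extract_component_solution(model, res), g, verify = verify)
}

#' Build the parsimony (minimum haplotype count) integer program
#'
#' Minimises the number of colors used: the objective counts first uses
#' `x_{v,2v-1} + x_{v,2v}` under the ownership scheme, node `v` may only
#' use colors `1..2v`, and edge sharing is relaxed to
#' `sum_j s_{e,j} <= 1` so that edges may silently drop out of the sharing
#' set. There are no deletion variables.
#'
#' @param g an igraph.
#' @return an `ilp_model`.
#' @export
build_min_haplotypes_ilp <- function(g) {
  edge_deletion_model_sparse(ilp_graph_ctx(g), relax_sharing = TRUE,
                             parsimony = TRUE)
}

#' Solve the parsimony haplotype-count program
#'
#' @param g an igraph.
#' @param cuts optional list of edge sets (2-column character matrices);
#'   for each, the constraint `sum over those edges of sum_j s_{e,j} <=
#'   |set| - 1` is added. Used by the phasing loop to outlaw sharing
#'   patterns that cannot be phased.
#' @inheritParams solve_edge_deletion
#' @return list with `count` (minimum number of haplotypes), `assignment`,
#'   `sharing` (2-column matrix: the edges where a color is shared, the set
#'   I), `status`, `objective`.
#' @export
solve_min_haplotypes <- function(g, cuts = NULL, time_limit = 600, seed = 1L) {
  g <- as_simple_graph(g)
  if (is.null(cuts) || length(cuts) == 0L) {
    comps <- igraph::decompose(g)
    parts <- lapply(comps, function(cmp)
      solve_min_haplotypes_component(cmp, NULL, time_limit, seed))
    merged <- merge_component_solutions(parts)
    return(list(count = count_haplotypes(merged$assignment),
                assignment = merged$assignment, sharing = merged$sharing,
                status = merged$status, objective = merged$objective))
  }
  p <- solve_min_haplotypes_component(g, cuts, time_limit, seed)
  list(count = if (p$status == "infeasible") NA_integer_
               else count_haplotypes(p$assignment),
       assignment = p$assignment, sharing = p$sharing,
       status = p$status, objective = p$objective)
}

solve_min_haplotypes_component <- function(cmp, cuts, time_limit, seed) {
  ctx <- ilp_graph_ctx(cmp)
  if (nrow(ctx$edges) == 0L) {
    nm <- V(ctx$g)$name
    a <- stats::setNames(lapply(seq_along(nm), function(i) c(2L * i - 1L, 2L * i)), nm)
    return(list(deleted_edges = matrix(character(0), 0, 2),
                inserted_edges = matrix(character(0), 0, 2),
                deleted_nodes = character(0), assignment = a,
                sharing = matrix(character(0), 0, 2),
                objective = 2 * length(nm), status = "optimal", seconds = 0))
  }
  model <- edge_deletion_model_sparse(ctx, relax_sharing = TRUE, parsimony = TRUE)
  for (cut in cuts %||% list()) {
    idx <- integer(0)
    for (r in seq_len(nrow(cut))) {
      u <- ctx$pos[[cut[r, 1]]]; v <- ctx$pos[[cut[r, 2]]]
      if (u > v) { tmp <- u; u <- v; v <- tmp }
      svars <- model$vars[startsWith(model$vars, paste0("s|", u, "|", v, "|"))]
      idx <- c(idx, vapply(svars, function(nm) ilp_var(model, nm), 1L))
    }
    ilp_add_con(model, idx, rep(1, length(idx)), "<=", nrow(cut) - 1)
  }
  res <- solve_ilp(model, time_limit = time_limit, seed = seed)
  if (res$status == "infeasible" || is.null(res$values))
    return(list(deleted_edges = matrix(character(0), 0, 2),
                inserted_edges = matrix(character(0), 0, 2),
                deleted_nodes = character(0), assignment = list(),
                sharing = matrix(character(0), 0, 2),
                objective = NA_real_, status = res$status,
                seconds = res$seconds))
  extract_component_solution(model, res)
}
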