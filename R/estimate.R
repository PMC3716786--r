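#' Estimate the haplotype population size from genotypes
#'
#' The end-to-end pipeline: preprocess the genotype matrix (drop fully
#' homozygous individuals, collapse duplicate genotypes), build the
#' Clark-consistency graph of potential haplotype sharing, make it a line
#' graph by the selected modification mode, and count the haplotypes of the
#' resulting coloring. Individuals dropped as fully homozygous carry one
#' directly observed haplotype each; the distinct ones among them are added
#' to the estimate and reported separately.
#'
#' @param m a `genotype_matrix`.
#' @param mode one of `"edge"` (minimum edge deletion), `"node"` (minimum
#'   node deletion), `"combined"` (nodes at relative cost `alpha`),
#'   `"edit"` (edge deletion + insertion), `"parsimony"` (minimum haplotype
#'   count, edges may drop silently).
#' @param alpha node-deletion cost for `mode = "combined"`.
#' @param insert_cap candidate cap for `mode = "edit"` (see [build_edit_ilp()]).
#' @param time_limit solver cap in seconds per component.
#' @param seed recorded in the report; the pipeline is deterministic.
#' @return a list of class `estimate_report`: `estimated_haplotypes`,
#'   `colors_estimate` (haplotypes among analysed individuals),
#'   `edges_removed`, `nodes_removed`, `edges_inserted`, `status`,
#'   `solve_seconds`, `preprocess` (the preprocessing report), `solution`
#'   (the underlying `deletion_solution`), `cc_graph`.
#' @export
estimate_population_size <- function(m, mode = c("edge", "node", "combined",
                                                 "edit", "parsimony"),
                                     alpha = 1.5, insert_cap = 2L,
                                     time_limit = 600, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "genotype_matrix"))
  t0 <- proc.time()[["elapsed"]]
  pp <- preprocess_genotypes(m)
  g <- build_cc_graph(pp$matrix)
  sol <- switch(mode,
    edge = solve_edge_deletion(g, time_limit = time_limit, seed = seed),
    node = solve_node_deletion(g, time_limit = time_limit, seed = seed),
    combined = solve_combined(g, alpha = alpha, time_limit = time_limit,
                              seed = seed),
    edit = solve_edit(g, genotypes = pp$matrix, insert_cap = insert_cap,
                      time_limit = time_limit, seed = seed),
    parsimony = NULL)
  if (mode == "parsimony") {
    ph <- solve_min_haplotypes(g, time_limit = time_limit, seed = seed)
    sol <- list(deleted_edges = matrix(character(0), 0, 2),
                inserted_edges = matrix(character(0), 0, 2),
                deleted_nodes = character(0), assignment = ph$assignment,
                sharing = ph$sharing, objective = ph$objective,
                status = ph$status, estimated_haplotypes = ph$count,
                surviving_graph = g)
    class(sol) <- "deletion_solution"
  }
  colors_est <- sol$estimated_haplotypes
  report <- list(
    mode = mode, alpha = if (mode == "combined") alpha else NULL,
    estimated_haplotypes = colors_est + pp$report$n_homozygous_haplotypes,
    colors_estimate = colors_est,
    homozygous_haplotypes = pp$report$n_homozygous_haplotypes,
    edges_removed = nrow(sol$deleted_edges),
    nodes_removed = length(sol$deleted_nodes),
    removed_node_ids = sol$deleted_nodes,
    edges_inserted = nrow(sol$inserted_edges),
    cc_edges = igraph::ecount(g),
    status = sol$status,
    solve_seconds = proc.time()[["elapsed"]] - t0,
    seed = seed,
    preprocess = pp$report,
    solution = sol,
    cc_graph = g)
  class(report) <- "estimate_report"
  report
}

#' @export
print.estimate_report <- function(x, ...) {
  cat("Haplotype population size estimate (mode =", x$mode, ")\n")
  cat("  CC graph edges:     ", x$cc_edges, "\n")
  cat("  edges removed:      ", x$edges_removed, "\n")
  cat("  nodes removed:      ", x$nodes_removed, "\n")
  if (x$edges_inserted) cat("  edges inserted:     ", x$edges_inserted, "\n")
  cat("  estimated haplotypes:", x$estimated_haplotypes, "\n")
  cat("  solver status:      ", x$status, "\n")
  invisible(x)
}

#' Compare an estimate against simulation ground truth
#'
#' @param report an `estimate_report`.
#' @param truth a `ground_truth` from the simulators.
#' @param masked character vector of individuals that were partially masked
#'   (for splitting node removals).
#' @return list with `estimated`, `true_count`, `ratio`, `edges_removed`,
#'   `false_edge_removals` (removed edges that were true sharings),
#'   `nodes_removed_masked`, `nodes_removed_unmasked`.
#' @export
evaluate_estimate <- function(report, truth, masked = character(0)) {
  stopifnot(inherits(report, "estimate_report"))
  ids <- rownames(truth$genotypes %||% matrix(, 0, 0))
  if (length(ids) && !all(report$solution$deleted_nodes %in% c(ids, character(0))))
    stop("estimate and truth refer to different individuals")
  key <- function(m) if (nrow(m)) paste(pmin(m[, 1], m[, 2]),
                                        pmax(m[, 1], m[, 2])) else character(0)
  true_edges <- key(truth$true_sharing_edges)
  removed <- key(report$solution$deleted_edges)
  del_nodes <- report$solution$deleted_nodes
  list(estimated = report$estimated_haplotypes,
       true_count = truth$true_count,
       ratio = report$estimated_haplotypes / truth$true_count,
       edges_removed = report$edges_removed,
       false_edge_removals = sum(removed %in% true_edges),
       nodes_removed_masked = sum(del_nodes %in% masked),
       nodes_removed_unmasked = sum(!del_nodes %in% masked))
}
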