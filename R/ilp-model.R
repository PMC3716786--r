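# Generic 0/1 integer-program container and the GLPK backend. Variables are
# addressed by semantic names ("x|v|j", "s|u|v|j", "d|u|v", "t|v", "c|u|v");
# the LP file uses positional names v1..vK so the solution parses back
# unambiguously. glpsol is single-threaded and deterministic; the seed in
# the solver options is recorded for provenance but GLPK takes none.

new_ilp_model <- function(meta = list()) {
  env <- new.env(parent = emptyenv())
  env$vars <- character(0)
  env$vidx <- new.env(hash = TRUE, parent = emptyenv())
  env$obj <- numeric(0)
  env$fixed0 <- logical(0)
  env$cons <- vector("list", 0)
  env$ncons <- 0L
  env$meta <- meta
  class(env) <- "ilp_model"
  env
}

#' @export
print.ilp_model <- function(x, ...) {
  cat("ILP model:", length(x$vars), "binary variables,", x$ncons,
      "constraints\n")
  invisible(x)
}

ilp_add_var <- function(model, name, obj = 0) {
  k <- length(model$vars) + 1L
  model$vars[k] <- name
  model$obj[k] <- obj
  model$fixed0[k] <- FALSE
  assign(name, k, envir = model$vidx)
  invisible(k)
}

ilp_var <- function(model, name) {
  get(name, envir = model$vidx, inherits = FALSE)
}

ilp_has_var <- function(model, name) {
  exists(name, envir = model$vidx, inherits = FALSE)
}

# coefs: named numeric (names = semantic var names) or numeric with idx
ilp_add_con <- function(model, idx, coefs, sense, rhs) {
  model$ncons <- model$ncons + 1L
  model$cons[[model$ncons]] <- list(idx = idx, coefs = coefs,
                                    sense = sense, rhs = rhs)
  invisible(model$ncons)
}

ilp_fix_zero <- function(model, names) {
  for (nm in names)
    if (ilp_has_var(model, nm)) model$fixed0[ilp_var(model, nm)] <- TRUE
  invisible(model)
}

# Write the model as a CPLEX-format LP file.
ilp_write_lp <- function(model, path) {
  nv <- length(model$vars)
  term <- function(idx, coefs) {
    sgn <- ifelse(coefs < 0, " - ", " + ")
    mag <- abs(coefs)
    co <- ifelse(mag == 1, "", paste0(format(mag, scientific = FALSE), " "))
    s <- paste0(sgn, co, "v", idx, collapse = "")
    sub("^ \\+ ", "", s)
  }
  obj_idx <- which(model$obj != 0)
  obj_str <- if (length(obj_idx)) term(obj_idx, model$obj[obj_idx]) else "0 v1"
  lines <- c("Minimize", paste0(" obj: ", obj_str), "Subject To")
  if (model$ncons > 0) {
    cons <- model$cons[seq_len(model$ncons)]
    body <- vapply(seq_along(cons), function(i) {
      cc <- cons[[i]]
      sense <- switch(cc$sense, "<=" = " <= ", ">=" = " >= ", "=" = " = ")
      paste0(" c", i, ": ", term(cc$idx, cc$coefs), sense,
             format(cc$rhs, scientific = FALSE))
    }, "")
    lines <- c(lines, body)
  } else {
    lines <- c(lines, " c1: 0 v1 <= 1")
  }
  fx <- which(model$fixed0)
  if (length(fx))
    lines <- c(lines, "Bounds", paste0(" v", fx, " = 0"))
  lines <- c(lines, "Binary", paste0(" v", seq_len(nv)), "End")
  writeLines(lines, path)
  invisible(path)
}

#' Solve a 0/1 integer program with GLPK
#'
#' Writes the model in LP format and runs the `glpsol` branch-and-cut
#' solver (single thread, zero relative gap, configurable wall-clock cap).
#' The returned status is one of `optimal`, `feasible` (time limit hit with
#' an incumbent), `timeout` (no incumbent), or `infeasible`.
#'
#' @param model an `ilp_model`.
#' @param time_limit seconds (default 600).
#' @param seed recorded in the result for provenance; GLPK is deterministic.
#' @return list with `status`, `objective`, `values` (named 0/1 vector over
#'   semantic variable names), `seconds`.
#' @export
solve_ilp <- function(model, time_limit = 600, seed = 1L) {
  stopifnot(inherits(model, "ilp_model"))
  t0 <- proc.time()[["elapsed"]]
  nv <- length(model$vars)
  if (nv == 0L)
    return(list(status = "optimal", objective = 0,
                values = stats::setNames(numeric(0), character(0)),
                seconds = 0, seed = seed))
  glpsol <- Sys.which("glpsol")
  if (glpsol == "") stop("glpsol (GLPK) not found on PATH")
  lp <- tempfile(fileext = ".lp"); sol <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp, sol)), add = TRUE)
  ilp_write_lp(model, lp)
  # Pseudocost branching plus clique cuts turn the combined node-and-edge
  # program from hours into seconds (its pairwise color-conflict rows
  # aggregate into cliques), but slow the pure edge-deletion program on
  # dense graphs; choose per program family.
  extra <- if (identical(model$meta$kind, "combined")) c("--pcost", "--clique")
           else character(0)
  out <- suppressWarnings(system2(glpsol,
    c("--lp", shQuote(lp), "--tmlim", as.integer(ceiling(time_limit)),
      extra, "-o", shQuote(sol)), stdout = TRUE, stderr = TRUE))
  secs <- proc.time()[["elapsed"]] - t0
  hit_limit <- any(grepl("TIME LIMIT EXCEEDED", out))
  if (!file.exists(sol)) stop("glpsol produced no solution file")
  txt <- readLines(sol)
  status_line <- grep("^Status:", txt, value = TRUE)
  raw_status <- if (length(status_line)) sub("^Status:\\s*", "", status_line[1]) else ""
  if (grepl("EMPTY|NO INTEGER|INFEASIBLE|UNDEFINED", raw_status)) {
    status <- if (hit_limit && grepl("UNDEFINED", raw_status)) "timeout" else "infeasible"
    return(list(status = status, objective = NA_real_,
                values = NULL, seconds = secs, seed = seed))
  }
  proven <- grepl("OPTIMAL", raw_status) && !grepl("NON-OPTIMAL", raw_status)
  status <- if (proven) "optimal" else "feasible"
  objective <- as.numeric(sub(".*obj = ([-0-9.eE+]+).*", "\\1",
                              grep("^Objective:", txt, value = TRUE)[1]))
  # parse column activities
  col_start <- grep("Column name", txt)[1]
  vals <- numeric(nv)
  if (!is.na(col_start)) {
    for (ln in txt[(col_start + 2):length(txt)]) {
      if (!nzchar(trimws(ln))) break
      mm <- regmatches(ln, regexec("^\\s*\\d+\\s+v(\\d+)\\s+\\*?\\s+([-0-9.eE+]+)", ln))[[1]]
      if (length(mm) == 3)
        vals[as.integer(mm[2])] <- as.numeric(mm[3])
    }
  }
  list(status = status,
       objective = objective,
       values = stats::setNames(round(vals), model$vars),
       seconds = secs, seed = seed,
       optimality_proven = proven)
}
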