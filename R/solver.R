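#' @useDynLib crisisgraph, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Solve a bounded mixed-integer linear program
#'
#' Exact branch-and-bound over an embedded bounded-variable simplex.
#' Minimizes `obj %*% x` subject to `mat %*% x == rhs` and
#' `lb <= x <= ub`, with the variables in `int_idx` required to be
#' integral. All bounds must be finite. This is the optimization kernel
#' behind the junction-balance and walk-decomposition programs; it is
#' tuned for the small, well-scaled instances those produce (hundreds of
#' columns), not for general-purpose use.
#'
#' @param obj numeric objective coefficients.
#' @param mat constraint matrix (dense), equality rows only.
#' @param rhs right-hand side vector.
#' @param lb,ub finite lower/upper variable bounds.
#' @param int_idx indices of integer-constrained variables.
#' @param node_limit maximum branch-and-bound nodes.
#' @param int_tol integrality tolerance.
#' @return list with `status` ("optimal", "infeasible", or "node_limit"),
#'   `x` (solution vector), and `objval`.
#' @keywords internal
cg_milp <- function(obj, mat, rhs, lb, ub, int_idx = integer(0),
                    node_limit = 200000L, int_tol = 1e-6) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub + 1e-12))
  mat <- as.matrix(mat)
  n <- length(obj)

  best_x <- NULL
  best_obj <- Inf
  # depth-first until the first incumbent (a greedy dive that rounds one
  # variable per level), then best-bound with pruning
  nodes <- list(list(lb = lb, ub = ub, bound = -Inf))
  bounds_vec <- -Inf
  n_nodes <- 0L

  while (length(nodes) > 0L) {
    if (n_nodes >= node_limit)
      return(list(status = "node_limit", x = best_x, objval = best_obj))
    i <- if (is.null(best_x)) length(nodes) else which.min(bounds_vec)
    nd <- nodes[[i]]
    nodes[[i]] <- NULL
    bounds_vec <- bounds_vec[-i]
    if (nd$bound >= best_obj - 1e-9) next
    n_nodes <- n_nodes + 1L

    sol <- .lp_solve_cpp(obj, mat, rhs, nd$lb, nd$ub)
    if (sol$status == 1L) next
    if (sol$status == 2L) stop("LP iteration limit reached inside cg_milp")
    lpobj <- sol$obj
    if (lpobj >= best_obj - 1e-9) next
    x <- as.numeric(sol$x)

    frac <- abs(x[int_idx] - round(x[int_idx]))
    if (length(int_idx) == 0L || all(frac <= int_tol)) {
      x[int_idx] <- round(x[int_idx])
      best_x <- x
      best_obj <- lpobj
      next
    }
    j <- int_idx[which.max(frac)]
    fl <- floor(x[j] + int_tol)
    fr <- x[j] - fl
    children <- list()
    ub_d <- nd$ub; ub_d[j] <- fl
    if (ub_d[j] >= nd$lb[j] - 1e-12)
      children$down <- list(lb = nd$lb, ub = ub_d, bound = lpobj)
    lb_u <- nd$lb; lb_u[j] <- fl + 1
    if (lb_u[j] <= nd$ub[j] + 1e-12)
      children$up <- list(lb = lb_u, ub = nd$ub, bound = lpobj)
    # push the nearer integer last so the dive explores it first
    ord <- if (fr <= 0.5) c("up", "down") else c("down", "up")
    for (nm in ord) if (!is.null(children[[nm]])) {
      nodes[[length(nodes) + 1L]] <- children[[nm]]
      bounds_vec <- c(bounds_vec, lpobj)
    }
  }

  if (is.null(best_x)) return(list(status = "infeasible", x = NULL, objval = Inf))
  list(status = "optimal", x = best_x, objval = best_obj)
}
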