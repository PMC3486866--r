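# Row-oriented LP front end.
#
# Simulation code assembles problems as
#   optimize c'x  s.t.  M x {<=,>=,=} rhs,  0 <= x <= ub
# and this wrapper converts them to the standard equality form consumed by
# the bounded-variable simplex in lp_simplex.R by appending one slack or
# surplus column per inequality row.

#' Solve a linear program over non-negative box-bounded variables
#'
#' @param obj objective coefficient vector (length n).
#' @param mat constraint matrix (dense), one row per constraint.
#' @param dir character vector of `"<="`, `">="`, `"="` per row.
#' @param rhs right-hand sides.
#' @param ub optional upper bounds on the variables (default all `Inf`).
#' @param maximize maximize instead of minimize.
#' @param tol pivoting tolerance.
#' @param max_iter simplex iteration cap (default scales with problem size).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x` (solution over the n structural variables,
#'   `NULL` unless optimal), `value`.
#' @export
solve_lp <- function(obj, mat, dir, rhs, ub = NULL, maximize = FALSE,
                     tol = 1e-9, max_iter = NULL) {
  n <- length(obj)
  mat <- matrix(as.numeric(mat), ncol = n)
  stopifnot(nrow(mat) == length(dir), length(dir) == length(rhs))
  if (is.null(ub)) ub <- rep(Inf, n)
  ineq <- which(dir != "=")
  n_slack <- length(ineq)
  A <- cbind(mat, matrix(0, nrow(mat), n_slack))
  if (n_slack > 0L) {
    for (k in seq_along(ineq)) {
      A[ineq[k], n + k] <- if (dir[ineq[k]] == "<=") 1 else -1
    }
  }
  res <- lp_solve_std(c(obj, rep(0, n_slack)), A, as.numeric(rhs),
                      u = c(ub, rep(Inf, n_slack)), maximize = maximize,
                      tol = tol, max_iter = max_iter)
  if (!is.null(res$x)) res$x <- res$x[seq_len(n)]
  res
}
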