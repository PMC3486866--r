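# Dense two-phase revised simplex for linear programs over box-bounded
# non-negative variables:
#
#   minimize  c'x   subject to  A x = b,  0 <= x <= u   (u may be Inf)
#
# Constraint-based simulation LPs are small (tens to a few hundred variables)
# but heavily degenerate: the steady-state block has an all-zero right-hand
# side, and deviation-variable pairs create many ties. The implementation
# therefore uses Dantzig pricing with an automatic switch to Bland's rule
# after a run of degenerate pivots (anti-cycling), a bounded-variable ratio
# test with bound flips, explicit basis-inverse updates with periodic
# refactorization, and a driving-out pass that removes artificial variables
# from the basis after phase 1 (redundant rows keep their artificial pinned
# at zero). All pivoting rules are deterministic, so identical inputs give
# identical optima.

#' Solve a box-bounded linear program in standard equality form
#'
#' @param obj objective coefficients (length n).
#' @param A dense constraint matrix (m x n) of `A x = b`.
#' @param b right-hand side (length m).
#' @param u upper bounds (length n, `Inf` allowed); lower bounds are 0.
#' @param maximize maximize instead of minimize.
#' @param tol pivoting/feasibility tolerance.
#' @param max_iter iteration cap (default scales with problem size).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x`, `value`.
#' @export
lp_solve_std <- function(obj, A, b, u = rep(Inf, length(obj)),
                         maximize = FALSE, tol = 1e-9, max_iter = NULL) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(length(b) == m, length(u) == n, all(u >= 0))
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  # orient rows so that b >= 0, then append artificial columns
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  ntot <- n + m
  Afull <- cbind(A, diag(m))
  ufull <- c(u, rep(Inf, m))
  state <- list(B = n + seq_len(m), Binv = diag(m),
                at_ub = rep(FALSE, ntot))
  if (is.null(max_iter)) max_iter <- 500L + 50L * (m + n)

  # ---- phase 1: minimize the artificial sum --------------------------------
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- .simplex_iterate(c1, Afull, b, ufull, state, tol, max_iter)
  if (ph1$status == "iteration_limit") {
    return(list(status = "iteration_limit", x = NULL, value = NA_real_))
  }
  x1 <- .simplex_solution(Afull, b, ufull, ph1$state)
  if (sum(x1[n + seq_len(m)]) > 1e-7 * (1 + max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  state <- .drive_out_artificials(Afull, n, ph1$state, tol)
  ufull[n + seq_len(m)] <- 0  # artificials may never move again

  # ---- phase 2 -------------------------------------------------------------
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplex_iterate(c2, Afull, b, ufull, state, tol, max_iter)
  if (ph2$status != "optimal") {
    val <- if (ph2$status == "unbounded") {
      if (maximize) Inf else -Inf
    } else NA_real_
    return(list(status = ph2$status, x = NULL, value = val))
  }
  x <- .simplex_solution(Afull, b, ufull, ph2$state)[seq_len(n)]
  value <- sum(obj * x)
  list(status = "optimal", x = x, value = value)
}

# Current primal point implied by a basis state.
.simplex_solution <- function(Afull, b, ufull, state) {
  ntot <- ncol(Afull)
  x <- numeric(ntot)
  nb_ub <- which(state$at_ub & !(seq_len(ntot) %in% state$B))
  x[nb_ub] <- ufull[nb_ub]
  rhs <- b
  if (length(nb_ub) > 0L) {
    rhs <- rhs - Afull[, nb_ub, drop = FALSE] %*% ufull[nb_ub]
  }
  x[state$B] <- as.numeric(state$Binv %*% rhs)
  x
}

# Main pivoting loop; returns the updated state and a status.
.simplex_iterate <- function(cvec, Afull, b, ufull, state, tol, max_iter) {
  m <- nrow(Afull); ntot <- ncol(Afull)
  B <- state$B; Binv <- state$Binv; at_ub <- state$at_ub
  degen_run <- 0L
  since_refactor <- 0L
  for (it in seq_len(max_iter)) {
    is_basic <- logical(ntot); is_basic[B] <- TRUE
    nb_ub <- which(at_ub & !is_basic)
    rhs <- b
    if (length(nb_ub) > 0L) {
      rhs <- rhs - Afull[, nb_ub, drop = FALSE] %*% ufull[nb_ub]
    }
    xB <- as.numeric(Binv %*% rhs)
    y <- as.numeric(crossprod(Binv, cvec[B]))   # simplex multipliers
    d <- cvec - as.numeric(y %*% Afull)         # reduced costs
    cand <- which(!is_basic & ufull > tol)
    viol <- ifelse(at_ub[cand], d[cand], -d[cand])
    ok <- viol > tol
    if (!any(ok)) {
      return(list(status = "optimal",
                  state = list(B = B, Binv = Binv, at_ub = at_ub)))
    }
    cand <- cand[ok]; viol <- viol[ok]
    # lowest index within a tolerance band of the strongest violation:
    # deterministic and immune to last-ulp noise, so numerically identical
    # programs follow identical pivot paths even through exact ties
    q <- if (degen_run > 50L) min(cand) else {
      band <- max(viol) * (1 - 1e-9)
      min(cand[viol >= band])
    }
    from_ub <- at_ub[q]
    w <- as.numeric(Binv %*% Afull[, q])
    if (from_ub) w <- -w  # entering variable decreases; flip direction
    # ratio test: basic variables hitting 0 (w>0) or their ub (w<0),
    # and the entering variable flipping to its other bound
    t_best <- ufull[q]; r_best <- 0L
    for (i in seq_len(m)) {
      if (w[i] > tol) {
        ti <- xB[i] / w[i]
        if (ti < t_best - 1e-12 ||
            (ti < t_best + 1e-12 && r_best > 0L && B[i] < B[r_best])) {
          t_best <- ti; r_best <- i
        }
      } else if (w[i] < -tol && is.finite(ufull[B[i]])) {
        ti <- (ufull[B[i]] - xB[i]) / (-w[i])
        if (ti < t_best - 1e-12 ||
            (ti < t_best + 1e-12 && r_best > 0L && B[i] < B[r_best])) {
          t_best <- ti; r_best <- i
        }
      }
    }
    if (is.infinite(t_best)) {
      return(list(status = "unbounded",
                  state = list(B = B, Binv = Binv, at_ub = at_ub)))
    }
    degen_run <- if (t_best < tol) degen_run + 1L else 0L
    if (r_best == 0L) {
      at_ub[q] <- !from_ub  # pure bound flip
      next
    }
    leaving <- B[r_best]
    # leaving variable lands at 0 (w>0 case) or at its upper bound
    at_ub[leaving] <- w[r_best] < 0
    at_ub[q] <- FALSE
    B[r_best] <- q
    wq <- as.numeric(Binv %*% Afull[, q])  # unflipped direction for the update
    piv <- wq[r_best]
    Binv[r_best, ] <- Binv[r_best, ] / piv
    for (i in seq_len(m)) {
      if (i != r_best && abs(wq[i]) > 0) {
        Binv[i, ] <- Binv[i, ] - wq[i] * Binv[r_best, ]
      }
    }
    since_refactor <- since_refactor + 1L
    if (since_refactor >= 60L) {
      Binv <- tryCatch(solve(Afull[, B, drop = FALSE]), error = function(e) Binv)
      since_refactor <- 0L
    }
  }
  list(status = "iteration_limit",
       state = list(B = B, Binv = Binv, at_ub = at_ub))
}

# After phase 1, pivot basic artificials out on any usable structural column;
# a row with no such column is redundant and keeps its artificial at zero.
.drive_out_artificials <- function(Afull, n, state, tol) {
  m <- nrow(Afull)
  B <- state$B; Binv <- state$Binv; at_ub <- state$at_ub
  for (r in seq_len(m)) {
    if (B[r] <= n) next
    row <- as.numeric(Binv[r, ] %*% Afull[, seq_len(n), drop = FALSE])
    is_basic <- seq_len(n) %in% B
    cands <- which(!is_basic & abs(row) > 1e-7)
    if (length(cands) == 0L) next
    q <- cands[1L]
    wq <- as.numeric(Binv %*% Afull[, q])
    piv <- wq[r]
    B[r] <- q
    at_ub[q] <- FALSE
    Binv[r, ] <- Binv[r, ] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(wq[i]) > 0) Binv[i, ] <- Binv[i, ] - wq[i] * Binv[r, ]
    }
  }
  list(B = B, Binv = Binv, at_ub = at_ub)
}
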