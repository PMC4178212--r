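# Internal LP layer: optimize a linear objective over the flux polytope
# { v : S v = 0, lb <= v <= ub }.
#
# Solved by a dense bounded-variable two-phase primal simplex written for
# this package. The flux polytopes that arise here are small (tens of
# variables) but highly degenerate (zero right-hand sides, many ties), so the
# implementation uses Bland's smallest-index rule for both the entering and
# the leaving variable, which guarantees termination without cycling.

# min c'x s.t. A x = b, l <= x <= u  (all bounds finite unless noted).
# Returns list(status = "optimal"|"infeasible", value, x).
#' @keywords internal
simplex_bounded <- function(A, b, cc, l, u, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # box only: each variable sits at whichever bound minimizes its cost
    x <- ifelse(cc > 0, l, u)
    x[cc == 0] <- l[cc == 0]
    return(list(status = "optimal", value = sum(cc * x), x = x))
  }
  # start with structurals at the bound of smaller magnitude; artificials
  # absorb the residual with +1 phase-1 cost each
  x0 <- ifelse(abs(l) <= abs(u), l, u)
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Af <- cbind(A, diag(sgn, m, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, rep(Inf, m))
  xf <- c(x0, abs(r))
  state <- list(x = xf, basis = (n + 1L):(n + m),
                at_upper = c(abs(l) > abs(u), rep(FALSE, m)))

  p1 <- simplex_iterate(Af, c(rep(0, n), rep(1, m)), lf, uf, state, tol)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  if (sum(p1$state$x[(n + 1L):(n + m)]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  uf[(n + 1L):(n + m)] <- 0  # artificials may stay basic at zero, never move
  p1$state$x[(n + 1L):(n + m)] <- 0
  p2 <- simplex_iterate(Af, c(cc, rep(0, m)), lf, uf, p1$state, tol)
  if (p2$status != "optimal") return(list(status = "infeasible"))
  x <- p2$state$x[seq_len(n)]
  list(status = "optimal", value = sum(cc * x), x = x)
}

#' @keywords internal
simplex_iterate <- function(A, cc, l, u, state, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 500L * (n + m)
  x <- state$x
  basis <- state$basis
  at_upper <- state$at_upper
  bvec <- as.numeric(A %*% x)  # the constant right-hand side A x = b
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    # refresh basic values from the nonbasic bounds: x_B = B^-1 (b - A_N x_N);
    # recomputing every iteration prevents drift in degenerate pivots
    nb <- setdiff(seq_len(n), basis)
    xn <- ifelse(at_upper[nb], u[nb], l[nb])
    x[nb] <- xn
    rhs <- bvec - if (length(nb)) as.numeric(A[, nb, drop = FALSE] %*% xn) else 0
    x[basis] <- as.numeric(solve(B, rhs))
    y <- tryCatch(solve(t(B), cc[basis]),
                  error = function(e) stop("singular simplex basis", call. = FALSE))
    d <- cc - as.numeric(crossprod(A, y))
    enter <- NA_integer_
    for (j in nb) {  # Bland: smallest eligible index
      if (l[j] == u[j]) next
      if (!at_upper[j] && d[j] < -tol) { enter <- j; break }
      if (at_upper[j] && d[j] > tol) { enter <- j; break }
    }
    if (is.na(enter)) {
      return(list(status = "optimal",
                  state = list(x = x, basis = basis, at_upper = at_upper)))
    }
    # entering variable moves away from its bound by t >= 0; basic variables
    # respond along -dir (entering from lower) where dir = B^-1 A_j
    dir <- as.numeric(solve(B, A[, enter]))
    sign_move <- if (at_upper[enter]) -1 else 1
    delta <- -sign_move * dir  # change of basic values per unit t

    t_best <- u[enter] - l[enter]  # bound flip of the entering variable
    leave_pos <- NA_integer_       # position in basis; NA = bound flip
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (delta[i] < -tol) {
        ti <- (l[bi] - x[bi]) / delta[i]
      } else if (delta[i] > tol) {
        ti <- (u[bi] - x[bi]) / delta[i]
      } else {
        next
      }
      ti <- max(ti, 0)
      if (ti < t_best - tol) {
        t_best <- ti
        leave_pos <- i
      } else if (ti <= t_best + tol) {
        # tie: Bland's rule, prefer the smallest leaving variable index
        t_best <- min(t_best, ti)
        if (is.na(leave_pos) || bi < basis[leave_pos]) leave_pos <- i
      }
    }
    if (!is.finite(t_best)) stop("unbounded LP in simplex_iterate", call. = FALSE)
    x[enter] <- x[enter] + sign_move * t_best
    x[basis] <- x[basis] + delta * t_best
    if (is.na(leave_pos)) {
      at_upper[enter] <- !at_upper[enter]  # entering flipped bound; basis unchanged
    } else {
      bi <- basis[leave_pos]
      at_upper[bi] <- delta[leave_pos] > 0
      x[bi] <- if (at_upper[bi]) u[bi] else l[bi]
      basis[leave_pos] <- enter
    }
  }
  stop("simplex iteration limit exceeded", call. = FALSE)
}

#' @keywords internal
lp_box <- function(S, lb, ub, obj = NULL, maximize = FALSE) {
  n <- length(lb)
  stopifnot(length(ub) == n, ncol(S) == n, all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_, v = NULL))
  if (is.null(obj)) obj <- numeric(n)
  cc <- if (maximize) -obj else obj
  res <- simplex_bounded(as.matrix(S), numeric(nrow(S)), cc, lb, ub)
  if (res$status != "optimal") {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  v <- res$x
  names(v) <- colnames(S)
  list(status = "optimal", value = sum(obj * v), v = v)
}

#' @keywords internal
lp_feasible <- function(S, lb, ub) {
  lp_box(S, lb, ub, obj = NULL)
}
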