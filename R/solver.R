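# Bounded-variable two-phase primal simplex on the standard form
#   min c'x  s.t.  A x = b,  0 <= x <= u
# All upper bounds must be finite, which every flux model in this package
# guarantees (missing bounds are a load-time error, not a default).
#
# The basis system is refactorized from scratch at every iteration (dense
# solve), so no error accumulates across pivots; problem sizes here are tens
# of rows, where this is cheap. Pivoting uses the Dantzig rule and falls back
# to Bland's rule after `bland_after` iterations to rule out cycling.
simplex_bounded <- function(cvec, A, b, u, tol = 1e-9, max_iter = 20000L,
                            bland_after = 500L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m, length(u) == n)
  if (any(!is.finite(u))) stop("simplex_bounded requires finite upper bounds")
  u <- pmax(u, 0)
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }
  Ae <- cbind(A, diag(m))
  ue <- c(u, pmax(b, 1))
  art <- n + seq_len(m)

  run_phase <- function(cost, basis, at_upper, xB, ue) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "iteration_limit"))
      bland <- iter > bland_after
      B <- Ae[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular_basis"))
      y <- drop(crossprod(Binv, cost[basis]))
      nb <- setdiff(seq_len(n + m), basis)
      rc <- cost[nb] - drop(crossprod(Ae[, nb, drop = FALSE], y))
      low <- !at_upper[nb]
      # variables clamped to a point (ue == 0) can never move
      cand <- ue[nb] > 0 & ((low & rc < -tol) | (!low & rc > tol))
      if (!any(cand)) {
        obj <- sum(cost[basis] * xB)
        up <- nb[at_upper[nb]]
        if (length(up)) obj <- obj + sum(cost[up] * ue[up])
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xB = xB, obj = obj))
      }
      idx <- which(cand)
      j_i <- if (bland) idx[which.min(nb[idx])] else idx[which.max(abs(rc[idx]))]
      j <- nb[j_i]
      s <- if (at_upper[j]) -1 else 1
      w <- s * drop(Binv %*% Ae[, j])
      # ratio test: entering moves distance t >= 0; basics move by -t*w
      t_best <- ue[j]
      leave <- 0L
      leave_to_upper <- FALSE
      pos <- which(w > tol)
      if (length(pos)) {
        ti <- xB[pos] / w[pos]
        k <- which.min(ti)
        if (ti[k] < t_best - 1e-12) {
          t_best <- max(ti[k], 0); leave <- pos[k]; leave_to_upper <- FALSE
        }
      }
      neg <- which(w < -tol)
      if (length(neg)) {
        ti <- (ue[basis[neg]] - xB[neg]) / (-w[neg])
        k <- which.min(ti)
        if (ti[k] < t_best - 1e-12) {
          t_best <- max(ti[k], 0); leave <- neg[k]; leave_to_upper <- TRUE
        }
      }
      xB <- xB - t_best * w
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]
      } else {
        enter_val <- if (at_upper[j]) ue[j] - t_best else t_best
        lv <- basis[leave]
        at_upper[lv] <- leave_to_upper
        xB[leave] <- enter_val
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
      xB[xB < 0 & xB > -1e-8] <- 0
    }
  }

  p1 <- run_phase(c(rep(0, n), rep(1, m)), basis = art,
                  at_upper = rep(FALSE, n + m), xB = b, ue = ue)
  if (!identical(p1$status, "optimal")) return(list(status = p1$status))
  if (p1$obj > 1e-6 * (1 + max(abs(b)))) return(list(status = "infeasible"))
  ue[art] <- 0
  p1$at_upper[art] <- FALSE
  p2 <- run_phase(c(cvec, rep(0, m)), p1$basis, p1$at_upper, p1$xB, ue)
  if (!identical(p2$status, "optimal")) return(list(status = p2$status))
  x <- numeric(n + m)
  x[p2$basis] <- p2$xB
  nb <- setdiff(seq_len(n + m), p2$basis)
  x[nb[p2$at_upper[nb]]] <- ue[nb[p2$at_upper[nb]]]
  if (any(x[art] > 1e-6)) return(list(status = "infeasible"))
  list(status = "optimal", x = x[seq_len(n)], obj = sum(cvec * x[seq_len(n)]))
}

#' Solve a steady-state linear program over a flux polytope
#'
#' Optimizes a linear flux objective subject to `S v = b` (mass balance) and
#' box bounds `lb <= v <= ub`. This is the optimization kernel behind
#' [fba()], [fva()], the exchange-cardinality minimization and the screening
#' steps; it is exported for diagnostic use.
#'
#' @param obj numeric objective coefficients, one per column of `S`.
#' @param S stoichiometric (or general constraint) matrix, metabolites in
#'   rows, reactions in columns. Dense or `Matrix` sparse.
#' @param lb,ub finite lower/upper flux bounds per reaction.
#' @param b right-hand side of the balance constraints (default all zero,
#'   i.e. steady state).
#' @param sense `"max"` or `"min"`.
#' @return A list with `status` (`"optimal"`, `"infeasible"` or a solver
#'   failure code), `fluxes` (named if `S` has column names) and `objective`.
#' @examples
#' S <- matrix(c(1, -1), 1, 2, dimnames = list("m", c("in", "out")))
#' solve_lp(c(0, 1), S, lb = c(0, 0), ub = c(5, 10))
#' @export
solve_lp <- function(obj, S, lb, ub, b = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds on every reaction")
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible",
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S)),
                objective = NA_real_))
  }
  if (is.null(b)) b <- numeric(nrow(S))
  bb <- b - drop(S %*% lb)
  cc <- if (sense == "max") -obj else obj
  r <- simplex_bounded(cc, S, bb, ub - lb)
  if (!identical(r$status, "optimal")) {
    return(list(status = r$status,
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S)),
                objective = NA_real_))
  }
  v <- r$x + lb
  names(v) <- colnames(S)
  list(status = "optimal", fluxes = v, objective = sum(obj * v))
}
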