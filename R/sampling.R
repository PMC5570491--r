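#' Hit-and-run sampling of the steady-state flux polytope
#'
#' Artificial-centering-style hit-and-run: warmup flux vectors are collected
#' from the per-reaction variability LPs, their running mean recenters the
#' chain, and each saved point is the end of `steps_per_point` hit-and-run
#' steps along random directions drawn from the null space of `S` (so every
#' step preserves mass balance exactly; only the bounds clip the step
#' interval).
#'
#' @param model a `metabolic_model`; all bounds must be finite, which rules
#'   out unbounded polytope directions before sampling starts.
#' @param n_points number of flux vectors to return.
#' @param steps_per_point chain steps between saved points.
#' @param warmup number of warmup directions (capped at twice the reaction
#'   count; the warmup set is the FVA vertex collection).
#' @param seed integer seed; required, so a sample stream is reproducible.
#' @return Object of class `flux_sample_set`: list with `samples`
#'   (`n_points` x reactions matrix), `medians`, and `params`.
#' @export
sample_fluxes <- function(model, n_points = 100, steps_per_point = 100,
                          warmup = 1000, seed) {
  if (missing(seed)) stop("a seed is required for flux sampling")
  stopifnot(is_feasible(model))
  set.seed(seed)
  n <- nrow(model$rxns)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("unbounded polytope direction: non-finite bounds")
  # warmup: FVA end points, averaged for an interior starting point
  pts <- list()
  for (j in seq_len(n)) {
    o <- numeric(n)
    o[j] <- 1
    for (sn in c("min", "max")) {
      r <- solve_lp(o, model$S, lb, ub, sense = sn)
      if (identical(r$status, "optimal")) pts[[length(pts) + 1]] <- r$fluxes
    }
    if (length(pts) >= min(warmup, 2 * n)) break
  }
  W <- do.call(rbind, pts)
  x <- colMeans(W)
  # null-space basis of S: directions that keep S v = 0
  N <- nullspace_basis(as.matrix(model$S))
  if (!ncol(N)) {
    samples <- matrix(rep(x, n_points), nrow = n_points, byrow = TRUE,
                      dimnames = list(NULL, model$rxns$id))
    return(structure(list(samples = samples,
                          medians = apply(samples, 2, stats::median),
                          params = list(n_points = n_points,
                                        steps_per_point = steps_per_point,
                                        warmup = nrow(W), seed = seed)),
                     class = "flux_sample_set"))
  }
  center <- x
  samples <- matrix(NA_real_, n_points, n,
                    dimnames = list(NULL, model$rxns$id))
  tol <- 1e-10
  for (p in seq_len(n_points)) {
    for (s in seq_len(steps_per_point)) {
      # artificial centering: direction through a random warmup point
      if (stats::runif(1) < 0.5 && nrow(W) > 1) {
        d <- W[sample.int(nrow(W), 1), ] - center
      } else {
        d <- drop(N %*% stats::rnorm(ncol(N)))
      }
      nd <- sqrt(sum(d^2))
      if (nd < tol) next
      d <- d / nd
      # step interval from bounds: lb <= x + t d <= ub
      tmax <- Inf
      tmin <- -Inf
      pos <- d > tol
      neg <- d < -tol
      if (any(pos)) {
        tmax <- min(tmax, min((ub[pos] - x[pos]) / d[pos]))
        tmin <- max(tmin, max((lb[pos] - x[pos]) / d[pos]))
      }
      if (any(neg)) {
        tmax <- min(tmax, min((lb[neg] - x[neg]) / d[neg]))
        tmin <- max(tmin, max((ub[neg] - x[neg]) / d[neg]))
      }
      if (!is.finite(tmax) || !is.finite(tmin)) next
      if (tmax < tmin) next
      x <- x + stats::runif(1, tmin, tmax) * d
      x <- pmin(pmax(x, lb), ub)
      center <- center + (x - center) / 100
    }
    samples[p, ] <- x
  }
  structure(list(samples = samples, medians = apply(samples, 2, stats::median),
                 params = list(n_points = n_points,
                               steps_per_point = steps_per_point,
                               warmup = nrow(W), seed = seed)),
            class = "flux_sample_set")
}

# orthonormal basis of the null space of A via complete QR
nullspace_basis <- function(A, tol = 1e-10) {
  if (!nrow(A)) return(diag(ncol(A)))
  qr_t <- qr(t(A))
  r <- qr_t$rank
  Q <- qr.Q(qr_t, complete = TRUE)
  n <- ncol(A)
  if (r >= n) return(matrix(0, n, 0))
  Q[, (r + 1):n, drop = FALSE]
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("flux_sample_set:", nrow(x$samples), "points x", ncol(x$samples),
      "reactions (seed", x$params$seed, ")\n")
  invisible(x)
}
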