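#' Flux balance analysis
#'
#' Optimizes a linear flux objective subject to steady state `S v = 0` and
#' the model's bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id (default: the model objective) or a named
#'   numeric vector of objective coefficients.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_solution` with `status` in `optimal`/`infeasible`.
#' @examples
#' m <- make_toy_glycolysis()
#' fba(m)$objective # 2 ATP per glucose
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  obj <- objective_vector(model, objective)
  r <- solve_lp(obj, model$S, model$rxns$lb, model$rxns$ub, sense = sense)
  flux_solution(r$fluxes, r$objective, r$status)
}

objective_vector <- function(model, objective) {
  n <- nrow(model$rxns)
  if (is.null(objective)) objective <- model$objective
  if (is.character(objective)) {
    i <- match(objective, model$rxns$id)
    if (anyNA(i)) stop("unknown objective reaction: ", objective[is.na(i)][1])
    obj <- numeric(n)
    obj[i] <- 1
  } else {
    i <- match(names(objective), model$rxns$id)
    if (anyNA(i)) stop("unknown objective reaction: ",
                       names(objective)[is.na(i)][1])
    obj <- numeric(n)
    obj[i] <- as.numeric(objective)
  }
  stats::setNames(obj, model$rxns$id)
}

# bare feasibility of the flux polytope (phase-1 only in effect)
is_feasible <- function(model) {
  r <- solve_lp(numeric(nrow(model$rxns)), model$S, model$rxns$lb,
                model$rxns$ub)
  identical(r$status, "optimal")
}

#' Parsimonious flux balance analysis
#'
#' Two-stage scheme: stage 1 optimizes the linear objective by [fba()];
#' stage 2 holds that optimum fixed (to a relative tolerance of 1e-7, for
#' numerical stability of the quadratic program) and minimizes the squared
#' Euclidean norm of the internal (non-exchange) fluxes. Exchange fluxes
#' carry a vanishing regularization weight so the quadratic form is strictly
#' convex, which makes the returned flux vector unique.
#'
#' @param model a `metabolic_model`.
#' @param objective as in [fba()].
#' @param sense `"max"` or `"min"` for stage 1.
#' @param exchange_weight regularization weight on exchange fluxes
#'   (default 1e-6; internal fluxes have weight 1).
#' @return A `flux_solution`; `objective` is the stage-1 linear optimum
#'   realized by the returned vector.
#' @examples
#' m <- make_parallel_pathways()
#' sol <- parsimonious_fba(m)
#' sol$fluxes[c("P1", "P2")] # identical halves
#' @export
parsimonious_fba <- function(model, objective = NULL,
                             sense = c("max", "min"),
                             exchange_weight = 1e-6) {
  sense <- match.arg(sense)
  obj <- objective_vector(model, objective)
  s1 <- fba(model, objective, sense)
  if (s1$status != "optimal")
    return(s1)
  z <- s1$objective
  n <- nrow(model$rxns)
  ex <- model$rxns$id %in% exchange_reactions(model)
  w <- ifelse(ex, exchange_weight, 1)
  Dmat <- diag(w, n)
  A_eq <- as.matrix(model$S)
  tol_z <- 1e-7 * (1 + abs(z))
  # inequality rows: objective band, bounds
  A_in <- rbind(if (sense == "max") obj else -obj,
                diag(n), -diag(n))
  b_in <- c(if (sense == "max") z - tol_z else -z - tol_z,
            model$rxns$lb, -model$rxns$ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, numeric(n), t(rbind(A_eq, A_in)),
                       c(numeric(nrow(A_eq)), b_in), meq = nrow(A_eq)),
    error = function(e) NULL)
  if (is.null(sol)) {
    # fall back to the stage-1 vertex if the QP is numerically intractable
    return(flux_solution(s1$fluxes, z, "optimal"))
  }
  v <- stats::setNames(sol$solution, model$rxns$id)
  flux_solution(v, sum(obj * v), "optimal")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux, holding the linear objective at a
#' fraction of its optimum (1.0 unless stated). With `objective_fraction =
#' NA` the objective constraint is omitted and the variability of the plain
#' flux polytope is reported.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param objective as in [fba()].
#' @param objective_fraction fraction of the optimum to enforce, or `NA`.
#' @param sense optimization sense of the objective.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$rxns$id, objective = NULL,
                objective_fraction = 1, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!is.na(objective_fraction)) {
    obj <- objective_vector(model, objective)
    s1 <- fba(model, objective, sense)
    if (s1$status != "optimal")
      stop("model infeasible; cannot run FVA (status ", s1$status, ")")
    model <- constrain_objective(model, obj, s1$objective,
                                 objective_fraction, sense)
  }
  i <- match(reactions, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction: ", reactions[is.na(i)][1])
  res <- vapply(i, function(j) {
    o <- numeric(nrow(model$rxns))
    o[j] <- 1
    lo <- solve_lp(o, model$S, model$rxns$lb, model$rxns$ub, sense = "min")
    hi <- solve_lp(o, model$S, model$rxns$lb, model$rxns$ub, sense = "max")
    if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal"))
      stop("FVA subproblem not optimal for reaction ", model$rxns$id[j])
    c(lo$objective, hi$objective)
  }, numeric(2))
  data.frame(reaction = reactions, min = res[1, ], max = res[2, ],
             stringsAsFactors = FALSE)
}

# tighten bounds so that obj'v stays within `fraction` of optimum z.
# For a single-reaction objective this is a plain bound update; otherwise an
# auxiliary constraint row with a slack column is appended.
constrain_objective <- function(model, obj, z, fraction, sense) {
  nz <- which(obj != 0)
  lim <- if (sense == "max") fraction * z else NA
  back <- 1e-9 * (1 + abs(z)) # round-off slack so the optimum stays feasible
  if (length(nz) == 1 && obj[nz] == 1) {
    if (sense == "max")
      model$rxns$lb[nz] <- max(model$rxns$lb[nz], fraction * z - back)
    else
      model$rxns$ub[nz] <- min(model$rxns$ub[nz], fraction * z +
                                 (1 - fraction) * abs(z) + back)
    return(model)
  }
  # general case: aux variable s = obj'v with its own bounds
  slack_id <- ".objective_value"
  S2 <- rbind(cbind(model$S, Matrix::Matrix(0, nrow(model$mets), 1)),
              c(obj, -1))
  tol <- 1e-9 * (1 + abs(z))
  if (sense == "max") bb <- c(fraction * z, z + tol)
  else bb <- c(z - tol, fraction * z + (1 - fraction) * abs(z))
  rx <- model$rxns
  rx[nrow(rx) + 1, c("id", "name", "gpr", "subsystem")] <-
    list(slack_id, slack_id, "", "")
  rx$lb[nrow(rx)] <- bb[1]
  rx$ub[nrow(rx)] <- bb[2]
  mets <- rbind(model$mets, data.frame(id = ".obj_balance",
                                       compartment = "", name = ".obj_balance",
                                       carbon = NA))
  out <- model
  out$mets <- mets
  out$rxns <- rx
  out$S <- S2
  dimnames(out$S) <- list(mets$id, rx$id)
  out
}

#' Test whether a model can realize an experimental growth rate
#'
#' Constrains the biomass objective to `mu * (1 - error)` ..
#' `mu * (1 + error)` and tests feasibility, reporting the model's
#' unconstrained achievable biomass range for diagnosis.
#'
#' @param model a `metabolic_model` (objective = biomass).
#' @param mu experimental growth rate, per hour; must be > 0.
#' @param error symmetric relative error band (default 0.2).
#' @return List with `feasible` (logical), `range` (unconstrained biomass
#'   min/max), and the applied `bounds`.
#' @export
check_growth_feasibility <- function(model, mu, error = 0.2) {
  if (!is.finite(mu) || mu <= 0) stop("growth rate must be positive")
  rng <- fva(model, model$objective, objective_fraction = NA)
  bio <- model$objective
  lo <- mu * (1 - error)
  hi <- mu * (1 + error)
  m2 <- model
  i <- match(bio, m2$rxns$id)
  m2$rxns$lb[i] <- max(m2$rxns$lb[i], lo)
  m2$rxns$ub[i] <- min(m2$rxns$ub[i], hi)
  feas <- m2$rxns$lb[i] <= m2$rxns$ub[i] && is_feasible(m2)
  list(feasible = feas, range = c(min = rng$min, max = rng$max),
       bounds = c(lb = lo, ub = hi))
}
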