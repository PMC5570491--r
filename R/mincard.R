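#' Candidate exchanges for metabolome completion
#'
#' All model exchanges not covered by the measured profile; these are the
#' exchanges whose activity the cardinality minimization may switch on.
#'
#' @param model a `metabolic_model`.
#' @param measured exchange reaction ids fixed by the measured profile.
#' @return Character vector of candidate exchange ids (lexicographic order,
#'   which also fixes the solver's tie-breaking).
#' @export
candidate_exchanges <- function(model, measured) {
  sort(setdiff(exchange_reactions(model), measured))
}

#' Minimize the number of unmeasured exchanges needed for feasibility
#'
#' The exchange-cardinality minimization: every candidate exchange is split
#' into nonnegative uptake and secretion components, the original candidate
#' columns are closed, and the one-norm of the candidate components is
#' minimized subject to steady state and the measured bounds (which include
#' the minimal-growth bound). The one-norm is the tractable relaxation of
#' the cardinality objective; with many independent constraints relative to
#' the solution support it recovers the true minimum with high probability,
#' and [verify_minimality_fva()] plus [brute_force_min_card()] check it on
#' small instances.
#'
#' @param model the constrained model (measured bounds applied).
#' @param candidates candidate exchange ids (see [candidate_exchanges()]).
#' @param active_tol component flux above which a candidate counts as
#'   active (default 1e-6 U).
#' @param cap upper bound on each unidirectional candidate component
#'   (default 2000 U, the medium default magnitude, keeping the LP bounded).
#' @return List with `active` (data.frame `exchange`, `direction`, `flux`),
#'   `solution` (a `flux_solution` on the original reactions, candidate net
#'   flux = secretion - uptake), `one_norm`, and diagnostic attributes
#'   `rank` (of the extended equality system) and `n_active_bounds`.
#' @export
min_exchange_cardinality <- function(model, candidates, active_tol = 1e-6,
                                     cap = 2000) {
  candidates <- sort(candidates)
  bad <- setdiff(candidates, exchange_reactions(model))
  if (length(bad)) stop("candidate is not an exchange reaction: ", bad[1])
  n <- nrow(model$rxns)
  S <- model$S
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  ci <- match(candidates, model$rxns$id)
  lb[ci] <- 0
  ub[ci] <- 0
  up_cols <- -S[, ci, drop = FALSE]
  sec_cols <- S[, ci, drop = FALSE]
  k <- length(candidates)
  up_ids <- if (k) paste0(candidates, "..uptake") else character(0)
  sec_ids <- if (k) paste0(candidates, "..secretion") else character(0)
  S_ext <- cbind(S, up_cols, sec_cols)
  colnames(S_ext) <- c(model$rxns$id, up_ids, sec_ids)
  lb_ext <- c(lb, rep(0, 2 * k))
  ub_ext <- c(ub, rep(cap, 2 * k))
  obj <- c(rep(0, n), rep(1, 2 * k))
  r <- solve_lp(obj, S_ext, lb_ext, ub_ext, sense = "min")
  if (!identical(r$status, "optimal")) {
    if (identical(r$status, "infeasible"))
      stop("profile unsatisfiable even with completed metabolome")
    stop("cardinality LP failed with status ", r$status)
  }
  ve <- r$fluxes[c(up_ids, sec_ids)]
  act <- which(ve > active_tol)
  active <- data.frame(
    exchange = sub("\\.\\.(uptake|secretion)$", "", names(ve)[act]),
    direction = sub("^.*\\.\\.", "", names(ve)[act]),
    flux = as.numeric(ve[act]), stringsAsFactors = FALSE)
  # an optimal one-norm solution never carries both directions of one
  # metabolite: that would add cost while cancelling in the balance
  if (anyDuplicated(active$exchange)) {
    active <- do.call(rbind, lapply(split(active, active$exchange),
                                    function(d) d[which.max(d$flux), ]))
  }
  active <- active[order(active$exchange), , drop = FALSE]
  rownames(active) <- NULL
  net <- r$fluxes[seq_len(n)]
  net[ci] <- r$fluxes[sec_ids] - r$fluxes[up_ids]
  names(net) <- model$rxns$id
  sol <- flux_solution(net, r$objective, "optimal")
  structure(list(active = active, solution = sol, one_norm = r$objective),
            rank = as.integer(Matrix::rankMatrix(S_ext)),
            n_active_bounds = sum(
              abs(r$fluxes[seq_len(n)] - lb) < 1e-9 & lb != 0 |
                abs(r$fluxes[seq_len(n)] - ub) < 1e-9 & ub != 0))
}

# model with candidates closed and the active directions opened
apply_active_set <- function(model, candidates, active, cap = 2000) {
  ci <- match(candidates, model$rxns$id)
  model$rxns$lb[ci] <- 0
  model$rxns$ub[ci] <- 0
  for (i in seq_len(nrow(active))) {
    j <- match(active$exchange[i], model$rxns$id)
    if (active$direction[i] == "uptake") model$rxns$lb[j] <- -cap
    else model$rxns$ub[j] <- cap
  }
  model
}

#' Verify minimality of the active exchange set and repair if needed
#'
#' With all non-active candidates closed, every active exchange must be
#' necessary: closing it alone must make the model infeasible. If a
#' removable exchange is found, it is permanently closed and the
#' cardinality minimization re-runs on the remaining candidates; the loop
#' repeats until the set is irreducible.
#'
#' @param model the constrained model (as passed to
#'   [min_exchange_cardinality()]).
#' @param candidates candidate exchange ids.
#' @param active the `active` data.frame from a previous minimization;
#'   recomputed when `NULL`.
#' @param active_tol,cap as in [min_exchange_cardinality()].
#' @param max_iter iteration cap (default 10).
#' @return List with `active` (verified), `iterations`, and `excluded`
#'   (candidates closed during verification).
#' @export
verify_minimality_fva <- function(model, candidates, active = NULL,
                                  active_tol = 1e-6, cap = 2000,
                                  max_iter = 10) {
  candidates <- sort(candidates)
  if (is.null(active))
    active <- min_exchange_cardinality(model, candidates, active_tol,
                                       cap)$active
  excluded <- character(0)
  iterations <- 1L
  repeat {
    m_act <- apply_active_set(model, candidates, active, cap)
    removable <- NULL
    for (i in seq_len(nrow(active))) {
      m2 <- set_bounds(m_act, active$exchange[i], lb = 0, ub = 0)
      if (is_feasible(m2)) {
        removable <- active$exchange[i]
        break
      }
    }
    if (is.null(removable)) break
    iterations <- iterations + 1L
    if (iterations > max_iter)
      stop("minimality verification exceeded ", max_iter,
           " iterations; remaining set: ",
           paste(active$exchange, collapse = ", "))
    excluded <- c(excluded, removable)
    candidates <- setdiff(candidates, removable)
    model <- set_bounds(model, removable, lb = 0, ub = 0)
    active <- min_exchange_cardinality(model, candidates, active_tol,
                                       cap)$active
  }
  list(active = active, iterations = iterations, excluded = excluded)
}

#' Exact minimum exchange cardinality by exhaustive enumeration
#'
#' Test oracle for the one-norm relaxation: enumerates candidate subsets in
#' order of increasing size and returns the size of the first subset whose
#' opening admits a feasible steady state. Only intended for small
#' instances.
#'
#' @param model the constrained model.
#' @param candidates candidate exchange ids.
#' @param cap bound magnitude for opened candidates.
#' @param max_candidates refuse larger instances (default 15).
#' @return List with `cardinality` and `witness` (one minimal subset).
#' @export
brute_force_min_card <- function(model, candidates, cap = 2000,
                                 max_candidates = 15) {
  candidates <- sort(candidates)
  if (length(candidates) > max_candidates)
    stop("brute force refused: ", length(candidates), " > ",
         max_candidates, " candidates")
  ci <- match(candidates, model$rxns$id)
  base <- model
  base$rxns$lb[ci] <- 0
  base$rxns$ub[ci] <- 0
  for (size in 0:length(candidates)) {
    subsets <- if (size == 0) list(integer(0))
               else utils::combn(length(candidates), size, simplify = FALSE)
    for (sub in subsets) {
      m2 <- base
      j <- ci[sub]
      m2$rxns$lb[j] <- -cap
      m2$rxns$ub[j] <- cap
      if (is_feasible(m2))
        return(list(cardinality = size, witness = candidates[sub]))
    }
  }
  stop("profile unsatisfiable even with completed metabolome")
}

#' Prune a model to its condition-specific form
#'
#' Removes unused (non-measured, non-active) exchanges, then removes all
#' blocked reactions — reactions unable to carry `|v| >= eps` in any
#' feasible steady state of the constrained model — and returns a
#' `condition_model` with full provenance. Pruning must preserve the
#' optimal biomass (relative tolerance 1e-6); a violation signals `eps` too
#' large and is an error.
#'
#' @param model the constrained model (measured bounds + minimal growth).
#' @param measured measured exchange ids (kept with their bounds).
#' @param active verified active set (data.frame `exchange`, `direction`).
#' @param eps blocked-reaction flux threshold (default 1e-4 U).
#' @param cap bound magnitude for opened active exchanges.
#' @param sample_id provenance label.
#' @return A `condition_model`: list with `model`, `sample_id`, `measured`,
#'   `added`, `removed_exchanges`, `removed_blocked`.
#' @export
prune_model <- function(model, measured, active, eps = 1e-4, cap = 2000,
                        sample_id = NA_character_) {
  candidates <- candidate_exchanges(model, measured)
  m2 <- apply_active_set(model, candidates, active, cap)
  ref_biomass <- fba(m2)$objective
  if (is.na(ref_biomass))
    stop("model infeasible before pruning")
  drop_ex <- setdiff(candidates, active$exchange)
  m2 <- remove_reactions(m2, drop_ex)
  blocked <- find_blocked_reactions(m2, eps)
  m3 <- remove_reactions(m2, blocked)
  new_biomass <- fba(m3)$objective
  if (is.na(new_biomass) ||
      abs(new_biomass - ref_biomass) > 1e-6 * (1 + abs(ref_biomass)))
    stop("pruning changed the biomass optimum (",
         format(ref_biomass), " -> ", format(new_biomass),
         "); eps too large?")
  structure(list(model = m3, sample_id = sample_id, measured = measured,
                 added = active$exchange,
                 removed_exchanges = drop_ex,
                 removed_blocked = blocked),
            class = "condition_model")
}

#' Find blocked internal reactions
#'
#' A reaction is blocked when it cannot carry an absolute flux of at least
#' `eps` in any feasible steady state of the model as constrained
#' (including the minimal-growth bound). Only net, non-exchange reactions
#' are scanned: exchanges are governed by the measured profile and the
#' cardinality minimization, not by blocked-reaction removal. The objective
#' reaction is never reported blocked.
#'
#' @param model a `metabolic_model`.
#' @param eps flux threshold (default 1e-4 U).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, eps = 1e-4) {
  internal <- setdiff(model$rxns$id,
                      c(exchange_reactions(model), model$objective))
  if (!length(internal)) return(character(0))
  rng <- fva(model, internal, objective_fraction = NA)
  rng$reaction[rng$max < eps & rng$min > -eps]
}

#' @export
print.condition_model <- function(x, ...) {
  cat("condition_model '", x$sample_id, "': ", nrow(x$model$rxns),
      " reactions (", length(x$measured), " measured exchanges, ",
      length(x$added), " added, ", length(x$removed_exchanges),
      " exchanges removed, ", length(x$removed_blocked),
      " blocked reactions removed)\n", sep = "")
  invisible(x)
}

#' Build a condition-specific model from one exchange profile
#'
#' The full pipeline: medium constraints, qualitative screening,
#' quantitative integration with rollback, exchange-cardinality
#' minimization with minimality verification, and pruning.
#'
#' @param model the global `metabolic_model`.
#' @param profile an `exchange_profile`.
#' @param mapping metabolite-to-exchange map.
#' @param config a [medium_config()].
#' @param allowance relative allowance on measured fluxes (default 0.2).
#' @param eps blocked-reaction threshold (default 1e-4).
#' @param active_tol active-component threshold (default 1e-6).
#' @return A `condition_model`; the integration ledger and verification
#'   report are attached as attributes `ledger` and `verification`.
#' @export
build_condition_model <- function(model, profile, mapping, config,
                                  allowance = 0.2, eps = 1e-4,
                                  active_tol = 1e-6) {
  m <- set_medium_constraints(model, config)
  res <- integrate_quantitative(m, profile, mapping, allowance)
  measured <- res$ledger$applied$exchange
  candidates <- candidate_exchanges(res$model, measured)
  ver <- verify_minimality_fva(res$model, candidates,
                               active_tol = active_tol,
                               cap = config$default_bound)
  cm <- prune_model(res$model, measured, ver$active, eps = eps,
                    cap = config$default_bound,
                    sample_id = profile$sample_id)
  attr(cm, "ledger") <- res$ledger
  attr(cm, "verification") <- ver
  cm
}
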