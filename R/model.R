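#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric matrix with flux
#' bounds, gene-protein-reaction (GPR) rules and an objective reaction
#' (typically biomass or ATP hydrolysis). All fluxes are carried in
#' U = fmol/cell/hr; with a unitary cell weight of 1e-12 g this coincides
#' numerically with mmol/gDW/hr, so models parameterized in the usual COBRA
#' unit need no rescaling.
#'
#' Exchange reactions are identified structurally as reactions touching a
#' single metabolite (boundary species omitted); negative flux is uptake,
#' positive is secretion.
#'
#' @param id model identifier.
#' @param mets data.frame with columns `id`, `compartment` (and optionally
#'   `name`, `carbon` — a logical marking carbon-bearing species, used by the
#'   glucose-only ATP sanity check).
#' @param rxns data.frame with columns `id`, `lb`, `ub` (and optionally
#'   `name`, `gpr`, `subsystem`).
#' @param S stoichiometric matrix (rows = metabolites in `mets` order,
#'   columns = reactions in `rxns` order); dense or sparse.
#' @param objective id of the objective reaction; must exist in `rxns`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, S, objective) {
  mets <- as.data.frame(mets)
  rxns <- as.data.frame(rxns)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$carbon)) mets$carbon <- NA
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- ""
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(mets$id, rxns$id)
  m <- structure(list(id = id, mets = mets, rxns = rxns, S = S,
                      objective = objective),
                 class = "metabolic_model")
  validate_metabolic_model(m)
  m
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks unique identifiers, finite nonzero stoichiometric coefficients,
#' finite bounds with `lb <= ub`, GPR parseability, and existence of the
#' objective reaction. Called by the constructor and by the model readers.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the offending element.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$mets$id))
    stop("duplicate metabolite id: ",
         model$mets$id[duplicated(model$mets$id)][1])
  if (anyDuplicated(model$rxns$id))
    stop("duplicate reaction id: ", model$rxns$id[duplicated(model$rxns$id)][1])
  if (!all(dim(model$S) == c(nrow(model$mets), nrow(model$rxns))))
    stop("stoichiometric matrix dimensions do not match mets/rxns tables")
  x <- as.numeric(as.matrix(model$S))
  if (any(!is.finite(x)))
    stop("stoichiometric coefficients must be finite and nonzero")
  bad <- !is.finite(model$rxns$lb) | !is.finite(model$rxns$ub)
  if (any(bad))
    stop("missing or non-finite bounds on reaction: ",
         model$rxns$id[bad][1], " (no silent defaults)")
  bad <- model$rxns$lb > model$rxns$ub
  if (any(bad))
    stop("lb > ub on reaction: ", model$rxns$id[bad][1])
  if (!model$objective %in% model$rxns$id)
    stop("objective reaction '", model$objective, "' not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", nrow(x$rxns), " reactions, ",
      nrow(x$mets), " metabolites, ", length(exchange_reactions(x)),
      " exchanges; objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Identify exchange reactions
#'
#' Exchange (boundary) reactions are exactly the reactions involving a single
#' metabolite, following the COBRA convention with the boundary species
#' omitted. Negative flux through an exchange is uptake, positive is
#' secretion.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$S != 0)
  model$rxns$id[nz == 1]
}

#' Metabolite carried by each exchange reaction
#'
#' @param model a `metabolic_model`.
#' @param exchanges exchange reaction ids (default: all).
#' @return Named character vector mapping exchange id to metabolite id.
#' @export
exchange_metabolites <- function(model, exchanges = exchange_reactions(model)) {
  out <- vapply(exchanges, function(r) {
    col <- model$S[, r]
    model$mets$id[which(col != 0)]
  }, character(1))
  out
}

#' Set flux bounds on reactions
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids.
#' @param lb,ub new bounds (recycled); `NULL` leaves the bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reactions, lb = NULL, ub = NULL) {
  i <- match(reactions, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction: ", reactions[is.na(i)][1])
  if (!is.null(lb)) model$rxns$lb[i] <- rep_len(lb, length(i))
  if (!is.null(ub)) model$rxns$ub[i] <- rep_len(ub, length(i))
  bad <- model$rxns$lb[i] > model$rxns$ub[i]
  if (any(bad)) stop("lb > ub on reaction: ", reactions[bad][1])
  model
}

#' Get reaction bounds as a two-column matrix
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (default all).
#' @return Matrix with columns `lb`, `ub`, rownames = reaction ids.
#' @export
get_bounds <- function(model, reactions = model$rxns$id) {
  i <- match(reactions, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction: ", reactions[is.na(i)][1])
  out <- cbind(lb = model$rxns$lb[i], ub = model$rxns$ub[i])
  rownames(out) <- reactions
  out
}

#' Remove reactions (and optionally orphaned metabolites) from a model
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to drop.
#' @param drop_orphans drop metabolites no longer used by any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, reactions, drop_orphans = TRUE) {
  if (!length(reactions)) return(model)
  i <- match(reactions, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction: ", reactions[is.na(i)][1])
  if (model$objective %in% reactions)
    stop("cannot remove the objective reaction")
  keep <- setdiff(seq_len(nrow(model$rxns)), i)
  model$rxns <- model$rxns[keep, , drop = FALSE]
  model$S <- model$S[, keep, drop = FALSE]
  if (drop_orphans) {
    used <- Matrix::rowSums(model$S != 0) > 0
    model$mets <- model$mets[used, , drop = FALSE]
    model$S <- model$S[used, , drop = FALSE]
  }
  rownames(model$rxns) <- NULL
  rownames(model$mets) <- NULL
  model
}

#' Genes appearing in the model's GPR rules
#'
#' @param model a `metabolic_model`.
#' @param collapse_transcripts merge transcript variants by stripping a
#'   trailing `.N` suffix (the `uniqueGene` convention).
#' @return Character vector of gene ids.
#' @export
model_genes <- function(model, collapse_transcripts = TRUE) {
  g <- unique(unlist(lapply(model$rxns$gpr, gpr_genes)))
  if (collapse_transcripts) g <- unique(sub("\\.\\d+$", "", g))
  sort(g)
}

# construct a flux_solution record
flux_solution <- function(fluxes, objective, status) {
  structure(list(fluxes = fluxes, objective = objective, status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: status =", x$status, "objective =",
      format(x$objective), "\n")
  invisible(x)
}
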