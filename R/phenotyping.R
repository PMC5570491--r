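#' Metabolite-centric flux splits
#'
#' For a target metabolite (or a group pooled across compartments), lists
#' every reaction producing it in the given flux vector — production flux
#' `P[i,j] = S[i,j] * v[j] > 0` — together with the total production and
#' each reaction's fractional share. Transport and exchange reactions are
#' excluded before summation: a reaction in which a target metabolite
#' appears on both sides (possibly in different compartments) shuttles
#' rather than produces, and exchanges only cross the boundary.
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_solution`, normally from [parsimonious_fba()]
#'   maximizing ATP production.
#' @param metabolites metabolite id(s) of the target group (e.g. all ATP
#'   species across compartments).
#' @param exclude additional reaction ids to exclude (mirrors a curated
#'   discard list; default none).
#' @return A `flux_split_report`: data.frame `reaction`, `production`,
#'   `share`, plus attributes `total` (Phi), `major` (major producer id,
#'   `NA` when production is zero), `excluded`, and `zero_production` flag.
#' @export
flux_splits <- function(model, solution, metabolites,
                        exclude = character(0)) {
  stopifnot(inherits(solution, "flux_solution"))
  mi <- match(metabolites, model$mets$id)
  if (anyNA(mi)) stop("unknown metabolite: ", metabolites[is.na(mi)][1])
  v <- solution$fluxes[model$rxns$id]
  Ssub <- model$S[mi, , drop = FALSE]
  ex <- exchange_reactions(model)
  # transport: a target metabolite (any compartment) on both reaction sides
  base_ids <- sub("\\[[^]]*\\]$|_[a-z]$", "", metabolites)
  transport <- vapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    ids <- sub("\\[[^]]*\\]$|_[a-z]$", "", model$mets$id[nz])
    tgt <- ids %in% base_ids
    any(tgt & col[nz] > 0) && any(tgt & col[nz] < 0)
  }, logical(1))
  excluded <- union(exclude, union(ex, model$rxns$id[transport]))
  # per-entry production P[i,j] = S[i,j] * v[j]; only positive terms count
  M <- sweep(as.matrix(Ssub), 2, as.numeric(v), `*`)
  P <- colSums(pmax(M, 0))
  P[model$rxns$id %in% excluded] <- 0
  prod_i <- which(P > 1e-12)
  total <- sum(P[prod_i])
  if (!length(prod_i) || total <= 0) {
    rep0 <- data.frame(reaction = character(0), production = numeric(0),
                       share = numeric(0))
    return(structure(rep0, class = c("flux_split_report", "data.frame"),
                     total = 0, major = NA_character_,
                     excluded = intersect(excluded, model$rxns$id),
                     zero_production = TRUE,
                     metabolites = metabolites))
  }
  ord <- prod_i[order(-P[prod_i], model$rxns$id[prod_i])]
  rep <- data.frame(reaction = model$rxns$id[ord],
                    production = as.numeric(P[ord]),
                    share = as.numeric(P[ord] / total),
                    stringsAsFactors = FALSE)
  structure(rep, class = c("flux_split_report", "data.frame"),
            total = total, major = rep$reaction[1],
            excluded = intersect(excluded, model$rxns$id),
            zero_production = FALSE, metabolites = metabolites)
}

#' ATP yield of a flux solution
#'
#' Total ATP production flux (the flux-split total over all ATP species,
#' transport/exchange excluded) divided by the absolute glucose uptake.
#' Other carbon sources stay allowed, so the yield may exceed the
#' glucose-only theoretical values (2 for aerobic glycolysis, 32 for full
#' oxidation).
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_solution` (parsimonious FBA maximizing ATP).
#' @param atp_metabolites ATP species ids (pooled across compartments).
#' @param glucose_exchange glucose exchange reaction id.
#' @param exclude extra reactions excluded from the production sum.
#' @return Scalar ATP yield (dimensionless, per glucose).
#' @export
atp_yield <- function(model, solution, atp_metabolites, glucose_exchange,
                      exclude = character(0)) {
  glc <- solution$fluxes[[glucose_exchange]]
  if (is.na(glc) || abs(glc) < 1e-12)
    stop("ATP yield undefined: zero glucose uptake in the solution")
  splits <- flux_splits(model, solution, atp_metabolites, exclude)
  attr(splits, "total") / abs(glc)
}

#' Default energy/cofactor subtype table
#'
#' Template mapping the (ATP, NADH, NADPH, FADH2) major-producer tuple to
#' the eight energy subtypes: glycolytic subtypes I-II differ only in the
#' FADH2 producer; OxPhos subtypes III/VI use dihydroceramide desaturase,
#' IV/VII cytosolic malic enzyme and V/VIII isocitrate dehydrogenase as the
#' leading NADPH source, with glyceraldehyde-3-phosphate dehydrogenase
#' versus 2-oxoglutarate dehydrogenase separating the more glycolytic from
#' the more oxidative members of each pair. Reaction identifiers are
#' reconstruction-specific, so the table is data a user can replace.
#'
#' @return data.frame with columns `subtype`, `atp`, `nadh`, `nadph`,
#'   `fadh2`.
#' @export
default_subtype_table <- function() {
  data.frame(
    subtype = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    atp = c("PGK", "PGK", rep("ATPS4m", 6)),
    nadh = c("GAPD", "GAPD", "GAPD", "GAPD", "GAPD",
             "AKGDm", "AKGDm", "AKGDm"),
    nadph = c("ICDHy", "ICDHy", "DESAT18_3", "ME2", "ICDHy",
              "DESAT18_3", "ME2", "ICDHy"),
    fadh2 = c("SUCD1m", "ETF", "SUCD1m", "SUCD1m", "SUCD1m",
              "SUCD1m", "SUCD1m", "SUCD1m"),
    stringsAsFactors = FALSE)
}

#' Classify the energy phenotype from major-producer reactions
#'
#' The energy class follows the identity of the major ATP producer:
#' phosphoglycerate kinase marks a glycolytic model, ATP synthase an OxPhos
#' model. The subtype (I-VIII) is looked up from the
#' (ATP, NADH, NADPH, FADH2) major-producer tuple; a tuple matching no row
#' is reported as `"unclassified"` together with the tuple. The ATP-yield
#' boundaries observed between the classes (4.21 and 7.26 in the study this
#' mirrors) are descriptive statistics, not the classifier.
#'
#' @param splits named list of `flux_split_report`s with elements `atp`,
#'   `nadh`, `nadph`, `fadh2`.
#' @param subtype_table producer-tuple table (default
#'   [default_subtype_table()]).
#' @param glycolytic_atp,oxphos_atp reaction ids identifying the two ATP
#'   producer classes.
#' @param yield optional ATP yield to carry through to the report.
#' @return A `phenotype_call`: list with `major` (named tuple),
#'   `energy_class`, `subtype`, `yield`.
#' @export
classify_energy_phenotype <- function(splits,
                                      subtype_table = default_subtype_table(),
                                      glycolytic_atp = "PGK",
                                      oxphos_atp = "ATPS4m",
                                      yield = NA_real_) {
  need <- c("atp", "nadh", "nadph", "fadh2")
  if (!all(need %in% names(splits)))
    stop("splits must contain reports named: ", paste(need, collapse = ", "))
  major <- vapply(splits[need], function(s) {
    m <- attr(s, "major")
    if (is.null(m) || is.na(m)) NA_character_ else m
  }, character(1))
  energy <- if (is.na(major[["atp"]])) "unclassified"
            else if (major[["atp"]] %in% glycolytic_atp) "glycolytic"
            else if (major[["atp"]] %in% oxphos_atp) "OxPhos"
            else "unclassified"
  hit <- which(subtype_table$atp == major[["atp"]] &
               subtype_table$nadh == major[["nadh"]] &
               subtype_table$nadph == major[["nadph"]] &
               subtype_table$fadh2 == major[["fadh2"]])
  subtype <- if (length(hit) == 1) subtype_table$subtype[hit]
             else "unclassified"
  structure(list(major = major, energy_class = energy, subtype = subtype,
                 yield = yield),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("phenotype_call:", x$energy_class, "(subtype", x$subtype,
      "); major producers:",
      paste(names(x$major), x$major, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Maximum ATP from glucose and oxygen only
#'
#' Sanity check on energy metabolism: closes the uptake of every
#' carbon-source exchange except glucose, opens all exchange upper bounds
#' (so secretion never limits), fixes glucose uptake to one unit, and
#' maximizes flux through the ATP hydrolysis reaction. On a model with
#' textbook stoichiometry this returns 32 with oxygen open and 2 with
#' oxygen closed; condition-specific models must not exceed the theoretical
#' measures.
#'
#' @param model a `metabolic_model` with an ATP hydrolysis reaction.
#' @param glucose_exchange glucose exchange id.
#' @param atp_reaction ATP hydrolysis reaction id.
#' @param carbon_exchanges exchanges to close for uptake; default: all
#'   exchanges whose metabolite is flagged `carbon` in `model$mets`
#'   (an error if the model carries no carbon annotation).
#' @param oxygen_bounds optional `(lb, ub)` override for the oxygen
#'   exchange, e.g. `c(0, 0)` to test anaerobic capacity.
#' @param oxygen_exchange oxygen exchange id (needed with
#'   `oxygen_bounds`).
#' @param glucose_uptake fixed uptake magnitude (default 1 U).
#' @param cap opened upper bound magnitude (default 2000 U).
#' @return ATP hydrolysis flux per unit glucose.
#' @export
max_atp_from_glucose <- function(model, glucose_exchange,
                                 atp_reaction = model$objective,
                                 carbon_exchanges = NULL,
                                 oxygen_bounds = NULL,
                                 oxygen_exchange = NULL,
                                 glucose_uptake = 1, cap = 2000) {
  if (!atp_reaction %in% model$rxns$id)
    stop("no ATP hydrolysis reaction '", atp_reaction, "' in model")
  ex <- exchange_reactions(model)
  if (is.null(carbon_exchanges)) {
    met <- exchange_metabolites(model, ex)
    flag <- model$mets$carbon[match(met, model$mets$id)]
    if (all(is.na(flag)))
      stop("model has no carbon annotation; pass carbon_exchanges")
    carbon_exchanges <- ex[!is.na(flag) & flag]
  }
  model <- set_bounds(model, ex, ub = cap)
  close_up <- setdiff(intersect(carbon_exchanges, ex), glucose_exchange)
  if (length(close_up)) model <- set_bounds(model, close_up, lb = 0)
  model <- set_bounds(model, glucose_exchange, lb = -glucose_uptake, ub = 0)
  if (!is.null(oxygen_bounds)) {
    if (is.null(oxygen_exchange))
      stop("oxygen_bounds given without oxygen_exchange")
    model <- set_bounds(model, oxygen_exchange, lb = oxygen_bounds[1],
                        ub = oxygen_bounds[2])
  }
  sol <- fba(model, atp_reaction, "max")
  if (sol$status != "optimal")
    stop("ATP sanity check infeasible (status ", sol$status, ")")
  glc <- sol$fluxes[[glucose_exchange]]
  if (abs(glc) < 1e-12) return(0)
  sol$objective / abs(glc)
}
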