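#' Phenotypic phase plane scan
#'
#' Fixes two exchange fluxes (`lb = ub = value`) on a grid and maximizes
#' biomass at every grid point. Default axis ranges follow the variability
#' of the measured constraints across the study conditions: oxygen 0 to
#' -1000 U, glucose 0 to -1080 U, glutamine 0 to -400 U, lactate 1620 to
#' 0 U, step 20 U. Infeasible points are flagged in the mask, never
#' reported as zero growth.
#'
#' @param model a `metabolic_model` (objective = biomass).
#' @param axis1,axis2 exchange reaction ids.
#' @param range1,range2 numeric `c(from, to)` fixed-flux ranges.
#' @param step grid step in U (> 0; applied to both axes).
#' @return A `phpp_grid`: list with `axis` (ids), `values1`, `values2`,
#'   `growth` (matrix, `NA` where infeasible), `feasible` (logical mask).
#' @export
phpp_scan <- function(model, axis1, axis2, range1, range2, step = 20) {
  if (!is.finite(step) || step <= 0) stop("step must be > 0")
  ex <- exchange_reactions(model)
  if (!axis1 %in% ex || !axis2 %in% ex)
    stop("both axes must be exchange reactions")
  vals1 <- seq(range1[1], range1[2],
               by = if (range1[2] >= range1[1]) step else -step)
  vals2 <- seq(range2[1], range2[2],
               by = if (range2[2] >= range2[1]) step else -step)
  growth <- matrix(NA_real_, length(vals1), length(vals2))
  for (a in seq_along(vals1)) {
    for (b in seq_along(vals2)) {
      m2 <- model
      i1 <- match(axis1, m2$rxns$id)
      i2 <- match(axis2, m2$rxns$id)
      m2$rxns$lb[c(i1, i2)] <- c(vals1[a], vals2[b])
      m2$rxns$ub[c(i1, i2)] <- c(vals1[a], vals2[b])
      sol <- fba(m2)
      if (sol$status == "optimal") growth[a, b] <- sol$objective
    }
  }
  structure(list(axis = c(axis1, axis2), values1 = vals1, values2 = vals2,
                 growth = growth, feasible = !is.na(growth)),
            class = "phpp_grid")
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat("phpp_grid:", x$axis[1], "x", x$axis[2], "(",
      length(x$values1), "x", length(x$values2), "points;",
      sum(x$feasible), "feasible)\n")
  invisible(x)
}

#' Classify a model's oxygen dependence (oxotype)
#'
#' Scans the oxygen exchange over `range` (fixed `lb = ub`) and records at
#' which uptake magnitudes the model still admits a feasible steady state
#' at the minimal-growth bound. Classes: `"low"` — feasible only at uptake
#' magnitudes below `split`; `"high"` — only above; `"indifferent"` —
#' feasible across the scanned range (or on both sides of `split`). The
#' boundary between low and high oxygen uptake is an interpretation, not a
#' measured constant; `split` defaults to the midpoint of the scanned range
#' and is configurable.
#'
#' @param model a `metabolic_model` with the minimal-growth bound in place.
#' @param oxygen_exchange oxygen exchange id.
#' @param range scanned fixed-flux range (default `c(0, -1000)`).
#' @param step scan step (default 20 U).
#' @param split uptake-magnitude threshold separating low from high
#'   (default: midpoint of the scanned magnitudes).
#' @return An `oxotype_call`: list with `class`, `feasible_interval`
#'   (magnitude range), `split`, `values`, `feasible`.
#' @export
classify_oxotype <- function(model, oxygen_exchange, range = c(0, -1000),
                             step = 20, split = NULL) {
  vals <- seq(range[1], range[2],
              by = if (range[2] >= range[1]) step else -step)
  i <- match(oxygen_exchange, model$rxns$id)
  if (is.na(i)) stop("unknown oxygen exchange: ", oxygen_exchange)
  feas <- vapply(vals, function(v) {
    m2 <- model
    m2$rxns$lb[i] <- v
    m2$rxns$ub[i] <- v
    is_feasible(m2)
  }, logical(1))
  if (!any(feas))
    stop("no feasible oxygen uptake in the scanned range; model broken")
  mag <- abs(vals)
  if (is.null(split)) split <- (min(mag) + max(mag)) / 2
  fmag <- mag[feas]
  cls <- if (all(feas)) "indifferent"
         else if (max(fmag) <= split) "low"
         else if (min(fmag) >= split) "high"
         else "indifferent"
  structure(list(class = cls,
                 feasible_interval = c(min(fmag), max(fmag)),
                 split = split, values = vals, feasible = feas),
            class = "oxotype_call")
}

#' @export
print.oxotype_call <- function(x, ...) {
  cat("oxotype:", x$class, "- feasible |vO2| in [",
      x$feasible_interval[1], ",", x$feasible_interval[2], "] (split",
      x$split, ")\n")
  invisible(x)
}

# growth after closing a set of reactions; biomass lower bound is relaxed so
# the knockout optimum is measurable even below the minimal-growth bound
knockout_growth <- function(model, closed) {
  i <- match(model$objective, model$rxns$id)
  model$rxns$lb[i] <- min(model$rxns$lb[i], 0)
  if (length(closed)) {
    j <- match(closed, model$rxns$id)
    model$rxns$lb[j] <- 0
    model$rxns$ub[j] <- 0
  }
  sol <- fba(model)
  if (sol$status != "optimal") 0 else sol$objective
}

deletion_class <- function(ko, wt) {
  ratio <- if (wt > 0) ko / wt else 0
  if (ratio < 0.05) "terminated"
  else if (ratio < 0.95) "reduced"
  else "unchanged"
}

#' Single-gene deletion screen
#'
#' For every gene (transcript variants collapsed to their base id, so all
#' isozyme transcripts of a gene are constrained at once), reactions whose
#' GPR rule evaluates false with the gene off are closed and biomass is
#' re-maximized with the minimal-growth bound relaxed. Classes relative to
#' the model's own wild-type maximum: `terminated` below 5%, `reduced`
#' between 5% and 95%, `unchanged` at or above 95%.
#'
#' @param model a `metabolic_model` with GPR rules.
#' @param genes genes to screen (default: all model genes, collapsed).
#' @return An `essentiality_report` data.frame: `gene`, `n_reactions_off`,
#'   `wild_type`, `knockout`, `class`.
#' @export
single_gene_deletion <- function(model, genes = NULL) {
  if (is.null(genes)) genes <- model_genes(model)
  wt <- knockout_growth(model, character(0))
  rows <- lapply(genes, function(g) {
    off <- vapply(model$rxns$gpr, function(r) !eval_gpr(r, g), logical(1))
    ko <- if (!any(off)) wt else knockout_growth(model, model$rxns$id[off])
    ko <- min(ko, wt) # knockout can never out-grow wild type
    data.frame(gene = g, n_reactions_off = sum(off), wild_type = wt,
               knockout = ko, class = deletion_class(ko, wt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("essentiality_report", "data.frame")
  out
}

#' Reaction essentiality screen
#'
#' Closes one reaction at a time and re-maximizes biomass, classifying with
#' the same 5%/95% thresholds as the gene screen. Used to resolve which of
#' an essential gene's reactions carry the essentiality.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to test.
#' @return An `essentiality_report` data.frame: `reaction`, `wild_type`,
#'   `knockout`, `class`.
#' @export
reaction_essentiality <- function(model, reactions) {
  i <- match(reactions, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction: ", reactions[is.na(i)][1])
  wt <- knockout_growth(model, character(0))
  rows <- lapply(reactions, function(r) {
    ko <- min(knockout_growth(model, r), wt)
    data.frame(reaction = r, wild_type = wt, knockout = ko,
               class = deletion_class(ko, wt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("essentiality_report", "data.frame")
  out
}

#' Detect obligate reductive carboxylation
#'
#' Flux variability of the isocitrate dehydrogenase / aconitase reactions
#' (forward = oxidative convention) at the minimal-growth bound, optionally
#' after clamping the oxygen exchange (e.g. `lb = ub = -100` U to emulate
#' restricted oxygenation). A reaction is `obligate_reverse` when its
#' entire feasible range is negative (net reductive flux is forced),
#' `forward_only` when entirely positive, and `optional` when the range
#' spans zero.
#'
#' @param model a `metabolic_model` with the minimal-growth bound in place.
#' @param reactions ids of the isocitrate dehydrogenase and aconitase
#'   reactions (oxidative direction positive).
#' @param oxygen_override optional `c(lb, ub)` clamp for the oxygen
#'   exchange.
#' @param oxygen_exchange oxygen exchange id (required with
#'   `oxygen_override`).
#' @param tol flux tolerance for calling a bound nonzero (default 1e-9).
#' @return data.frame `reaction`, `min`, `max`, `class`.
#' @export
detect_reductive_carboxylation <- function(model, reactions,
                                           oxygen_override = NULL,
                                           oxygen_exchange = NULL,
                                           tol = 1e-9) {
  if (!is.null(oxygen_override)) {
    if (is.null(oxygen_exchange))
      stop("oxygen_override given without oxygen_exchange")
    model <- set_bounds(model, oxygen_exchange, lb = oxygen_override[1],
                        ub = oxygen_override[2])
  }
  rng <- fva(model, reactions, objective_fraction = NA)
  rng$class <- ifelse(rng$max < -tol, "obligate_reverse",
                      ifelse(rng$min > tol, "forward_only", "optional"))
  rng
}
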