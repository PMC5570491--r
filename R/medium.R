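#' Medium configuration for the global model
#'
#' Collects the bound conventions applied before any sample-specific data:
#' the open default for every exchange, per-class uptake limits, the oxygen
#' window, closed uptakes for reactive oxygen species, and the
#' minimal-growth bound kept in the model throughout model building.
#'
#' Default magnitudes (in U = fmol/cell/hr): exchanges open at
#' `[-2000, 2000]`; ion uptake `-100`; vitamin uptake `-1`; essential amino
#' acid uptake `-10`; bulk compounds (water, protons) `-100`; oxygen
#' `[-1000, 0]`; superoxide/hydrogen peroxide uptake closed; biomass lower
#' bound `0.008`.
#'
#' @param classes named list mapping class label (`ions`, `vitamins`,
#'   `essential_aa`, `bulk`) to exchange reaction ids.
#' @param oxygen exchange id of the oxygen exchange (or `NULL`).
#' @param closed_uptake exchange ids whose uptake is closed (ROS species).
#' @param default_bound open default magnitude.
#' @param class_bounds named numeric of per-class uptake lower bounds.
#' @param oxygen_bounds oxygen `(lb, ub)`.
#' @param min_growth biomass lower bound.
#' @return A `medium_config` list.
#' @export
medium_config <- function(classes = list(), oxygen = NULL,
                          closed_uptake = character(0),
                          default_bound = 2000,
                          class_bounds = c(ions = -100, vitamins = -1,
                                           essential_aa = -10, bulk = -100),
                          oxygen_bounds = c(-1000, 0),
                          min_growth = 0.008) {
  if (!is.null(oxygen)) {
    stopifnot(oxygen_bounds[1] < 0, oxygen_bounds[2] == 0)
  }
  unknown <- setdiff(names(classes), names(class_bounds))
  if (length(unknown))
    stop("no bound defined for class: ", unknown[1])
  structure(list(classes = classes, oxygen = oxygen,
                 closed_uptake = closed_uptake,
                 default_bound = default_bound, class_bounds = class_bounds,
                 oxygen_bounds = oxygen_bounds, min_growth = min_growth),
            class = "medium_config")
}

#' Apply medium constraints to the global model
#'
#' Sets every exchange to the open default, then overrides per-class uptake
#' bounds, the oxygen window, and the closed ROS uptakes, and finally fixes
#' the biomass lower bound to the minimal-growth value. Class entries that
#' name a non-exchange reaction are an error.
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction.
#' @param config a [medium_config()].
#' @return The constrained model.
#' @export
set_medium_constraints <- function(model, config) {
  stopifnot(inherits(config, "medium_config"))
  ex <- exchange_reactions(model)
  listed <- c(unlist(config$classes, use.names = FALSE), config$oxygen,
              config$closed_uptake)
  bad <- setdiff(listed, ex)
  if (length(bad))
    stop("medium class entry is not an exchange reaction: ", bad[1])
  model <- set_bounds(model, ex, lb = -config$default_bound,
                      ub = config$default_bound)
  for (cl in names(config$classes)) {
    ids <- config$classes[[cl]]
    if (length(ids))
      model <- set_bounds(model, ids, lb = config$class_bounds[[cl]])
  }
  if (!is.null(config$oxygen))
    model <- set_bounds(model, config$oxygen, lb = config$oxygen_bounds[1],
                        ub = config$oxygen_bounds[2])
  if (length(config$closed_uptake))
    model <- set_bounds(model, config$closed_uptake, lb = 0)
  i <- match(model$objective, model$rxns$id)
  model$rxns$lb[i] <- config$min_growth
  model
}
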