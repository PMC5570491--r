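#' Allowance bounds around a measured flux
#'
#' Returns the `(lb, ub)` flux window for a measured rate `x` under a
#' relative allowance (default 20%): the interval spanned by `0.8 x` and
#' `1.2 x`, ordered so `lb <= ub` regardless of sign. For an uptake of
#' -860 U this gives `(-1032, -688)`: the 1.2-fold multiple becomes the
#' *lower* bound, matching the convention used when the measured rate is
#' negative.
#'
#' @param x measured flux in U (negative = uptake).
#' @param allowance relative allowance fraction (default 0.2).
#' @return Numeric `c(lb, ub)`.
#' @examples
#' allowance_bounds(-860)  # -1032, -688
#' allowance_bounds(32.35) # 25.88, 38.82
#' @export
allowance_bounds <- function(x, allowance = 0.2) {
  stopifnot(is.finite(x), is.finite(allowance), allowance >= 0)
  lo <- (1 - allowance) * x
  hi <- (1 + allowance) * x
  c(lb = min(lo, hi), ub = max(lo, hi))
}

#' Screen profiled metabolites for qualitative exchange feasibility
#'
#' A profiled metabolite's uptake (resp. secretion) is usable iff the model
#' stays feasible while that exchange is forced to carry a small flux in the
#' corresponding direction (uptake: `ub = -eps`; secretion: `lb = +eps`).
#' Directions that cannot carry flux — no catabolic or anabolic route in the
#' network — are discarded before quantitative integration.
#'
#' @param model the medium-constrained global model (must be feasible).
#' @param profile an `exchange_profile`.
#' @param mapping metabolite-to-exchange map (data.frame `metabolite`,
#'   `exchange`).
#' @param eps screening flux magnitude in U (default 1e-4).
#' @return List with `uptake` and `secretion` (usable metabolite ids),
#'   `discarded` (data.frame `metabolite`, `direction`), and `unmapped`.
#' @export
screen_qualitative_exchanges <- function(model, profile, mapping,
                                         eps = 1e-4) {
  if (!is_feasible(model))
    stop("model infeasible under medium constraints before screening")
  mets <- names(profile$entries)
  idx <- match(mets, mapping$metabolite)
  unmapped <- mets[is.na(idx)]
  usable_up <- character(0)
  usable_sec <- character(0)
  disc <- list()
  for (k in which(!is.na(idx))) {
    met <- mets[k]
    ex <- mapping$exchange[idx[k]]
    i <- match(ex, model$rxns$id)
    if (is.na(i)) {
      unmapped <- c(unmapped, met)
      next
    }
    lb0 <- model$rxns$lb[i]
    ub0 <- model$rxns$ub[i]
    # uptake: force v <= -eps
    m2 <- model
    m2$rxns$lb[i] <- min(lb0, -eps)
    m2$rxns$ub[i] <- -eps
    up_ok <- is_feasible(m2)
    # secretion: force v >= +eps
    m2 <- model
    m2$rxns$lb[i] <- eps
    m2$rxns$ub[i] <- max(ub0, eps)
    sec_ok <- is_feasible(m2)
    if (up_ok) usable_up <- c(usable_up, met)
    if (sec_ok) usable_sec <- c(usable_sec, met)
    if (!up_ok && !sec_ok) disc[[met]] <- "both"
    else if (!up_ok) disc[[met]] <- "uptake"
    else if (!sec_ok) disc[[met]] <- "secretion"
  }
  discarded <- data.frame(metabolite = names(disc),
                          direction = unlist(disc, use.names = FALSE),
                          stringsAsFactors = FALSE)
  if (!nrow(discarded))
    discarded <- data.frame(metabolite = character(0),
                            direction = character(0))
  list(uptake = usable_up, secretion = usable_sec, discarded = discarded,
       unmapped = unique(unmapped))
}

#' Integrate one sample's quantitative exchange fluxes
#'
#' Applies each measured flux as an allowance window on its exchange
#' reaction, one metabolite at a time in profile order. After each
#' application the model is checked for a feasible steady state at the
#' minimal-growth bound (which is already part of the model's bounds); on
#' infeasibility the pair's previous bounds are restored and the rollback is
#' logged. Zero-valued entries are flagged and skipped, and directions the
#' qualitative screen discarded are not applied.
#'
#' @param model the medium-constrained global model.
#' @param profile an `exchange_profile`.
#' @param mapping metabolite-to-exchange map.
#' @param allowance relative allowance (default 0.2).
#' @param screen result of [screen_qualitative_exchanges()]; computed here
#'   when `NULL`.
#' @return List with `model` (constrained) and `ledger`, a
#'   `constraint_ledger` with `applied`, `restored`,
#'   `discarded_qualitative`, `unmapped`, `zero_flagged`, and the
#'   application `order`.
#' @export
integrate_quantitative <- function(model, profile, mapping, allowance = 0.2,
                                   screen = NULL) {
  if (is.null(screen))
    screen <- screen_qualitative_exchanges(model, profile, mapping)
  if (!is_feasible(model))
    stop("model infeasible before quantitative integration")
  applied <- list()
  restored <- list()
  mets <- names(profile$entries)
  for (met in mets) {
    x <- profile$entries[[met]]
    ex <- mapping$exchange[match(met, mapping$metabolite)]
    if (is.na(ex) || !ex %in% model$rxns$id) next
    if (x == 0) next
    dir <- if (x < 0) "uptake" else "secretion"
    usable <- if (dir == "uptake") met %in% screen$uptake
              else met %in% screen$secretion
    if (!usable) next
    b <- allowance_bounds(x, allowance)
    i <- match(ex, model$rxns$id)
    old <- c(model$rxns$lb[i], model$rxns$ub[i])
    model$rxns$lb[i] <- b[["lb"]]
    model$rxns$ub[i] <- b[["ub"]]
    if (is_feasible(model)) {
      applied[[met]] <- data.frame(metabolite = met, exchange = ex,
                                   lb = b[["lb"]], ub = b[["ub"]],
                                   stringsAsFactors = FALSE)
    } else {
      model$rxns$lb[i] <- old[1]
      model$rxns$ub[i] <- old[2]
      restored[[met]] <- data.frame(metabolite = met, exchange = ex,
                                    reason = "growth check infeasible",
                                    stringsAsFactors = FALSE)
    }
  }
  if (!is_feasible(model))
    stop("model infeasible even after rollback of all conflicting pairs")
  ledger <- structure(
    list(sample_id = profile$sample_id,
         applied = do.call(rbind, c(applied, list(
           data.frame(metabolite = character(0), exchange = character(0),
                      lb = numeric(0), ub = numeric(0))))),
         restored = do.call(rbind, c(restored, list(
           data.frame(metabolite = character(0), exchange = character(0),
                      reason = character(0))))),
         discarded_qualitative = screen$discarded,
         unmapped = screen$unmapped,
         zero_flagged = profile$zero_entries,
         order = mets),
    class = "constraint_ledger")
  list(model = model, ledger = ledger)
}

#' @export
print.constraint_ledger <- function(x, ...) {
  cat("constraint_ledger '", x$sample_id, "': ", nrow(x$applied),
      " applied, ", nrow(x$restored), " restored, ",
      nrow(x$discarded_qualitative), " discarded (qualitative), ",
      length(x$unmapped), " unmapped, ", length(x$zero_flagged),
      " zero-flagged\n", sep = "")
  invisible(x)
}
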