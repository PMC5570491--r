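#' Split reversible reactions into unidirectional pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' (`<id>_f`, bounds `[max(lb,0), max(ub,0)]`... more precisely the positive
#' parts) and a reverse copy (`<id>_r`, negated column, bounds from the
#' negative part), so that all returned reactions have nonnegative lower
#' bounds and the net flux of the original reaction equals
#' `forward - reverse`. Irreversible reactions pass through unchanged.
#'
#' @param model a `metabolic_model`.
#' @return List with `model` (the split model) and `backmap`, a data.frame
#'   with columns `original`, `forward`, `reverse` (`NA` where no reverse
#'   copy exists) consumed by [merge_split_fluxes()].
#' @export
split_reversible <- function(model) {
  rxns <- model$rxns
  rev_i <- which(rxns$lb < 0)
  backmap <- data.frame(original = rxns$id, forward = rxns$id,
                        reverse = NA_character_, stringsAsFactors = FALSE)
  if (!length(rev_i)) return(list(model = model, backmap = backmap))
  S <- model$S
  new_cols <- list()
  for (i in rev_i) {
    id <- rxns$id[i]
    fwd <- paste0(id, "_f")
    rev <- paste0(id, "_r")
    backmap$forward[backmap$original == id] <- fwd
    backmap$reverse[backmap$original == id] <- rev
    new_cols[[fwd]] <- list(col = S[, id], lb = max(rxns$lb[i], 0),
                            ub = max(rxns$ub[i], 0), from = i)
    new_cols[[rev]] <- list(col = -S[, id], lb = max(-rxns$ub[i], 0),
                            ub = -rxns$lb[i], from = i)
  }
  keep <- setdiff(seq_len(nrow(rxns)), rev_i)
  S_new <- cbind(S[, keep, drop = FALSE],
                 do.call(cbind, lapply(new_cols, `[[`, "col")))
  colnames(S_new) <- c(rxns$id[keep], names(new_cols))
  tmpl <- rxns[c(keep, vapply(new_cols, `[[`, 1L, "from")), , drop = FALSE]
  tmpl$id <- colnames(S_new)
  tmpl$lb <- c(rxns$lb[keep], vapply(new_cols, `[[`, numeric(1), "lb"))
  tmpl$ub <- c(rxns$ub[keep], vapply(new_cols, `[[`, numeric(1), "ub"))
  objective <- model$objective
  if (!objective %in% tmpl$id) objective <- paste0(objective, "_f")
  out <- metabolic_model(model$id, model$mets, tmpl, S_new, objective)
  list(model = out, backmap = backmap)
}

#' Recombine fluxes of a split model into net original fluxes
#'
#' @param fluxes named flux vector of a model produced by
#'   [split_reversible()].
#' @param backmap the `backmap` component returned by [split_reversible()].
#' @return Named net flux vector on the original reaction ids
#'   (`forward - reverse`).
#' @export
merge_split_fluxes <- function(fluxes, backmap) {
  fwd <- fluxes[backmap$forward]
  rev <- ifelse(is.na(backmap$reverse), 0, fluxes[backmap$reverse])
  stats::setNames(as.numeric(fwd) - as.numeric(rev), backmap$original)
}
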