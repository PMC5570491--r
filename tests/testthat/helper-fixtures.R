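# helpers shared across the suite

# minimal 3-reaction network: one exchange, one transport, one demand
make_mini_model <- function() {
  mets <- data.frame(id = c("a_e", "a_c"), compartment = c("e", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_a", "At", "DM_a"),
                     lb = c(-10, 0, 0), ub = c(0, 10, 10),
                     gpr = c("", "gT1 or gT2", ""),
                     stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0,
                -1, 1,
                0, -1), nrow = 2,
              dimnames = list(mets$id, rxns$id))
  metabolic_model("mini", mets, rxns, S, "DM_a")
}

# random mass-balanced toy: a chain of metabolites with reversible internal
# conversions, one uptake and one secretion; always feasible (v = 0 works)
make_random_chain_model <- function(n_mets, seed) {
  set.seed(seed)
  ids <- paste0("m", seq_len(n_mets))
  mets <- data.frame(id = ids, compartment = "c", stringsAsFactors = FALSE)
  rxn_ids <- c("EX_in", "EX_out",
               paste0("R", seq_len(n_mets - 1)))
  S <- matrix(0, n_mets, length(rxn_ids),
              dimnames = list(ids, rxn_ids))
  S[1, "EX_in"] <- -1
  S[n_mets, "EX_out"] <- -1
  for (k in seq_len(n_mets - 1)) {
    S[k, paste0("R", k)] <- -1
    S[k + 1, paste0("R", k)] <- round(stats::runif(1, 0.5, 2), 2)
  }
  lb <- c(-round(stats::runif(1, 1, 10), 2), 0,
          ifelse(stats::runif(n_mets - 1) < 0.5, -5, 0))
  ub <- c(0, round(stats::runif(1, 5, 20), 2), rep(5, n_mets - 1))
  rxns <- data.frame(id = rxn_ids, lb = lb, ub = ub,
                     stringsAsFactors = FALSE)
  metabolic_model(paste0("chain", seed), mets, rxns, S, "EX_out")
}

expect_steady_state <- function(model, fluxes, tol = 1e-8) {
  resid <- max(abs(as.matrix(model$S) %*% fluxes[model$rxns$id]))
  expect_lt(resid, tol)
  expect_true(all(fluxes[model$rxns$id] >= model$rxns$lb - 1e-8))
  expect_true(all(fluxes[model$rxns$id] <= model$rxns$ub + 1e-8))
}

# close all candidates, then reopen the verified active directions
apply_active_set_for_test <- function(model, candidates, active,
                                      cap = 2000) {
  model <- set_bounds(model, candidates, lb = 0, ub = 0)
  for (i in seq_len(nrow(active))) {
    if (active$direction[i] == "uptake")
      model <- set_bounds(model, active$exchange[i], lb = -cap)
    else
      model <- set_bounds(model, active$exchange[i], ub = cap)
  }
  model
}

write_profile_tsv <- function(path, mets, samples) {
  tab <- data.frame(metabolite = mets, samples, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
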