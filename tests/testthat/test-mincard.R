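test_that("cardinality minimization recovers a forced single exchange", {
  fx <- make_exchange_completion_fixture(3, 1, 7)
  mc <- min_exchange_cardinality(fx$model, fx$candidates)
  expect_equal(sort(mc$active$exchange), fx$truth)
  expect_equal(nrow(mc$active), 1)
  # the flux vector satisfies all constraints of the extended system
  expect_identical(mc$solution$status, "optimal")
  v <- mc$solution$fluxes
  resid <- max(abs(as.matrix(fx$model$S) %*% v[fx$model$rxns$id]))
  expect_lt(resid, 1e-8)
})

test_that("a model feasible on measured exchanges alone needs no additions", {
  fx <- make_exchange_completion_fixture(5, 0, 13)
  mc <- min_exchange_cardinality(fx$model, fx$candidates)
  expect_equal(nrow(mc$active), 0)
  expect_equal(brute_force_min_card(fx$model, fx$candidates)$cardinality, 0)
})

test_that("uptake and secretion of one metabolite are never both active", {
  for (seed in c(3, 17, 29)) {
    fx <- make_exchange_completion_fixture(8, 3, seed)
    mc <- min_exchange_cardinality(fx$model, fx$candidates)
    expect_false(anyDuplicated(mc$active$exchange) > 0)
  }
})

test_that("brute-force oracle refuses oversized instances and bounds the relaxation", {
  fx <- make_exchange_completion_fixture(6, 2, 5)
  expect_error(brute_force_min_card(fx$model, fx$candidates,
                                    max_candidates = 3), "refused")
  bf <- brute_force_min_card(fx$model, fx$candidates)
  mc <- min_exchange_cardinality(fx$model, fx$candidates)
  expect_lte(bf$cardinality, nrow(mc$active))
  expect_equal(bf$cardinality, 2)
})

test_that("an unsatisfiable profile is a loud error", {
  fx <- make_exchange_completion_fixture(4, 2, 11)
  m <- fx$model
  # close every candidate for good and demand growth: nothing can fix this
  m <- set_bounds(m, fx$candidates, lb = 0, ub = 0)
  expect_error(min_exchange_cardinality(m, character(0)),
               "unsatisfiable")
})

test_that("minimality verification eliminates the one-norm artifact", {
  rf <- make_redundant_completion_fixture()
  mc <- min_exchange_cardinality(rf$model, rf$candidates)
  expect_equal(nrow(mc$active), 2)  # the one-norm optimum is not minimal
  ver <- verify_minimality_fva(rf$model, rf$candidates, mc$active)
  expect_equal(nrow(ver$active), rf$truth_cardinality)
  expect_equal(ver$active$exchange, "EX_q")
  expect_equal(ver$iterations, 2)
  expect_lte(nrow(ver$active), nrow(mc$active)) # never grows

  # an already-minimal set is returned unchanged in one iteration
  fx <- make_exchange_completion_fixture(5, 2, 21)
  mc2 <- min_exchange_cardinality(fx$model, fx$candidates)
  ver2 <- verify_minimality_fva(fx$model, fx$candidates, mc2$active)
  expect_equal(ver2$iterations, 1)
  expect_equal(sort(ver2$active$exchange), sort(mc2$active$exchange))
})

test_that("verified cardinality equals the brute-force oracle across seeds", {
  combos <- expand.grid(n_c = c(4, 6, 8), n_r = 0:2, seed = c(1, 2))
  for (i in seq_len(nrow(combos))) {
    fx <- make_exchange_completion_fixture(combos$n_c[i], combos$n_r[i],
                                           combos$seed[i] + 100 * i)
    ver <- verify_minimality_fva(fx$model, fx$candidates)
    bf <- brute_force_min_card(fx$model, fx$candidates)
    expect_equal(nrow(ver$active), bf$cardinality,
                 info = sprintf("n_c=%d n_r=%d seed=%d", combos$n_c[i],
                                combos$n_r[i], combos$seed[i] + 100 * i))
    expect_equal(bf$cardinality, combos$n_r[i])
  }
})

test_that("repeated runs return the same active set", {
  fx <- make_exchange_completion_fixture(8, 3, 19)
  a1 <- min_exchange_cardinality(fx$model, fx$candidates)$active
  a2 <- min_exchange_cardinality(fx$model, fx$candidates)$active
  expect_identical(a1, a2)
})

test_that("pruning drops dead branches but preserves the optima", {
  # aerobic toy plus a dead-end branch: pyruvate to a metabolite without sink
  m <- make_toy_aerobic()
  mets2 <- rbind(m$mets, data.frame(id = "x_c", compartment = "c",
                                    name = "x_c", carbon = TRUE))
  S2 <- rbind(m$S, Matrix::Matrix(0, 1, nrow(m$rxns), sparse = TRUE))
  S2 <- cbind(S2, Matrix::Matrix(0, nrow(mets2), 1, sparse = TRUE))
  S2[c("pyr_c"), nrow(m$rxns) + 1] <- -1
  S2[nrow(mets2), nrow(m$rxns) + 1] <- 1
  rxns2 <- rbind(m$rxns, data.frame(id = "XDEAD", name = "XDEAD", lb = 0,
                                    ub = 2000, gpr = "", subsystem = ""))
  m2 <- metabolic_model("aerobic_dead", mets2, rxns2, S2, m$objective)

  measured <- exchange_reactions(m2)   # treat all exchanges as measured
  active <- data.frame(exchange = character(0), direction = character(0),
                       flux = numeric(0))
  before <- fba(m2)$objective
  cm <- prune_model(m2, measured, active, sample_id = "s1")
  expect_true("XDEAD" %in% cm$removed_blocked)
  expect_false("XDEAD" %in% cm$model$rxns$id)
  expect_false("x_c" %in% cm$model$mets$id)
  expect_equal(fba(cm$model)$objective, before,
               tolerance = 1e-6 * (1 + abs(before)))

  # a model with nothing blocked passes through unchanged
  g <- make_toy_glycolysis()
  cmg <- prune_model(g, exchange_reactions(g), active, sample_id = "s2")
  expect_setequal(cmg$model$rxns$id, g$rxns$id)
  expect_length(cmg$removed_blocked, 0)
})

test_that("the full pipeline yields a clean condition-specific model", {
  fx <- make_exchange_completion_fixture(6, 2, 9)
  ver <- verify_minimality_fva(fx$model, fx$candidates)
  cm <- prune_model(fx$model, fx$measured, ver$active,
                    sample_id = fx$profile$sample_id)
  # every surviving exchange is measured or completion-added
  kept_ex <- exchange_reactions(cm$model)
  expect_true(all(kept_ex %in% c(fx$measured, cm$added)))
  # no surviving reaction is blocked
  expect_length(find_blocked_reactions(cm$model), 0)
  # the pruned model grows at the minimal-growth bound
  sol <- fba(cm$model)
  expect_identical(sol$status, "optimal")
  expect_gte(sol$objective, 0.008 - 1e-9)
})
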