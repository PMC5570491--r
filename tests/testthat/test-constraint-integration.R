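rc_medium <- function() {
  medium_config(oxygen = "EX_o2", min_growth = 0.008)
}

test_that("medium constraints apply defaults, class overrides and ROS closure", {
  m <- make_toy_rc_loop()
  cfg <- medium_config(
    classes = list(ions = "EX_byp"), # stand-in exchange for the class bound
    oxygen = "EX_o2",
    closed_uptake = "EX_co2",
    min_growth = 0.008)
  mm <- set_medium_constraints(m, cfg)
  expect_equal(drop(unname(get_bounds(mm, "EX_byp"))), c(-100, 2000))
  expect_equal(drop(unname(get_bounds(mm, "EX_o2"))), c(-1000, 0))
  expect_equal(drop(unname(get_bounds(mm, "EX_co2"))), c(0, 2000))
  expect_equal(drop(unname(get_bounds(mm, "EX_glc"))), c(-2000, 2000))
  i <- match(mm$objective, mm$rxns$id)
  expect_equal(mm$rxns$lb[i], 0.008)

  # a class entry naming a non-exchange reaction is an error
  bad <- medium_config(classes = list(ions = "GLS"), oxygen = "EX_o2")
  expect_error(set_medium_constraints(m, bad), "not an exchange")
  # oxygen invariant: lb < 0, ub = 0
  expect_error(medium_config(oxygen = "EX_o2", oxygen_bounds = c(10, 0)))
})

test_that("allowance bounds order correctly for both flux signs", {
  expect_equal(unname(allowance_bounds(-860)), c(-1032, -688))
  expect_equal(unname(allowance_bounds(32.35)), c(25.880, 38.82))
  expect_equal(unname(allowance_bounds(-304.27)), c(-365.124, -243.416))
  expect_equal(unname(allowance_bounds(0)), c(0, 0))
  # odd symmetry: bounds(-x) is the reversed negation of bounds(x)
  for (x in c(0.5, 13.87, 860, 1345.14)) {
    b <- allowance_bounds(x)
    nb <- allowance_bounds(-x)
    expect_equal(unname(nb), unname(-rev(b)))
    expect_lte(nb[["lb"]], nb[["ub"]])
  }
})

test_that("qualitative screening discards directions the network cannot carry", {
  # custom toy: 'u' consumable only, 's' producible only, 'dead' disconnected,
  # 'both' transportable in both directions with source and sink
  mets <- data.frame(
    id = c("u_e", "u_c", "s_e", "s_c", "dead_e", "both_e", "both_c", "w_e"),
    compartment = c("e", "c", "e", "c", "e", "e", "c", "e"))
  rxns <- data.frame(
    id = c("EX_u", "EX_s", "EX_dead", "EX_both", "EX_w", "Ut", "St", "Bt",
           "CAT", "SRC", "BSINK", "BSRC", "BIO"),
    lb = c(-2000, -2000, -2000, -2000, -2000, 0, 0, -2000, 0, 0, 0, 0, 0),
    ub = rep(2000, 13))
  S <- Matrix::Matrix(0, nrow(mets), nrow(rxns),
                      dimnames = list(mets$id, rxns$id), sparse = TRUE)
  S["u_e", "EX_u"] <- -1
  S["s_e", "EX_s"] <- -1
  S["dead_e", "EX_dead"] <- -1
  S["both_e", "EX_both"] <- -1
  S["w_e", "EX_w"] <- -1
  S["u_e", "Ut"] <- -1; S["u_c", "Ut"] <- 1      # uptake only
  S["s_c", "St"] <- -1; S["s_e", "St"] <- 1      # secretion only
  S["both_e", "Bt"] <- -1; S["both_c", "Bt"] <- 1 # reversible
  S["u_c", "CAT"] <- -1; S["w_e", "CAT"] <- 1     # u catabolized to waste
  S["s_c", "SRC"] <- 1                            # s produced from nothing? no:
  S["u_c", "SRC"] <- -1                           # ... from u
  S["both_c", "BSINK"] <- -1; S["w_e", "BSINK"] <- 1
  S["u_c", "BSRC"] <- -1; S["both_c", "BSRC"] <- 1
  S["w_e", "BIO"] <- -1
  m <- metabolic_model("screenToy", mets, as.data.frame(rxns), S, "BIO")
  prof <- exchange_profile("s1", c(u_e = -5, s_e = 2, dead_e = -1,
                                   both_e = 1))
  map <- data.frame(metabolite = c("u_e", "s_e", "dead_e", "both_e"),
                    exchange = c("EX_u", "EX_s", "EX_dead", "EX_both"))
  scr <- screen_qualitative_exchanges(m, prof, map)
  expect_true("u_e" %in% scr$uptake)
  expect_false("u_e" %in% scr$secretion)   # no anabolic route back out
  expect_true("s_e" %in% scr$secretion)
  expect_false("s_e" %in% scr$uptake)      # no catabolic route in
  expect_true("both_e" %in% scr$uptake)
  expect_true("both_e" %in% scr$secretion)
  expect_equal(scr$discarded$direction[scr$discarded$metabolite == "dead_e"],
               "both")
})

test_that("quantitative integration applies pairs in order and rolls back conflicts", {
  m <- set_medium_constraints(make_toy_rc_loop(), rc_medium())
  map <- exchange_map_from_model(m)

  # compatible pairs: everything applied, nothing restored
  prof <- make_synthetic_profile(m, c("EX_glc", "EX_gln", "EX_byp"),
                                 noise = 0, seed = 2)
  res <- integrate_quantitative(m, prof, map)
  expect_equal(nrow(res$ledger$applied), 3)
  expect_equal(nrow(res$ledger$restored), 0)

  # after integration the model still reaches the minimal-growth bound
  sol <- fba(res$model)
  expect_identical(sol$status, "optimal")
  expect_gte(sol$objective, 0.008 - 1e-9)

  # a pair that conflicts with an earlier one by mass balance is restored
  prof2 <- make_synthetic_profile(m, c("EX_glc", "EX_gln", "EX_byp"),
                                  noise = 0, seed = 2, corrupt = "EX_byp")
  res2 <- integrate_quantitative(m, prof2, map)
  expect_equal(res2$ledger$restored$exchange, "EX_byp")
  expect_true(is_feasible(res2$model))
  # ...and with the conflicting pair first, the conflict lands elsewhere:
  # applied + restored still partition the usable entries
  expect_equal(nrow(res2$ledger$applied) + nrow(res2$ledger$restored), 3)

  # ledger partition holds in the clean case too
  usable <- sum(names(prof$entries) %in%
                  c(res$ledger$applied$metabolite,
                    res$ledger$restored$metabolite))
  expect_equal(nrow(res$ledger$applied) + nrow(res$ledger$restored), usable)
})

test_that("screening is conservative: usable directions can carry flux", {
  m <- set_medium_constraints(make_toy_rc_loop(), rc_medium())
  map <- exchange_map_from_model(m)
  prof <- make_synthetic_profile(m, c("EX_glc", "EX_gln", "EX_byp"),
                                 noise = 0, seed = 4)
  scr <- screen_qualitative_exchanges(m, prof, map)
  for (met in scr$uptake) {
    ex <- map$exchange[map$metabolite == met]
    m2 <- set_bounds(m, ex, lb = -2000, ub = -1e-4)
    expect_true(is_feasible(m2))
  }
  for (met in scr$secretion) {
    ex <- map$exchange[map$metabolite == met]
    m2 <- set_bounds(m, ex, lb = 1e-4, ub = 2000)
    expect_true(is_feasible(m2))
  }
})
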