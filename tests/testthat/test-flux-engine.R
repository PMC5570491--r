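test_that("FBA solves toy networks and detects infeasibility", {
  g <- make_toy_glycolysis()
  sol <- fba(g)
  expect_identical(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  expect_steady_state(g, sol$fluxes)

  closed <- set_bounds(g, exchange_reactions(g), lb = 0, ub = 0)
  sol0 <- fba(closed)
  expect_true(sol0$status == "infeasible" ||
                abs(sol0$objective) < 1e-9)

  # LP monotonicity: tightening a bound never raises a maximization optimum
  for (seed in 1:5) {
    m <- make_random_chain_model(5, seed)
    base <- fba(m)$objective
    i <- sample(nrow(m$rxns), 1)
    m2 <- m
    m2$rxns$ub[i] <- m2$rxns$ub[i] * 0.5
    m2$rxns$lb[i] <- min(m2$rxns$lb[i], m2$rxns$ub[i])
    tightened <- fba(m2)
    if (tightened$status == "optimal")
      expect_lte(tightened$objective, base + 1e-9)
  }
})

test_that("LP kernel agrees with an independent simplex implementation", {
  # random box-bounded equality-constrained LPs against scipy's HiGGS-based
  # linprog, driven through the pre-installed python
  set.seed(99)
  script <- paste(
    "import json,sys,numpy as np",
    "from scipy.optimize import linprog",
    "d=json.load(open(sys.argv[1]))",
    "r=linprog(d['c'],A_eq=np.array(d['A']),b_eq=d['b'],",
    "          bounds=list(zip(d['lb'],d['ub'])),method='highs')",
    "print(r.status, r.fun if r.status==0 else 'NA')", sep = "\n")
  sfile <- tempfile(fileext = ".py")
  writeLines(script, sfile)
  for (k in 1:12) {
    m <- sample(2:5, 1)
    n <- m + sample(1:5, 1)
    A <- matrix(round(stats::rnorm(m * n), 2), m, n,
                dimnames = list(paste0("c", 1:m), paste0("v", 1:n)))
    lb <- round(stats::runif(n, -5, 0), 2)
    ub <- lb + round(stats::runif(n, 0, 10), 2)
    x0 <- lb + stats::runif(n) * (ub - lb)
    b <- if (k %% 2) drop(A %*% x0) else round(stats::rnorm(m), 2)
    obj <- round(stats::rnorm(n), 2)
    mine <- solve_lp(obj, A, lb, ub, b = b, sense = "min")
    jfile <- tempfile(fileext = ".json")
    jsonlite::write_json(list(c = obj,
                              A = lapply(seq_len(m),
                                         function(i) unname(A[i, ])),
                              b = unname(b), lb = lb, ub = ub),
                         jfile, digits = NA)
    out <- system2("python", c(sfile, jfile), stdout = TRUE)
    parts <- strsplit(out[length(out)], " ")[[1]]
    if (parts[1] == "0") {
      expect_identical(mine$status, "optimal")
      expect_equal(mine$objective, as.numeric(parts[2]),
                   tolerance = 1e-6)
    } else {
      expect_false(identical(mine$status, "optimal"))
    }
    unlink(jfile)
  }
  unlink(sfile)
})

test_that("FBA optimum matches COBRApy on the aerobic fixture", {
  m <- make_toy_aerobic()
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import cobra,sys;m=cobra.io.load_json_model('", path,
    "');print(m.optimize().objective_value)"))), stdout = TRUE)
  ref <- as.numeric(out[length(out)])
  expect_equal(fba(m)$objective, ref, tolerance = 1e-6)
  expect_equal(ref, 32)
  unlink(path)
})

test_that("parsimonious FBA is unique and preserves the linear optimum", {
  p <- make_parallel_pathways()
  s1 <- parsimonious_fba(p)
  # two identical parallel routes split exactly in half by symmetry
  expect_equal(unname(s1$fluxes["P1"]), unname(s1$fluxes["P2"]),
               tolerance = 1e-6)
  expect_equal(s1$objective, fba(p)$objective,
               tolerance = 1e-6 * (1 + abs(fba(p)$objective)))
  # single-pathway model: pFBA coincides with FBA
  g <- make_toy_glycolysis()
  expect_equal(parsimonious_fba(g)$fluxes, fba(g)$fluxes,
               tolerance = 1e-6)
  # deterministic to well below solver tolerance
  s2 <- parsimonious_fba(p)
  expect_equal(s1$fluxes, s2$fluxes, tolerance = 1e-9)
  # pFBA norm never exceeds the norm of the stage-1 vertex
  internal <- setdiff(p$rxns$id, exchange_reactions(p))
  expect_lte(sum(s1$fluxes[internal]^2),
             sum(fba(p)$fluxes[internal]^2) + 1e-9)
})

test_that("FVA brackets are tight and contain the pFBA flux", {
  m <- make_toy_aerobic()
  rng <- fva(m)
  expect_true(all(rng$min <= rng$max + 1e-9))
  pf <- parsimonious_fba(m)
  i <- match(rng$reaction, names(pf$fluxes))
  expect_true(all(pf$fluxes[i] >= rng$min - 1e-6))
  expect_true(all(pf$fluxes[i] <= rng$max + 1e-6))

  # a flux fixed by equality bounds has min == max
  m2 <- set_bounds(m, "EX_glc", lb = -1, ub = -1)
  r2 <- fva(m2, "EX_glc", objective_fraction = NA)
  expect_equal(r2$min, r2$max)
  expect_equal(r2$min, -1)

  # an internal two-reaction loop shows a wide symmetric range
  mets <- data.frame(id = c("x_c", "y_c"), compartment = "c")
  rxns <- data.frame(id = c("F", "B"), lb = c(-50, -50), ub = c(50, 50))
  S <- matrix(c(-1, 1, 1, -1), 2, dimnames = list(mets$id, rxns$id))
  loop <- metabolic_model("loop", mets, rxns, S, "F")
  lr <- fva(loop, objective_fraction = NA)
  expect_equal(lr$min, c(-50, -50))
  expect_equal(lr$max, c(50, 50))
})

test_that("growth feasibility check respects the error band", {
  m <- make_toy_rc_loop()
  rng <- fva(m, m$objective, objective_fraction = NA)
  ok <- check_growth_feasibility(m, mu = mean(c(rng$min, rng$max)),
                                 error = 0.2)
  expect_true(ok$feasible)
  # an experimental rate far above the model's reach is infeasible
  bad <- check_growth_feasibility(m, mu = rng$max * 10, error = 0.2)
  expect_false(bad$feasible)
  expect_equal(unname(bad$range), c(rng$min, rng$max), tolerance = 1e-6)
  expect_error(check_growth_feasibility(m, 0), "positive")
})

test_that("hit-and-run samples stay in the polytope and are reproducible", {
  g <- make_toy_glycolysis()
  ss <- sample_fluxes(g, n_points = 30, steps_per_point = 30, seed = 11)
  rng <- fva(g, objective_fraction = NA)
  for (j in seq_along(rng$reaction)) {
    expect_true(all(ss$samples[, rng$reaction[j]] >= rng$min[j] - 1e-6))
    expect_true(all(ss$samples[, rng$reaction[j]] <= rng$max[j] + 1e-6))
  }
  resid <- max(abs(as.matrix(g$S) %*% t(ss$samples)))
  expect_lt(resid, 1e-7)
  ss2 <- sample_fluxes(g, n_points = 30, steps_per_point = 30, seed = 11)
  expect_identical(ss$samples, ss2$samples)
  expect_error(sample_fluxes(g, n_points = 2), "seed")
})

test_that("sampling marginals on a box-like polytope match uniform theory", {
  # two independent internal loops: the polytope is a rectangle in the two
  # loop coordinates, whose marginals are uniform
  mets <- data.frame(id = c("a_c", "b_c"), compartment = "c")
  rxns <- data.frame(id = c("L1", "L1b", "L2", "L2b"),
                     lb = c(0, 0, 0, 0), ub = c(10, 10, 4, 4))
  S <- matrix(c(-1, 1,
                1, -1,
                -2, 2,
                2, -2), 2, dimnames = list(mets$id, rxns$id))
  box <- metabolic_model("box", mets, rxns, S, "L1")
  n <- 400
  ss <- sample_fluxes(box, n_points = n, steps_per_point = 15, seed = 42)
  for (rx in c("L1", "L2")) {
    u <- ss$samples[, rx]
    width <- if (rx == "L1") 10 else 4
    se <- width / sqrt(12) / sqrt(n)
    expect_lt(abs(mean(u) - width / 2), 3 * se * 3) # autocorrelation slack
    expect_gt(stats::sd(u), width / sqrt(12) / 3)
  }
})
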