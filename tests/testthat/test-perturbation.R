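test_that("phase plane grids respect geometry and flag infeasible points", {
  # default oxygen axis arithmetic: 0, -20, ..., -1000 is 51 points
  expect_length(seq(0, -1000, by = -20), 51)

  m <- make_toy_rc_loop()
  gr <- phpp_scan(m, "EX_glc", "EX_o2", c(0, -10), c(0, -20), step = 2)
  expect_equal(dim(gr$growth), c(6, 11))
  # growth at any grid point never exceeds the unconstrained maximum
  expect_lte(max(gr$growth, na.rm = TRUE), fba(m)$objective + 1e-9)
  # growth is non-decreasing along the glucose axis at fixed feasible O2
  col <- gr$growth[, 2]
  ok <- !is.na(col)
  expect_true(all(diff(col[ok]) >= -1e-9))

  # a grid point conflicting with a measured constraint is infeasible:
  # byproduct secretion is pinned, but the glucose axis at 0 starves the
  # only pathway able to make it
  m2 <- set_bounds(m, "EX_byp", lb = 1, ub = 1)
  gr2 <- phpp_scan(m2, "EX_glc", "EX_o2", c(0, 0), c(0, -20), step = 20)
  expect_false(any(gr2$feasible[1, ]))

  expect_error(phpp_scan(m, "EX_glc", "EX_o2", c(0, -10), c(0, -10),
                         step = 0), "step")
})

test_that("oxotypes follow the feasible oxygen interval", {
  # low: NADH supply (hence O2 consumption) is capacity-limited
  mets <- data.frame(id = c("o2_c", "nadh_c", "nad_c", "w_c"),
                     compartment = "c")
  rxns <- data.frame(id = c("EX_o2", "NSRC", "ETC", "BIO"),
                     lb = c(-1000, 0, 0, 0.5),
                     ub = c(0, 100, 2000, 2000))
  S <- matrix(0, 4, 4, dimnames = list(mets$id, rxns$id))
  S["o2_c", "EX_o2"] <- -1
  S["nad_c", "NSRC"] <- -1; S["nadh_c", "NSRC"] <- 1; S["w_c", "NSRC"] <- 1
  S["nadh_c", "ETC"] <- -1; S["o2_c", "ETC"] <- -0.5; S["nad_c", "ETC"] <- 1
  S["w_c", "BIO"] <- -1
  low_m <- metabolic_model("lowToy", mets, rxns, S, "BIO")
  # O2 fixed at -v must be consumed by ETC = 2v, needing NSRC = 2v <= 100,
  # so only |vO2| <= 50 is feasible
  ox_low <- classify_oxotype(low_m, "EX_o2", range = c(0, -1000), step = 20)
  expect_equal(ox_low$class, "low")
  expect_equal(ox_low$feasible_interval[2], 40) # last step below 50

  # high: growth demands at least 600 U of oxygen-driven ATP
  mets2 <- data.frame(id = c("o2_c", "atp_c"), compartment = "c")
  rxns2 <- data.frame(id = c("EX_o2", "RESP", "BIO"),
                      lb = c(-1000, 0, 600), ub = c(0, 2000, 2000))
  S2 <- matrix(0, 2, 3, dimnames = list(mets2$id, rxns2$id))
  S2["o2_c", "EX_o2"] <- -1
  S2["o2_c", "RESP"] <- -1; S2["atp_c", "RESP"] <- 1
  S2["atp_c", "BIO"] <- -1
  high_m <- metabolic_model("highToy", mets2, rxns2, S2, "BIO")
  ox_high <- classify_oxotype(high_m, "EX_o2", range = c(0, -1000),
                              step = 20)
  expect_equal(ox_high$class, "high")
  expect_equal(ox_high$feasible_interval[1], 600)

  # indifferent: with medium-scale substrate bounds the loop model grows at
  # every scanned oxygen level
  wide <- set_medium_constraints(make_toy_rc_loop(),
                                 medium_config(oxygen = "EX_o2"))
  ox_ind <- classify_oxotype(wide, "EX_o2")
  expect_equal(ox_ind$class, "indifferent")
  # the un-opened loop model instead is oxygen-limited: a low oxotype
  expect_equal(classify_oxotype(make_toy_rc_loop(), "EX_o2")$class, "low")

  # no feasible oxygen value at all is an error
  broken <- set_bounds(high_m, "RESP", lb = 0, ub = 0)
  expect_error(classify_oxotype(broken, "EX_o2"), "broken")
})

test_that("gene deletions honor GPR logic and the 5%/95% thresholds", {
  g <- make_toy_glycolysis()
  rep <- single_gene_deletion(g)
  expect_s3_class(rep, "essentiality_report")
  # isozymes: "gPGK1 or gPGK2" survives the loss of either one
  expect_equal(rep$class[rep$gene == "gPGK1"], "unchanged")
  expect_equal(rep$class[rep$gene == "gLDHA"], "unchanged")
  # "gHK and gPFK": either subunit loss kills glycolysis entirely
  expect_equal(rep$class[rep$gene == "gHK"], "terminated")
  expect_equal(rep$knockout[rep$gene == "gHK"], 0)
  # knockout growth never exceeds wild type; classes match ratios exactly
  expect_true(all(rep$knockout <= rep$wild_type + 1e-9))
  ratio <- rep$knockout / rep$wild_type
  expect_identical(rep$class,
                   ifelse(ratio < 0.05, "terminated",
                          ifelse(ratio < 0.95, "reduced", "unchanged")))

  # a gene absent from all rules changes nothing
  rep2 <- single_gene_deletion(g, "gNOT_PRESENT")
  expect_equal(rep2$class, "unchanged")
  expect_equal(rep2$n_reactions_off, 0)

  # transcript variants collapse onto the base gene
  m <- make_mini_model()
  m$rxns$gpr[m$rxns$id == "At"] <- "gT1.1 or gT1.2"
  rep3 <- single_gene_deletion(m, "gT1")
  expect_equal(rep3$class, "terminated")
})

test_that("reaction essentiality distinguishes bypassed from sole producers", {
  p <- make_parallel_pathways()
  rep <- reaction_essentiality(p, c("P1", "P2", "At"))
  # either parallel route alone is dispensable
  expect_equal(rep$class[rep$reaction %in% c("P1", "P2")],
               c("unchanged", "unchanged"))
  # the only transporter is essential
  expect_equal(rep$class[rep$reaction == "At"], "terminated")
  expect_true(all(rep$knockout <= rep$wild_type + 1e-9))
})

test_that("reductive carboxylation is obligate only under oxygen restriction", {
  m <- make_toy_rc_loop()
  free <- detect_reductive_carboxylation(m, c("IDH", "ACONT"))
  expect_equal(free$class, c("optional", "optional"))
  clamped <- detect_reductive_carboxylation(
    m, c("IDH", "ACONT"), oxygen_override = c(0, 0),
    oxygen_exchange = "EX_o2")
  expect_equal(clamped$class, c("obligate_reverse", "obligate_reverse"))
  expect_true(all(clamped$max < 0))
  # FVA certificates: the reported extremes are achievable fluxes
  m0 <- set_bounds(m, "EX_o2", lb = 0, ub = 0)
  for (k in seq_len(nrow(clamped))) {
    mfix <- set_bounds(m0, clamped$reaction[k],
                       lb = clamped$max[k] - 1e-9,
                       ub = clamped$max[k] + 1e-9)
    expect_true(is_feasible(mfix))
  }
  # monotonicity: loosening oxygen never turns obligate into forward-only
  seq_cl <- lapply(c(0, -1, -5, -1000), function(o2)
    detect_reductive_carboxylation(m, "IDH", oxygen_override = c(o2, 0),
                                   oxygen_exchange = "EX_o2"))
  classes <- vapply(seq_cl, function(d) d$class, character(1))
  expect_false(any(classes == "forward_only"))
  expect_error(detect_reductive_carboxylation(m, "IDH",
                                              oxygen_override = c(0, 0)),
               "oxygen_exchange")
})
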