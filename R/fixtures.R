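# Deterministic toy networks with analytically known answers. These stand in
# for a genome-scale reconstruction plus measured exometabolome in every
# test: stoichiometric yields are exact by construction (textbook P/O ratios
# of 2.5 per NADH and 1.5 per FADH2, so full oxidation of glucose gives
# 2 + 2 + 10*2.5 + 2*1.5 = 32 ATP, and anaerobic glycolysis gives 2).

toy_builder <- function(id, mets, rxn_list, objective, carbon = NULL) {
  met_ids <- mets$id
  S <- matrix(0, length(met_ids), length(rxn_list),
              dimnames = list(met_ids, names(rxn_list)))
  rxns <- data.frame(id = names(rxn_list), lb = NA_real_, ub = NA_real_,
                     gpr = "", subsystem = "", stringsAsFactors = FALSE)
  for (j in seq_along(rxn_list)) {
    r <- rxn_list[[j]]
    S[names(r$stoich), j] <- r$stoich
    rxns$lb[j] <- r$lb
    rxns$ub[j] <- r$ub
    if (!is.null(r$gpr)) rxns$gpr[j] <- r$gpr
    if (!is.null(r$subsystem)) rxns$subsystem[j] <- r$subsystem
  }
  if (!is.null(carbon)) mets$carbon <- mets$id %in% carbon
  metabolic_model(id, mets, rxns, S, objective)
}

rx <- function(stoich, lb = 0, ub = 2000, gpr = NULL, subsystem = NULL) {
  list(stoich = stoich, lb = lb, ub = ub, gpr = gpr, subsystem = subsystem)
}

glycolysis_parts <- function() {
  list(
    EX_glc = rx(c(glc_e = -1), lb = -1, ub = 0),
    EX_lac = rx(c(lac_e = -1), lb = 0),
    EX_h2o = rx(c(h2o_c = -1), lb = -100),
    EX_h = rx(c(h_c = -1), lb = -100),
    EX_pi = rx(c(pi_c = -1), lb = -100),
    GLCt = rx(c(glc_e = -1, glc_c = 1), gpr = "gGLUT1"),
    LACt = rx(c(lac_c = -1, lac_e = 1), gpr = "gMCT1"),
    GLYC_inv = rx(c(glc_c = -1, atp_c = -2, g3p_c = 2, adp_c = 2),
                  gpr = "gHK and gPFK", subsystem = "glycolysis"),
    GAPD = rx(c(g3p_c = -1, pi_c = -1, nad_c = -1, bpg_c = 1, nadh_c = 1),
              gpr = "gGAPDH", subsystem = "glycolysis"),
    PGK = rx(c(bpg_c = -1, adp_c = -1, pg3_c = 1, atp_c = 1),
             gpr = "gPGK1 or gPGK2", subsystem = "glycolysis"),
    ENO_PYK = rx(c(pg3_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
                 gpr = "gENO and gPKM", subsystem = "glycolysis"),
    LDH = rx(c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
             gpr = "gLDHA or gLDHB", subsystem = "fermentation"),
    ATPM = rx(c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
              subsystem = "maintenance"))
}

glycolysis_mets <- function() {
  data.frame(
    id = c("glc_e", "glc_c", "g3p_c", "bpg_c", "pg3_c", "pyr_c", "lac_c",
           "lac_e", "atp_c", "adp_c", "pi_c", "nad_c", "nadh_c", "h2o_c",
           "h_c"),
    compartment = c("e", rep("c", 6), "e", rep("c", 7)),
    stringsAsFactors = FALSE)
}

glycolysis_carbon <- c("glc_e", "glc_c", "g3p_c", "bpg_c", "pg3_c", "pyr_c",
                       "lac_c", "lac_e")

#' Toy anaerobic glycolysis network
#'
#' Embden-Meyerhof stoichiometry lumped to a handful of reactions:
#' glucose -> 2 lactate with a net 2 ATP per glucose (4 produced by
#' phosphoglycerate kinase + pyruvate kinase, 2 invested upstream), NADH
#' redox-balanced through lactate dehydrogenase, phosphate/water/proton
#' bookkeeping closed via their exchanges. The objective is the ATP
#' hydrolysis (maintenance) reaction.
#'
#' @return A `metabolic_model` whose maximal ATP hydrolysis per glucose is
#'   exactly 2 and whose lactate secretion at that optimum is 2 per
#'   glucose.
#' @export
make_toy_glycolysis <- function() {
  toy_builder("toy_glycolysis", glycolysis_mets(), glycolysis_parts(),
              objective = "ATPM", carbon = glycolysis_carbon)
}

#' Toy aerobic glucose oxidation network
#'
#' Extends the glycolytic core with pyruvate dehydrogenase, a lumped TCA
#' turn (3 NADH, 1 FADH2, 1 substrate-level ATP per acetyl-CoA), and
#' electron transport with P/O ratios of 2.5 (NADH) and 1.5 (FADH2), so
#' full oxidation of one glucose yields exactly 32 ATP with oxygen open and
#' 2 (lactate fermentation) with oxygen closed.
#'
#' @return A `metabolic_model`; objective is ATP hydrolysis.
#' @export
make_toy_aerobic <- function() {
  mets <- rbind(glycolysis_mets(), data.frame(
    id = c("accoa_m", "nad_m", "nadh_m", "fad_m", "fadh2_m", "o2_c",
           "co2_c"),
    compartment = c(rep("m", 5), "c", "c"), stringsAsFactors = FALSE))
  parts <- c(glycolysis_parts(), list(
    EX_o2 = rx(c(o2_c = -1), lb = -1000, ub = 0),
    EX_co2 = rx(c(co2_c = -1), lb = 0),
    PDHm = rx(c(pyr_c = -1, nad_m = -1, accoa_m = 1, co2_c = 1,
                nadh_m = 1), gpr = "gPDHA1", subsystem = "TCA"),
    TCA = rx(c(accoa_m = -1, nad_m = -3, fad_m = -1, adp_c = -1,
               pi_c = -1, co2_c = 2, nadh_m = 3, fadh2_m = 1, atp_c = 1),
             gpr = "gCS and gSUCOAS", subsystem = "TCA"),
    ETC_NADH = rx(c(nadh_m = -1, o2_c = -0.5, adp_c = -2.5, pi_c = -2.5,
                    nad_m = 1, atp_c = 2.5, h2o_c = 1),
                  gpr = "gNDUFA and gATP5", subsystem = "OxPhos"),
    ETC_FADH2 = rx(c(fadh2_m = -1, o2_c = -0.5, adp_c = -1.5,
                     pi_c = -1.5, fad_m = 1, atp_c = 1.5, h2o_c = 1),
                   gpr = "gSDHA and gATP5", subsystem = "OxPhos"),
    # NADH shuttle so cytosolic glycolytic NADH can reach the chain
    SHUTTLE = rx(c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
                 subsystem = "shuttle")))
  toy_builder("toy_aerobic", mets, parts, objective = "ATPM",
              carbon = c(glycolysis_carbon, "accoa_m", "co2_c"))
}

#' Toy network with two identical parallel pathways
#'
#' One substrate feeds a demand through two stoichiometrically identical
#' routes `P1` and `P2`; any split between them is an alternate linear
#' optimum, and the parsimonious (minimum-norm) solution is the exact
#' half/half split.
#'
#' @return A `metabolic_model`; objective is the demand reaction `DM`.
#' @export
make_parallel_pathways <- function() {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  parts <- list(
    EX_a = rx(c(a_e = -1), lb = -10, ub = 0),
    At = rx(c(a_e = -1, a_c = 1)),
    P1 = rx(c(a_c = -1, b_c = 1)),
    P2 = rx(c(a_c = -1, b_c = 1)),
    DM = rx(c(b_c = -1)))
  toy_builder("toy_parallel", mets, parts, objective = "DM")
}

#' Toy TCA-loop network for reductive carboxylation
#'
#' Citrate (for lipogenic acetyl-CoA and oxaloacetate) can be made either
#' forward — glucose-derived pyruvate via pyruvate dehydrogenase and
#' citrate synthase, which produces NADH and therefore needs oxygen to
#' regenerate NAD — or in reverse from glutamine-derived 2-oxoglutarate
#' through isocitrate dehydrogenase and aconitase running backwards
#' (carboxylation), which consumes NADPH supplied by an oxidative pentose
#' phosphate lump and needs no oxygen. Clamping the oxygen exchange to
#' (or near) zero therefore forces both reactions net reverse; with oxygen
#' open both directions remain possible.
#'
#' Forward (oxidative) flux through `IDH` and `ACONT` is positive by
#' convention.
#'
#' @return A `metabolic_model`; objective is the biomass reaction
#'   `BIOMASS` (lower bound 0.008 U, the minimal-growth value).
#' @export
make_toy_rc_loop <- function() {
  mets <- data.frame(
    id = c("glc_e", "gln_e", "glc_c", "gln_c", "akg_c", "icit_c", "cit_c",
           "accoa_c", "oaa_c", "pyr_c", "nad_c", "nadh_c", "nadp_c",
           "nadph_c", "o2_c", "co2_c", "byp_e"),
    compartment = c("e", "e", rep("c", 14), "e"), stringsAsFactors = FALSE)
  parts <- list(
    EX_glc = rx(c(glc_e = -1), lb = -10, ub = 0),
    EX_gln = rx(c(gln_e = -1), lb = -10, ub = 0),
    EX_o2 = rx(c(o2_c = -1), lb = -1000, ub = 0),
    EX_co2 = rx(c(co2_c = -1), lb = -100),
    EX_byp = rx(c(byp_e = -1), lb = 0),
    GLCt = rx(c(glc_e = -1, glc_c = 1)),
    GLNt = rx(c(gln_e = -1, gln_c = 1)),
    GLS = rx(c(gln_c = -1, akg_c = 1), gpr = "gGLS"),
    GLYC = rx(c(glc_c = -1, pyr_c = 2, nad_c = -2, nadh_c = 2)),
    PDH = rx(c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
               nadh_c = 1), gpr = "gPDHA1"),
    PC = rx(c(pyr_c = -1, co2_c = -1, oaa_c = 1), gpr = "gPC"),
    CS = rx(c(accoa_c = -1, oaa_c = -1, cit_c = 1), gpr = "gCS"),
    # oxidative forward direction: citrate -> isocitrate -> 2-oxoglutarate
    ACONT = rx(c(cit_c = -1, icit_c = 1), lb = -2000, gpr = "gACO1 or gACO2"),
    IDH = rx(c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1,
               nadph_c = 1), lb = -2000, gpr = "gIDH1 or gIDH2"),
    CLY = rx(c(cit_c = -1, accoa_c = 1, oaa_c = 1), gpr = "gACLY"),
    AKGD = rx(c(akg_c = -1, nad_c = -1, oaa_c = 1, co2_c = 1, nadh_c = 1),
              gpr = "gOGDH"),
    PPP = rx(c(glc_c = -1, nadp_c = -2, nadph_c = 2, co2_c = 1,
               byp_e = 1), gpr = "gG6PD"),
    ETC = rx(c(nadh_c = -1, o2_c = -0.5, nad_c = 1), gpr = "gNDUFA"),
    BIOMASS = rx(c(accoa_c = -1, oaa_c = -1, nadph_c = -0.1,
                   nadp_c = 0.1), lb = 0.008))
  toy_builder("toy_rc_loop", mets, parts, objective = "BIOMASS",
              carbon = c("glc_e", "gln_e", "glc_c", "gln_c", "akg_c",
                         "icit_c", "cit_c", "accoa_c", "oaa_c", "pyr_c",
                         "co2_c", "byp_e"))
}

#' Exchange-completion fixture with a known minimal exchange set
#'
#' Builds a toy model plus a measured profile whose integration alone is
#' infeasible: growth requires `n_required` precursor metabolites, each
#' obtainable only through its own (unmeasured) candidate exchange, so the
#' unique minimal completion has exactly those `n_required` exchanges
#' active. The remaining candidates are decoys — consumable (each feeds a
#' waste sink) but useless for growth. Identifier order is shuffled by the
#' seed, so the minimizer's tie-breaking cannot accidentally align with
#' construction order.
#'
#' @param n_candidates total number of candidate exchanges (<= 15).
#' @param n_required number of precursor exchanges growth needs
#'   (<= `n_candidates`).
#' @param seed integer seed controlling identifier shuffling and measured
#'   flux values.
#' @return List with `model` (medium-style bounds and biomass lower bound
#'   0.008 already applied), `profile` (measured exchanges), `measured`
#'   (their exchange ids), `candidates`, and `truth` (the ground-truth
#'   active exchange ids).
#' @export
make_exchange_completion_fixture <- function(n_candidates, n_required,
                                             seed) {
  stopifnot(n_required <= n_candidates, n_candidates <= 15)
  set.seed(seed)
  labels <- sample(LETTERS, n_candidates)
  req <- labels[seq_len(n_required)]
  dec <- setdiff(labels, req)
  pfx <- function(pre, g, suf) if (length(g)) paste0(pre, g, suf)
                               else character(0)
  mets <- data.frame(
    id = c("s_e", "s_c", "w_c", "w_e",
           pfx("p", req, "_e"), pfx("p", req, "_c"),
           pfx("d", dec, "_e"), pfx("d", dec, "_c")),
    compartment = rep(c("e", "c", "c", "e", "e", "c", "e", "c"),
                      c(1, 1, 1, 1, length(req), length(req),
                        length(dec), length(dec))),
    stringsAsFactors = FALSE)
  uptake <- -round(stats::runif(1, 5, 20), 2)
  parts <- list(
    EX_s = rx(c(s_e = -1), lb = -2000),
    St = rx(c(s_e = -1, s_c = 1)),
    CAT = rx(c(s_c = -1, w_c = 1)),
    Wt = rx(c(w_c = -1, w_e = 1)),
    EX_w = rx(c(w_e = -1), lb = -2000))
  for (g in req) {
    parts[[paste0("EX_p", g)]] <- rx(stats::setNames(-1, paste0("p", g, "_e")),
                                     lb = 0, ub = 0)
    parts[[paste0("Pt", g)]] <- rx(stats::setNames(c(-1, 1),
                                                   paste0("p", g, c("_e", "_c"))))
  }
  for (g in dec) {
    parts[[paste0("EX_d", g)]] <- rx(stats::setNames(-1, paste0("d", g, "_e")),
                                     lb = 0, ub = 0)
    parts[[paste0("Dt", g)]] <- rx(stats::setNames(c(-1, 1),
                                                   paste0("d", g, c("_e", "_c"))))
    parts[[paste0("Dsink", g)]] <- rx(stats::setNames(c(-1, 1),
                                                      c(paste0("d", g, "_c"),
                                                        "w_c")))
  }
  # biomass converts substrate (plus every required precursor) into a small
  # waste fraction, so it always touches >= 2 metabolites and is never
  # mistaken for an exchange reaction
  bm <- stats::setNames(c(rep(-1, n_required + 1), 0.1),
                        c("s_c", pfx("p", req, "_c"), "w_c"))
  parts$BIOMASS <- rx(bm, lb = 0.008)
  model <- toy_builder(sprintf("completion_%d_%d_%d", n_candidates,
                               n_required, seed),
                       mets, parts, objective = "BIOMASS")
  # measured: substrate uptake and waste secretion, consistent with uptake
  profile <- exchange_profile(
    sprintf("fix%d", seed),
    stats::setNames(c(uptake, -uptake * 0.9), c("s_e", "w_e")))
  measured <- c("EX_s", "EX_w")
  model <- set_bounds(model, "EX_s", lb = allowance_bounds(uptake)[["lb"]],
                      ub = allowance_bounds(uptake)[["ub"]])
  model <- set_bounds(model, "EX_w",
                      lb = allowance_bounds(-uptake * 0.9)[["lb"]],
                      ub = allowance_bounds(-uptake * 0.9)[["ub"]])
  truth <- sort(pfx("EX_p", req, ""))
  list(model = model, profile = profile, measured = measured,
       candidates = candidate_exchanges(model, measured), truth = truth)
}

#' Completion fixture where the one-norm optimum is not minimal
#'
#' Growth needs one precursor `p`. A direct exchange `EX_p` is capped below
#' the requirement, while a precursor-rich route `EX_q` (one q yields 0.5 p)
#' is unlimited but flux-expensive. The one-norm relaxation therefore picks
#' *both* exchanges (cheapest total flux), although `EX_q` alone is
#' feasible: the minimal cardinality is 1. Minimality verification detects
#' that `EX_p` is removable and a second minimization round returns the
#' true minimum.
#'
#' @return List with `model`, `measured`, `candidates`, and
#'   `truth_cardinality` (1).
#' @export
make_redundant_completion_fixture <- function() {
  mets <- data.frame(id = c("p_e", "p_c", "q_e", "q_c"),
                     compartment = c("e", "c", "e", "c"),
                     stringsAsFactors = FALSE)
  parts <- list(
    EX_p = rx(c(p_e = -1), lb = 0, ub = 0),
    EX_q = rx(c(q_e = -1), lb = 0, ub = 0),
    Pt = rx(c(p_e = -1, p_c = 1), ub = 0.005),
    Qt = rx(c(q_e = -1, q_c = 1)),
    QtoP = rx(c(q_c = -1, p_c = 0.5)),
    BIOMASS = rx(c(p_c = -1), lb = 0.008))
  model <- toy_builder("redundant_completion", mets, parts,
                       objective = "BIOMASS")
  list(model = model, measured = character(0),
       candidates = c("EX_p", "EX_q"), truth_cardinality = 1L)
}

#' Synthetic exchange profile from a reference flux distribution
#'
#' Draws a feasible reference flux by parsimonious FBA, then reports the
#' chosen exchanges' fluxes with multiplicative noise
#' `x = v * (1 + delta)`, `delta ~ U(-noise, noise)`. For noise up to
#' about 1/6 the true flux stays inside the 20% allowance window of the
#' reported value, so integration applies every pair; a `corrupt` entry
#' can push one flux out of the feasible set to exercise rollback.
#'
#' @param model a feasible `metabolic_model`.
#' @param exchanges measured exchange ids.
#' @param noise noise fraction (default 0).
#' @param seed integer seed.
#' @param sample_id profile label.
#' @param corrupt optional exchange id whose reported flux is multiplied
#'   by `corrupt_factor`.
#' @param corrupt_factor multiplier for the corrupted entry (default 50).
#' @return An `exchange_profile` (metabolite ids = exchange metabolites).
#' @export
make_synthetic_profile <- function(model, exchanges, noise = 0, seed = 1,
                                   sample_id = "synthetic",
                                   corrupt = NULL, corrupt_factor = 50) {
  set.seed(seed)
  ref <- parsimonious_fba(model)
  if (ref$status != "optimal") stop("model infeasible; no reference flux")
  v <- ref$fluxes[exchanges]
  delta <- stats::runif(length(v), -noise, noise)
  x <- v * (1 + delta)
  if (!is.null(corrupt)) {
    stopifnot(corrupt %in% exchanges)
    x[corrupt == exchanges] <- x[corrupt == exchanges] * corrupt_factor
  }
  mets <- exchange_metabolites(model, exchanges)
  exchange_profile(sample_id, stats::setNames(as.numeric(x), unname(mets)))
}

#' Generate a toy network by template name
#'
#' Dispatcher over the fixture constructors, mirroring the templates the
#' test-suite and the command line use.
#'
#' @param template one of `"anaerobic_glycolysis"`, `"aerobic_oxidation"`,
#'   `"exchange_completion"`, `"rc_loop"`, `"parallel_pathways"`.
#' @param ... arguments passed to the underlying constructor
#'   (`exchange_completion` takes `n_candidates`, `n_required`, `seed`).
#' @return A `metabolic_model`, or the fixture list for
#'   `exchange_completion`.
#' @export
make_toy_network <- function(template = c("anaerobic_glycolysis",
                                          "aerobic_oxidation",
                                          "exchange_completion", "rc_loop",
                                          "parallel_pathways"), ...) {
  template <- match.arg(template)
  switch(template,
         anaerobic_glycolysis = make_toy_glycolysis(),
         aerobic_oxidation = make_toy_aerobic(),
         exchange_completion = make_exchange_completion_fixture(...),
         rc_loop = make_toy_rc_loop(),
         parallel_pathways = make_parallel_pathways())
}
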