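#!/usr/bin/env Rscript
# exoflux command line: thin wrappers over the package functions.
#
#   exoflux fixtures --template T [--seed N] [--n-candidates K --n-required R] --out DIR
#   exoflux validate-model --model FILE
#   exoflux build --model FILE --profiles TSV --mapping TSV --out DIR
#   exoflux phenotype --model FILE [--glucose EX] [--atp-metabolite MET] --out DIR

suppressPackageStartupMessages(library(exoflux))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  cat("usage: exoflux <fixtures|validate-model|build|phenotype> [options]\n")
  quit(status = 1)
}
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
}

if (cmd == "fixtures") {
  template <- get_opt("--template", "aerobic_oxidation")
  seed <- as.integer(get_opt("--seed", "1"))
  outdir <- get_opt("--out", ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (template == "exchange_completion") {
    fx <- make_exchange_completion_fixture(
      as.integer(get_opt("--n-candidates", "6")),
      as.integer(get_opt("--n-required", "2")), seed)
    save_model(fx$model, file.path(outdir, "model.json"))
    tab <- data.frame(metabolite = names(fx$profile$entries),
                      value = as.numeric(fx$profile$entries))
    names(tab)[2] <- fx$profile$sample_id
    write.table(tab, file.path(outdir, "profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(truth = fx$truth, measured = fx$measured,
                              candidates = fx$candidates),
                         file.path(outdir, "truth.json"))
    cat("wrote model.json, profile.tsv, truth.json to", outdir, "\n")
  } else {
    m <- make_toy_network(template)
    save_model(m, file.path(outdir, paste0(m$id, ".json")))
    save_model(m, file.path(outdir, paste0(m$id, ".xml")), format = "sbml")
    cat("wrote", paste0(m$id, ".{json,xml}"), "to", outdir, "\n")
  }
} else if (cmd == "validate-model") {
  m <- load_model(get_opt("--model"))
  validate_metabolic_model(m)
  print(m)
  cat("model valid;", length(exchange_reactions(m)), "exchanges\n")
} else if (cmd == "build") {
  model <- load_model(get_opt("--model"))
  mapping <- load_exchange_map(get_opt("--mapping"))
  profs <- load_profiles(get_opt("--profiles"), mapping)
  outdir <- get_opt("--out", "models")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  oxygen <- get_opt("--oxygen")
  cfg <- medium_config(oxygen = oxygen,
                       min_growth = as.numeric(get_opt("--min-growth",
                                                       "0.008")))
  for (p in profs) {
    cm <- build_condition_model(model, p, mapping, cfg)
    base <- file.path(outdir, p$sample_id)
    save_model(cm$model, paste0(base, ".json"))
    jsonlite::write_json(list(sample_id = cm$sample_id,
                              measured = cm$measured, added = cm$added,
                              removed_exchanges = cm$removed_exchanges,
                              removed_blocked = cm$removed_blocked),
                         paste0(base, "_provenance.json"))
    print(cm)
  }
} else if (cmd == "phenotype") {
  m <- load_model(get_opt("--model"))
  glc <- get_opt("--glucose", "EX_glc")
  atp_met <- strsplit(get_opt("--atp-metabolite", "atp_c"), ",")[[1]]
  sol <- parsimonious_fba(m)
  sp <- flux_splits(m, sol, atp_met)
  outdir <- get_opt("--out", ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(as.data.frame(sp), file.path(outdir, "flux_splits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("major producer:", attr(sp, "major"),
      "| total production:", attr(sp, "total"), "\n")
  cat("ATP yield:", atp_yield(m, sol, atp_met, glc), "\n")
  cat("glucose-only max ATP:", max_atp_from_glucose(m, glc), "\n")
} else {
  cat("unknown command:", cmd, "\n")
  quit(status = 1)
}
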