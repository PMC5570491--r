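#' Read a metabolic model from SBML or COBRA-style JSON
#'
#' JSON follows the COBRA model schema (`metabolites`, `reactions` with
#' `metabolites` coefficient maps, `lower_bound`/`upper_bound`,
#' `gene_reaction_rule`, `objective_coefficient`). SBML is Level 3 with the
#' FBC v2 package: flux bounds must be given through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters — a reaction without
#' both bounds is an error, never a silent default.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return A `metabolic_model`.
#' @seealso [save_model()]
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to SBML or COBRA-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("parse error in '", path, "': missing 'metabolites' or 'reactions'")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% ""), character(1)),
    stringsAsFactors = FALSE)
  carbon <- vapply(doc$metabolites, function(m) {
    if (is.null(m$notes$carbon)) NA else isTRUE(m$notes$carbon)
  }, logical(1))
  mets$carbon <- carbon
  n <- length(doc$reactions)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), character(1)),
    name = vapply(doc$reactions, function(r)
      as.character(r$name %||% r$id), character(1)),
    lb = vapply(doc$reactions, function(r) {
      if (is.null(r$lower_bound)) stop("reaction '", r$id,
                                       "' has no lower bound")
      as.numeric(r$lower_bound)
    }, numeric(1)),
    ub = vapply(doc$reactions, function(r) {
      if (is.null(r$upper_bound)) stop("reaction '", r$id,
                                       "' has no upper bound")
      as.numeric(r$upper_bound)
    }, numeric(1)),
    gpr = vapply(doc$reactions, function(r)
      as.character(r$gene_reaction_rule %||% ""), character(1)),
    subsystem = vapply(doc$reactions, function(r)
      as.character(r$subsystem %||% ""), character(1)),
    stringsAsFactors = FALSE)
  S <- Matrix::Matrix(0, nrow(mets), n, sparse = TRUE,
                      dimnames = list(mets$id, rxns$id))
  for (j in seq_len(n)) {
    coefs <- doc$reactions[[j]]$metabolites
    if (length(coefs)) {
      i <- match(names(coefs), mets$id)
      if (anyNA(i))
        stop("parse error: reaction '", rxns$id[j],
             "' references unknown metabolite '",
             names(coefs)[is.na(i)][1], "'")
      S[i, j] <- as.numeric(unlist(coefs))
    }
  }
  obj <- vapply(doc$reactions, function(r)
    as.numeric(r$objective_coefficient %||% 0), numeric(1))
  objective <- if (any(obj != 0)) rxns$id[which(obj != 0)[1]] else rxns$id[1]
  metabolic_model(doc$id %||% "model", mets, rxns, S, objective)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- list(id = model$mets$id[i], compartment = model$mets$compartment[i])
    if (!is.na(model$mets$carbon[i]))
      m$notes <- list(carbon = model$mets$carbon[i])
    m
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    list(id = model$rxns$id[j],
         name = model$rxns$name[j],
         metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                               model$mets$id[nz])),
         lower_bound = model$rxns$lb[j],
         upper_bound = model$rxns$ub[j],
         gene_reaction_rule = model$rxns$gpr[j],
         subsystem = model$rxns$subsystem[j],
         objective_coefficient =
           if (model$rxns$id[j] == model$objective) 1 else 0)
  })
  genes <- lapply(model_genes(model, collapse_transcripts = FALSE),
                  function(g) list(id = g))
  doc <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = genes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
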