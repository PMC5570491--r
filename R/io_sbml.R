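# Minimal SBML Level 3 + FBC v2 reader/writer built on xml2, covering the
# subset this package's models use: compartments, species, reactions with
# stoichiometry, fbc flux-bound parameters, the fbc objective, and fbc gene
# product associations. Identifiers are SId-sanitized on write ("R_"/"M_"
# prefixes) and unprefixed on read, following the COBRA convention.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", x))

unsbml_id <- function(x, prefix) {
  out <- sub(paste0("^", prefix), "", x)
  gsub("__", "-", out, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(sbml_id(model$id, ""))))
  comps <- unique(model$mets$compartment)
  comps[!nzchar(comps)] <- "c"
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>',
                     esc(unique(comps))),
             "    </listOfCompartments>")
  cvals <- ifelse(nzchar(model$mets$compartment), model$mets$compartment, "c")
  lines <- c(lines, "    <listOfSpecies>",
             sprintf(paste0('      <species id="%s" name="%s" ',
                            'compartment="%s" hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"%s/>'),
                     esc(sbml_id(model$mets$id, "M_")),
                     esc(model$mets$name), esc(cvals),
                     ifelse(is.na(model$mets$carbon), "",
                            sprintf(' sboTerm="SBO:0000%d"',
                                    ifelse(model$mets$carbon, 247L, 291L)))),
             "    </listOfSpecies>")
  bnds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- stats::setNames(sprintf("fb_%d", seq_along(bnds)), num(bnds))
  lines <- c(lines, "    <listOfParameters>",
             sprintf(paste0('      <parameter id="%s" value="%s" ',
                            'constant="true"/>'), bid, names(bid)),
             "    </listOfParameters>")
  genes <- model_genes(model, collapse_transcripts = FALSE)
  if (length(genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                              'fbc:label="%s"/>'),
                       esc(sbml_id(genes, "G_")), esc(genes)),
               "    </fbc:listOfGeneProducts>")
  }
  gpr_xml <- function(gpr, indent) {
    tok <- gpr_tokens(gpr)
    if (!length(tok)) return(character(0))
    # recursive-descent over the token stream
    pos <- 1L
    parse_or <- function() {
      l <- parse_and()
      while (pos <= length(tok) && tolower(tok[pos]) == "or") {
        pos <<- pos + 1L
        l <- list(op = "or", args = c(if (identical(l$op, "or")) l$args
                                      else list(l), list(parse_and())))
      }
      l
    }
    parse_and <- function() {
      l <- parse_atom()
      while (pos <= length(tok) && tolower(tok[pos]) == "and") {
        pos <<- pos + 1L
        l <- list(op = "and", args = c(if (identical(l$op, "and")) l$args
                                       else list(l), list(parse_atom())))
      }
      l
    }
    parse_atom <- function() {
      if (tok[pos] == "(") {
        pos <<- pos + 1L
        out <- parse_or()
        if (pos > length(tok) || tok[pos] != ")")
          stop("unbalanced parentheses in GPR: ", gpr)
        pos <<- pos + 1L
        return(out)
      }
      g <- tok[pos]
      pos <<- pos + 1L
      list(op = "gene", gene = g)
    }
    render <- function(node, ind) {
      pad <- strrep(" ", ind)
      if (node$op == "gene")
        return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                       pad, esc(sbml_id(node$gene, "G_"))))
      tag <- if (node$op == "or") "fbc:or" else "fbc:and"
      c(sprintf("%s<%s>", pad, tag),
        unlist(lapply(node$args, render, ind + 2)),
        sprintf("%s</%s>", pad, tag))
    }
    tree <- parse_or()
    if (pos <= length(tok)) stop("trailing tokens in GPR: ", gpr)
    pad <- strrep(" ", indent)
    c(sprintf("%s<fbc:geneProductAssociation>", pad),
      render(tree, indent + 2),
      sprintf("%s</fbc:geneProductAssociation>", pad))
  }
  lines <- c(lines, "    <listOfReactions>")
  for (j in seq_len(nrow(model$rxns))) {
    col <- model$S[, j]
    nz <- which(col != 0)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(sbml_id(model$rxns$id[j], "R_")), esc(model$rxns$name[j]),
      if (model$rxns$lb[j] < 0) "true" else "false",
      bid[num(model$rxns$lb[j])], bid[num(model$rxns$ub[j])]))
    lines <- c(lines, gpr_xml(model$rxns$gpr[j], 8))
    rct <- nz[col[nz] < 0]
    prd <- nz[col[nz] > 0]
    if (length(rct))
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(sbml_id(model$mets$id[rct], "M_")),
                         num(-as.numeric(col[rct]))),
                 "        </listOfReactants>")
    if (length(prd))
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(sbml_id(model$mets$id[prd], "M_")),
                         num(as.numeric(col[prd]))),
                 "        </listOfProducts>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                            'fbc:coefficient="1"/>'),
                     esc(sbml_id(model$objective, "R_"))),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("parse error: no <model> element")
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("parse error: no species")
  sbo <- xml2::xml_attr(sp, "sboTerm")
  mets <- data.frame(
    id = unsbml_id(xml2::xml_attr(sp, "id"), "M_"),
    compartment = xml2::xml_attr(sp, "compartment"),
    name = xml2::xml_attr(sp, "name"),
    carbon = ifelse(is.na(sbo), NA, sbo == "SBO:0000247"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("parse error: no reactions")
  sid <- xml2::xml_attr(rx, "id")
  lbp <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
  ubp <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
  if (anyNA(lbp) || anyNA(ubp))
    stop("reaction '", sid[which(is.na(lbp) | is.na(ubp))[1]],
         "' lacks fbc flux bounds (no silent defaults)")
  bad <- !(lbp %in% names(pval)) | !(ubp %in% names(pval))
  if (any(bad))
    stop("reaction '", sid[bad][1], "' references undefined bound parameter")
  read_gpr <- function(node) {
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (inherits(assoc, "xml_missing")) return("")
    render <- function(n) {
      nm <- xml2::xml_name(n)
      if (nm == "geneProductRef")
        return(unsbml_id(xml2::xml_attr(n, "fbc:geneProduct", ns = ns), "G_"))
      kids <- vapply(xml2::xml_children(n), render, character(1))
      op <- if (nm == "or") " or " else " and "
      paste0("(", paste(kids, collapse = op), ")")
    }
    kids <- xml2::xml_children(assoc)
    if (!length(kids)) return("")
    render(kids[[1]])
  }
  n <- length(rx)
  rxns <- data.frame(
    id = unsbml_id(sid, "R_"),
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), unsbml_id(sid, "R_"),
                  xml2::xml_attr(rx, "name")),
    lb = as.numeric(pval[lbp]),
    ub = as.numeric(pval[ubp]),
    gpr = vapply(rx, read_gpr, character(1)),
    subsystem = "",
    stringsAsFactors = FALSE)
  S <- Matrix::Matrix(0, nrow(mets), n, sparse = TRUE,
                      dimnames = list(mets$id, rxns$id))
  for (j in seq_len(n)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[j]],
                                 sprintf("./s:%s/s:speciesReference", side), ns)
      if (!length(refs)) next
      ids <- unsbml_id(xml2::xml_attr(refs, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      if (anyNA(coef))
        stop("parse error: missing stoichiometry in reaction '", rxns$id[j],
             "'")
      i <- match(ids, mets$id)
      if (anyNA(i))
        stop("parse error: reaction '", rxns$id[j],
             "' references unknown species '", ids[is.na(i)][1], "'")
      sgn <- if (side == "listOfReactants") -1 else 1
      S[i, j] <- S[i, j] + sgn * coef
    }
  }
  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objective <- if (inherits(fo, "xml_missing")) rxns$id[1] else
    unsbml_id(xml2::xml_attr(fo, "fbc:reaction", ns = ns), "R_")
  metabolic_model(unsbml_id(xml2::xml_attr(mdl, "id") %||% "model", ""),
                  mets, rxns, S, objective)
}
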