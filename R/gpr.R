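# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are the usual COBRA strings, e.g. "(g1 and g2) or g3.1". Tokens other
# than "and"/"or" (case-insensitive) and parentheses are gene identifiers;
# identifiers may contain dots (transcript suffixes), so rules are evaluated
# by direct tokenization rather than by parsing as R code.

gpr_tokens <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", gpr)[[1]]
  regmatches(gpr, list(m))[[1]]
}

gpr_genes <- function(gpr) {
  tok <- gpr_tokens(gpr)
  setdiff(tok[!tolower(tok) %in% c("and", "or", "(", ")")], character(0))
}

#' Evaluate a GPR rule under a set of disabled genes
#'
#' A gene token counts as disabled when it (or its transcript-collapsed base
#' id, i.e. with a trailing `.N` suffix stripped) is in `off`. Empty rules
#' evaluate to `TRUE`: reactions without gene association are never disabled
#' by a knockout.
#'
#' @param gpr GPR rule string.
#' @param off character vector of knocked-out gene ids (base or transcript).
#' @return `TRUE` if the reaction remains available, otherwise `FALSE`.
#' @export
eval_gpr <- function(gpr, off = character(0)) {
  tok <- gpr_tokens(gpr)
  if (!length(tok)) return(TRUE)
  expr <- vapply(tok, function(t) {
    tl <- tolower(t)
    if (tl == "and") return("&&")
    if (tl == "or") return("||")
    if (t %in% c("(", ")")) return(t)
    base <- sub("\\.\\d+$", "", t)
    if (t %in% off || base %in% off) "FALSE" else "TRUE"
  }, character(1))
  out <- tryCatch(eval(parse(text = paste(expr, collapse = " "))),
                  error = function(e) NULL)
  if (is.null(out) || !is.logical(out) || length(out) != 1 || is.na(out))
    stop("unparseable GPR rule: '", gpr, "'")
  out
}
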