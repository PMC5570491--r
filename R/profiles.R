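#' Construct an exchange profile
#'
#' One sample's measured extracellular fluxes: a named vector of rates in
#' U = fmol/cell/hr, negative for uptake, positive for secretion. Zero
#' entries are permitted but flagged (`zero_entries`); they are below the
#' calibration range rather than evidence of no exchange, and the
#' integration step does not turn them into closed bounds.
#'
#' @param sample_id sample identifier.
#' @param entries named numeric vector, names = metabolite ids.
#' @param cell_line optional cell line label.
#' @return An `exchange_profile`.
#' @export
exchange_profile <- function(sample_id, entries, cell_line = NA_character_) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("profile entries must be named by metabolite id")
  if (anyDuplicated(names(entries)))
    stop("duplicate metabolite in profile: ",
         names(entries)[duplicated(names(entries))][1])
  if (any(!is.finite(entries)))
    stop("non-finite flux for metabolite: ",
         names(entries)[!is.finite(entries)][1])
  structure(list(sample_id = sample_id, cell_line = cell_line,
                 entries = entries,
                 zero_entries = names(entries)[entries == 0]),
            class = "exchange_profile")
}

#' @export
print.exchange_profile <- function(x, ...) {
  cat("exchange_profile '", x$sample_id, "': ", length(x$entries),
      " metabolites (", sum(x$entries < 0), " uptakes, ",
      sum(x$entries > 0), " secretions, ", length(x$zero_entries),
      " zero)\n", sep = "")
  invisible(x)
}

#' Load exchange profiles from a TSV/CSV table
#'
#' Column 1 must hold metabolite ids; every remaining column is one sample
#' (header = sample id), with fluxes in U (negative = uptake). Metabolites
#' absent from `mapping` are kept in the profiles but listed in the
#' `unmapped` attribute so they are reported rather than silently dropped.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param mapping optional metabolite-to-exchange map (see
#'   [load_exchange_map()]) used only to report unmapped metabolites.
#' @return List of `exchange_profile`, one per sample column, with attribute
#'   `unmapped` (character vector of metabolite ids missing from `mapping`).
#' @export
load_profiles <- function(path, mapping = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop("profile table needs a metabolite column plus >= 1 sample column")
  met <- tab[[1]]
  if (anyDuplicated(met))
    stop("duplicate metabolite row: ", met[duplicated(met)][1])
  samples <- names(tab)[-1]
  profs <- lapply(samples, function(s) {
    raw <- tab[[s]]
    if (all(!nzchar(trimws(raw))))
      stop("empty sample column: ", s)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric value in column '", s, "', row ", bad[1],
           " (metabolite '", met[bad[1]], "')")
    exchange_profile(s, stats::setNames(val, met),
                     cell_line = sub("-\\d+$", "", s))
  })
  names(profs) <- samples
  unmapped <- character(0)
  if (!is.null(mapping)) unmapped <- setdiff(met, mapping$metabolite)
  attr(profs, "unmapped") <- unmapped
  profs
}

#' Load a metabolite-to-exchange-reaction mapping table
#'
#' Two-column TSV (`metabolite`, `exchange`), mapping profile metabolite ids
#' to model exchange reaction ids.
#'
#' @param path file path.
#' @return data.frame with columns `metabolite` and `exchange`.
#' @export
load_exchange_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("metabolite", "exchange") %in% names(tab)))
    stop("mapping table needs columns 'metabolite' and 'exchange'")
  tab[c("metabolite", "exchange")]
}

#' Derive the metabolite-to-exchange map implied by a model
#'
#' Maps the single metabolite of every exchange reaction to that reaction;
#' convenient for fixtures, where profile metabolite ids are model ids.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `metabolite` and `exchange`.
#' @export
exchange_map_from_model <- function(model) {
  ex <- exchange_reactions(model)
  data.frame(metabolite = unname(exchange_metabolites(model, ex)),
             exchange = ex, stringsAsFactors = FALSE)
}
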