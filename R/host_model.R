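# ---- host genome-scale model ----------------------------------------------
#
# Reference dialect: a two-section TSV, hand-writable so that worked-example
# fixtures stay self-contained.
#
#   ## metabolites
#   model_id  compartment  name
#   ## reactions
#   id  equation  lb  ub  is_biomass  is_exchange
#
# Reaction equations are written over model metabolite ids with the same term
# grammar as reaction tables; exchange and biomass pseudo-reactions may have
# an empty right-hand side ("glc_e <=>" exports/imports glucose).

#' Load a host genome-scale metabolic model
#'
#' Reads the two-section TSV model dialect (see the package vignette) plus an
#' optional metabolite-to-KEGG-compound mapping table with columns
#' `model_id`, `kegg_id` and optional `manual_flag`.  Metabolites without a
#' mapping entry are retained with `kegg_id = NA` and counted in the mapping
#' report; several compartmental species may map to the same compound, but a
#' model id may not map to two compounds.
#'
#' @param stoich_path path to the model TSV.
#' @param mapping_path optional path to the mapping TSV.
#' @return object of class `hp_host_model` with elements `metabolites`
#'   (`data.frame` `model_id`, `compartment`, `name`, `kegg_id`), `reactions`
#'   (named list with `id`, `stoich` named numeric over model ids, `lb`,
#'   `ub`, `is_biomass`, `is_exchange`), `biomass_id`, `exchange_ids`, and
#'   `mapping_report`.
#' @export
load_host_model <- function(stoich_path, mapping_path = NULL) {
  lines <- readLines(stoich_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sec_met <- which(trimws(lines) == "## metabolites")
  sec_rxn <- which(trimws(lines) == "## reactions")
  if (length(sec_met) != 1L || length(sec_rxn) != 1L || sec_rxn < sec_met) {
    stop("host model file must contain a '## metabolites' section followed by a '## reactions' section")
  }
  read_sec <- function(from, to) {
    if (to < from) return(NULL)
    utils::read.delim(text = paste(lines[from:to], collapse = "\n"),
                      stringsAsFactors = FALSE, quote = "",
                      colClasses = "character")
  }
  mets <- read_sec(sec_met + 1L, sec_rxn - 1L)
  rxns <- read_sec(sec_rxn + 1L, length(lines))
  if (is.null(mets) || !all(c("model_id", "compartment") %in% names(mets))) {
    stop("metabolite section needs columns model_id, compartment")
  }
  if (is.null(rxns) || !all(c("id", "equation", "lb", "ub") %in% names(rxns))) {
    stop("reaction section needs columns id, equation, lb, ub")
  }
  if (anyDuplicated(mets$model_id))
    stop("duplicate metabolite model_id in host model")
  if (anyDuplicated(rxns$id))
    stop(sprintf("duplicate reaction id in host model: %s",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  if (!"name" %in% names(mets)) mets$name <- mets$model_id

  mapping <- NULL
  if (!is.null(mapping_path)) {
    mapping <- utils::read.delim(mapping_path, stringsAsFactors = FALSE,
                                 quote = "", colClasses = "character")
    stopifnot(all(c("model_id", "kegg_id") %in% names(mapping)))
    if (anyDuplicated(mapping$model_id))
      stop("mapping table maps a model_id to more than one compound")
  }
  mets$kegg_id <- if (is.null(mapping)) NA_character_ else
    mapping$kegg_id[match(mets$model_id, mapping$model_id)]
  mets$kegg_id[!is.na(mets$kegg_id) & !nzchar(mets$kegg_id)] <- NA_character_

  declared <- mets$model_id
  reactions <- list()
  for (i in seq_len(nrow(rxns))) {
    rid <- rxns$id[[i]]
    eq <- parse_equation(rxns$equation[[i]], compound_table = NULL,
                         allow_empty_side = TRUE)
    stoich <- numeric()
    for (k in seq_len(nrow(eq$substrates))) {
      cid <- eq$substrates$name[[k]]  # model ids are used verbatim
      stoich[cid] <- (if (cid %in% names(stoich)) stoich[[cid]] else 0) -
        eq$substrates$coef[[k]]
    }
    for (k in seq_len(nrow(eq$products))) {
      cid <- eq$products$name[[k]]
      stoich[cid] <- (if (cid %in% names(stoich)) stoich[[cid]] else 0) +
        eq$products$coef[[k]]
    }
    stoich <- stoich[abs(stoich) > 1e-12]
    bad <- setdiff(names(stoich), declared)
    if (length(bad)) {
      stop(sprintf("reaction %s references undeclared metabolite(s): %s",
                   rid, paste(bad, collapse = ", ")))
    }
    lb <- as.numeric(rxns$lb[[i]]); ub <- as.numeric(rxns$ub[[i]])
    if (!is.finite(lb) || !is.finite(ub) || lb > ub)
      stop(sprintf("reaction %s has invalid bounds [%s, %s]", rid,
                   rxns$lb[[i]], rxns$ub[[i]]))
    reactions[[rid]] <- list(
      id = rid, stoich = stoich, lb = lb, ub = ub,
      is_biomass = tab_cell(rxns, "is_biomass", i) %in% c("1", "TRUE", "true"),
      is_exchange = tab_cell(rxns, "is_exchange", i) %in% c("1", "TRUE", "true"))
  }
  biomass_ids <- names(reactions)[vapply(reactions, `[[`, logical(1), "is_biomass")]
  if (length(biomass_ids) != 1L) {
    stop(sprintf("host model must designate exactly one biomass reaction (found %d)",
                 length(biomass_ids)))
  }
  exchange_ids <- names(reactions)[vapply(reactions, `[[`, logical(1), "is_exchange")]
  structure(list(
    metabolites = mets,
    reactions = reactions,
    biomass_id = biomass_ids,
    exchange_ids = exchange_ids,
    mapping_report = list(
      n_metabolites = nrow(mets),
      n_mapped = sum(!is.na(mets$kegg_id)),
      unmapped = mets$model_id[is.na(mets$kegg_id)])),
    class = "hp_host_model")
}

#' @export
print.hp_host_model <- function(x, ...) {
  cat(sprintf("<hp_host_model> %d metabolites (%d KEGG-mapped), %d reactions, biomass = %s, %d exchanges\n",
              nrow(x$metabolites), x$mapping_report$n_mapped,
              length(x$reactions), x$biomass_id, length(x$exchange_ids)))
  invisible(x)
}

# translate a model-id stoichiometry vector into compound-id space,
# merging compartmental species of the same compound; returns NULL if any
# metabolite is unmapped
stoich_to_kegg <- function(stoich, mets) {
  kegg <- mets$kegg_id[match(names(stoich), mets$model_id)]
  if (anyNA(kegg)) return(NULL)
  v <- tapply(unname(stoich), kegg, sum)
  v <- stats::setNames(as.numeric(v), names(v))
  v[abs(v) > 1e-12]
}

#' Native metabolite and reaction sets of a host
#'
#' The starting point of the network expansion: `M0` is the
#' compartment-collapsed set of KEGG compound identifiers present anywhere in
#' the host model, and `R0` is the set of stoichiometric signatures of native
#' reactions expressed over those identifiers.  Reactions containing any
#' unmapped metabolite, exchange and biomass pseudo-reactions, and reactions
#' whose stoichiometry cancels under compartment collapse (pure transport)
#' are excluded from `R0`, since they cannot be compared against
#' database-space reactions.
#'
#' @param model an `hp_host_model`.
#' @return list with `M0` (character compound ids) and `R0` (character
#'   signatures).
#' @export
native_sets <- function(model) {
  M0 <- sort(unique(model$metabolites$kegg_id[!is.na(model$metabolites$kegg_id)]))
  sigs <- character()
  for (r in model$reactions) {
    if (r$is_biomass || r$is_exchange) next
    v <- stoich_to_kegg(r$stoich, model$metabolites)
    if (is.null(v) || length(v) == 0L) next
    if (all(v > 0) || all(v < 0)) next  # one-sided after collapse
    fake <- list(
      substrates = data.frame(compound = names(v)[v < 0], coef = -unname(v[v < 0]),
                              stringsAsFactors = FALSE),
      products = data.frame(compound = names(v)[v > 0], coef = unname(v[v > 0]),
                            stringsAsFactors = FALSE))
    sigs <- c(sigs, reaction_signature(fake))
  }
  list(M0 = M0, R0 = sort(unique(sigs)))
}
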