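# ---- compound identifiers -------------------------------------------------

KEGG_ID_RE <- "^[A-Za-z][0-9]+$"

#' Resolve a compound token to a stable compound identifier
#'
#' Tokens that already look like KEGG compound identifiers (a letter followed
#' by digits, e.g. `"C02457"`) are returned as-is.  Other tokens are treated
#' as compound names: they are matched case-insensitively against an optional
#' name-to-identifier table, and names with no entry are assigned a
#' deterministic synthetic identifier in the reserved `X_` namespace so that
#' the same name always maps to the same identifier.
#'
#' @param token character vector of compound tokens (identifiers or names).
#' @param compound_table optional `data.frame` with columns `name` and
#'   `compound_id` used to resolve names to identifiers.
#' @return character vector of compound identifiers.
#' @export
#' @examples
#' resolve_compound("C00022")
#' resolve_compound("pentane-2,4-dione")
resolve_compound <- function(token, compound_table = NULL) {
  token <- trimws(token)
  out <- character(length(token))
  is_id <- grepl(KEGG_ID_RE, token)
  out[is_id] <- toupper(token[is_id])
  if (any(!is_id)) {
    nm <- normalize_compound_name(token[!is_id])
    resolved <- rep(NA_character_, length(nm))
    if (!is.null(compound_table)) {
      stopifnot(all(c("name", "compound_id") %in% names(compound_table)))
      key <- normalize_compound_name(compound_table$name)
      idx <- match(nm, key)
      resolved <- as.character(compound_table$compound_id)[idx]
    }
    slug <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", nm))
    synth <- paste0("X_", slug)
    resolved[is.na(resolved)] <- synth[is.na(resolved)]
    out[!is_id] <- resolved
  }
  out
}

normalize_compound_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# ---- equation parsing -----------------------------------------------------

EQ_SEPARATORS <- c("<=>", "↔", "=")

# a term coefficient token: plain integer or decimal
is_numeric_coef <- function(tok) grepl("^[0-9]+$|^[0-9]*\\.[0-9]+$", tok)
# symbolic/polymer coefficients such as "n", "2n", "(n+1)", "m"
is_symbolic_coef <- function(tok) {
  grepl("^\\(?[0-9]*[nmx]([+-][0-9]+)?\\)?$", tok)
}

parse_side <- function(side, compound_table, line_label) {
  side <- trimws(side)
  if (!nzchar(side)) {
    return(data.frame(compound = character(), name = character(),
                      coef = numeric(), stringsAsFactors = FALSE))
  }
  terms <- trimws(strsplit(side, "\\s\\+\\s")[[1]])
  terms <- terms[nzchar(terms)]
  coefs <- numeric(length(terms))
  names_out <- character(length(terms))
  for (k in seq_along(terms)) {
    toks <- strsplit(terms[[k]], "[[:space:]]+")[[1]]
    coef <- 1
    if (length(toks) > 1L && is_numeric_coef(toks[[1]])) {
      coef <- as.numeric(toks[[1]])
      toks <- toks[-1L]
    } else if (length(toks) > 1L && is_symbolic_coef(toks[[1]])) {
      stop(hp_condition(
        sprintf("symbolic coefficient '%s' in %s", toks[[1]], line_label),
        class = "hetpath_symbolic_coef"))
    }
    if (length(toks) == 0L || (length(toks) == 1L && is_numeric_coef(toks[[1]]))) {
      stop(hp_condition(sprintf("term '%s' has no compound token in %s",
                                terms[[k]], line_label),
                        class = "hetpath_parse_error"))
    }
    if (coef <= 0 || !is.finite(coef)) {
      stop(hp_condition(sprintf("non-positive coefficient in %s", line_label),
                        class = "hetpath_parse_error"))
    }
    coefs[[k]] <- coef
    names_out[[k]] <- paste(toks, collapse = " ")
  }
  data.frame(compound = resolve_compound(names_out, compound_table),
             name = names_out, coef = coefs, stringsAsFactors = FALSE)
}

hp_condition <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Parse a reaction equation string
#'
#' Accepts the KEGG-ligand equation dialect used in reaction dumps and in
#' printed pathway tables: terms joined by `" + "`, an optional leading
#' numeric stoichiometric coefficient per term (default 1), and one of the
#' separators `"<=>"`, `"↔"` or `"="` between the two sides.  Compound
#' tokens may be KEGG identifiers or free-text names (resolved through
#' `compound_table`, see [resolve_compound()]).
#'
#' Equations with symbolic polymer coefficients (`"n"`, `"(n+1)"`, ...) are
#' rejected with a condition of class `"hetpath_symbolic_coef"`; equations
#' without exactly one separator raise `"hetpath_parse_error"`.
#'
#' @param text single equation string.
#' @param compound_table optional name-to-identifier table.
#' @param allow_empty_side allow an empty product side (used for exchange and
#'   biomass pseudo-reactions in host models); default `FALSE`.
#' @return list with `substrates` and `products`, each a `data.frame` with
#'   columns `compound`, `name`, `coef` in the order written.
#' @export
#' @examples
#' parse_equation("C00022 + C00004 <=> C00186 + C00003")
parse_equation <- function(text, compound_table = NULL, allow_empty_side = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  sep_hits <- EQ_SEPARATORS[vapply(EQ_SEPARATORS, function(s)
    grepl(s, text, fixed = TRUE), logical(1))]
  # "=" is a substring of "<=>"; prefer the longest separator present
  sep <- if ("<=>" %in% sep_hits) "<=>" else if ("↔" %in% sep_hits) "↔"
         else if ("=" %in% sep_hits) "=" else NULL
  if (is.null(sep)) {
    stop(hp_condition(sprintf("no reaction separator (<=>, ↔, =) in '%s'", text),
                      class = "hetpath_parse_error"))
  }
  sides <- strsplit(text, sep, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) {
    stop(hp_condition(sprintf("more than one separator in '%s'", text),
                      class = "hetpath_parse_error"))
  }
  lab <- sprintf("equation '%s'", text)
  subs <- parse_side(sides[[1]], compound_table, lab)
  prods <- parse_side(sides[[2]], compound_table, lab)
  if (!allow_empty_side && (nrow(subs) == 0L || nrow(prods) == 0L)) {
    stop(hp_condition(sprintf("empty reaction side in %s", lab),
                      class = "hetpath_parse_error"))
  }
  list(substrates = subs, products = prods)
}

#' Serialize parsed equation sides back to the canonical text dialect
#'
#' @param eq list with `substrates` and `products` as from [parse_equation()].
#' @return single equation string using `"<=>"` and unit coefficients omitted.
#' @export
serialize_equation <- function(eq) {
  fmt_side <- function(df) {
    if (nrow(df) == 0L) return("")
    coefs <- vapply(df$coef, format, character(1), trim = TRUE, digits = 12)
    terms <- ifelse(df$coef == 1, df$compound, paste(coefs, df$compound))
    paste(terms, collapse = " + ")
  }
  paste(fmt_side(eq$substrates), "<=>", fmt_side(eq$products))
}

# ---- reactions ------------------------------------------------------------

# collapse repeated compounds within a side, then cancel compounds appearing
# on both sides (net stoichiometry); drops fully cancelling compounds
canonicalize_sides <- function(subs, prods) {
  tally <- function(df, sign) {
    if (nrow(df) == 0L) return(numeric())
    v <- tapply(df$coef, df$compound, sum) * sign
    stats::setNames(as.numeric(v), names(v))
  }
  net <- c(tally(subs, -1))
  p <- tally(prods, +1)
  for (cid in names(p)) net[cid] <- ifelse(cid %in% names(net),
                                           net[[cid]] + p[[cid]], p[[cid]])
  net <- net[abs(net) > 1e-12]
  list(
    substrates = data.frame(compound = names(net)[net < 0],
                            coef = -unname(net[net < 0]),
                            stringsAsFactors = FALSE),
    products = data.frame(compound = names(net)[net > 0],
                          coef = unname(net[net > 0]),
                          stringsAsFactors = FALSE)
  )
}

#' Construct a candidate heterologous reaction
#'
#' Stoichiometry is canonicalized to net form: repeated compounds within a
#' side are merged and compounds appearing on both sides are cancelled.
#' Reactions whose stoichiometry cancels completely are rejected.
#'
#' @param reaction_id unique identifier.
#' @param substrates,products `data.frame`s with columns `compound`, `coef`
#'   (positive), e.g. from [parse_equation()].
#' @param reversible logical; the expansion treats every reaction as usable in
#'   both directions, mirroring the all-reversible screening assumption.
#' @param ec,genes,organisms character vectors of annotations.
#' @return object of class `hp_reaction`.
#' @export
hp_reaction <- function(reaction_id, substrates, products, reversible = TRUE,
                        ec = character(), genes = character(),
                        organisms = character()) {
  stopifnot(nzchar(reaction_id))
  can <- canonicalize_sides(substrates, products)
  if (nrow(can$substrates) == 0L || nrow(can$products) == 0L) {
    stop(hp_condition(
      sprintf("reaction %s has empty net stoichiometry on one side", reaction_id),
      class = "hetpath_degenerate_reaction"))
  }
  stopifnot(all(is.finite(can$substrates$coef)), all(can$substrates$coef > 0),
            all(is.finite(can$products$coef)), all(can$products$coef > 0))
  structure(list(reaction_id = reaction_id,
                 substrates = can$substrates,
                 products = can$products,
                 reversible = isTRUE(reversible),
                 ec = ec, genes = genes, organisms = organisms,
                 km = NULL),
            class = "hp_reaction")
}

#' @export
print.hp_reaction <- function(x, ...) {
  cat(sprintf("<hp_reaction %s> %s\n", x$reaction_id, serialize_equation(x)))
  if (length(x$ec)) cat("  EC:", paste(x$ec, collapse = "; "), "\n")
  if (!is.null(x$km))
    cat(sprintf("  min Km: %.4g mM (%s)\n", x$km$km_value, x$km$organism))
  invisible(x)
}

#' Canonical stoichiometric signature of a reaction
#'
#' The signature is invariant under reordering of terms and under swapping
#' the two sides (reactions are treated as reversible), so two reactions with
#' the same net stoichiometry over the same compound identifiers always share
#' a signature.  Orientation is normalized by requiring the coefficient of
#' the lexicographically smallest compound to be positive.
#'
#' @param r an `hp_reaction`, or a list with `substrates`/`products` frames.
#' @return single character signature.
#' @export
#' @examples
#' r1 <- hp_reaction("r1", parse_equation("A1 + B1 <=> D1")$substrates,
#'                   parse_equation("A1 + B1 <=> D1")$products)
#' r2 <- hp_reaction("r2", parse_equation("D1 <=> B1 + A1")$substrates,
#'                   parse_equation("D1 <=> B1 + A1")$products)
#' identical(reaction_signature(r1), reaction_signature(r2))
reaction_signature <- function(r) {
  net <- stats::setNames(
    c(-r$substrates$coef, r$products$coef),
    c(r$substrates$compound, r$products$compound))
  net <- net[order(names(net))]
  if (net[[1]] < 0) net <- -net
  paste(sprintf("%s:%s", names(net),
                vapply(net, format, character(1), trim = TRUE, digits = 12)),
        collapse = "|")
}

# ---- reaction database ----------------------------------------------------

split_list_col <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

tab_cell <- function(tab, col, i) {
  if (col %in% names(tab)) tab[[col]][[i]] else ""
}

#' Load a reaction database from a KEGG-ligand-style TSV table
#'
#' The table must have columns `reaction_id` and `equation`; optional columns
#' `ec`, `genes` and `organisms` hold semicolon-separated annotation lists.
#' Rows whose equations cannot be used as stoichiometric candidates (symbolic
#' polymer coefficients, missing separator, fully cancelling stoichiometry)
#' are recorded in the skip report with a reason rather than silently
#' dropped.  Reactions sharing a stoichiometric signature are collapsed to
#' one representative that keeps the union of annotations, so heterologous
#' additions are never double counted.
#'
#' @param path TSV file path.
#' @param compound_table optional name-to-identifier table (`data.frame` or
#'   TSV path with columns `name`, `compound_id`).
#' @param collapse_duplicates collapse signature duplicates (default `TRUE`).
#' @return object of class `hp_reaction_db` with elements `reactions` (named
#'   list of `hp_reaction`), `compounds` (character), `skip` (`data.frame`
#'   `reaction_id`, `reason`) and `duplicates` (`data.frame` `kept`,
#'   `dropped`).
#' @export
load_reaction_table <- function(path, compound_table = NULL,
                                collapse_duplicates = TRUE) {
  if (is.character(compound_table)) {
    compound_table <- utils::read.delim(compound_table, stringsAsFactors = FALSE,
                                        quote = "", comment.char = "")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  req <- c("reaction_id", "equation")
  if (!all(req %in% names(tab))) {
    stop(sprintf("reaction table %s is missing required column(s): %s",
                 path, paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  if (anyDuplicated(tab$reaction_id)) {
    stop(sprintf("duplicate reaction_id in %s: %s", path,
                 paste(unique(tab$reaction_id[duplicated(tab$reaction_id)]),
                       collapse = ", ")))
  }
  reactions <- list()
  skip <- data.frame(reaction_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    rid <- tab$reaction_id[[i]]
    r <- tryCatch({
      eq <- parse_equation(tab$equation[[i]], compound_table)
      hp_reaction(rid, eq$substrates, eq$products,
                  ec = split_list_col(tab_cell(tab, "ec", i)),
                  genes = split_list_col(tab_cell(tab, "genes", i)),
                  organisms = split_list_col(tab_cell(tab, "organisms", i)))
    }, error = function(e) e)
    if (inherits(r, "error")) {
      skip <- rbind(skip, data.frame(reaction_id = rid,
                                     reason = conditionMessage(r),
                                     stringsAsFactors = FALSE))
    } else {
      reactions[[rid]] <- r
    }
  }
  db <- structure(list(reactions = reactions, skip = skip,
                       duplicates = data.frame(kept = character(),
                                               dropped = character(),
                                               stringsAsFactors = FALSE)),
                  class = "hp_reaction_db")
  if (collapse_duplicates) db <- dedupe_reactions(db)
  db$compounds <- db_compounds(db)
  db
}

db_compounds <- function(db) {
  sort(unique(unlist(lapply(db$reactions, function(r)
    c(r$substrates$compound, r$products$compound)), use.names = FALSE)))
}

#' Collapse signature-duplicate reactions in a database
#'
#' @param db an `hp_reaction_db`.
#' @return the database with one representative per signature (smallest
#'   reaction id), annotations merged, and the `duplicates` frame filled in.
#' @export
dedupe_reactions <- function(db) {
  if (length(db$reactions) == 0L) return(db)
  ids <- sort(names(db$reactions))
  sigs <- vapply(db$reactions[ids], reaction_signature, character(1))
  keep <- !duplicated(sigs)
  dup <- data.frame(kept = ids[match(sigs[!keep], sigs)],
                    dropped = ids[!keep], stringsAsFactors = FALSE)
  merged <- db$reactions[ids[keep]]
  for (j in seq_len(nrow(dup))) {
    k <- dup$kept[[j]]; d <- db$reactions[[dup$dropped[[j]]]]
    merged[[k]]$ec <- union(merged[[k]]$ec, d$ec)
    merged[[k]]$genes <- union(merged[[k]]$genes, d$genes)
    merged[[k]]$organisms <- union(merged[[k]]$organisms, d$organisms)
  }
  db$reactions <- merged
  db$duplicates <- dup
  db$compounds <- db_compounds(db)
  db
}

#' @export
print.hp_reaction_db <- function(x, ...) {
  cat(sprintf("<hp_reaction_db> %d reactions, %d compounds, %d skipped, %d duplicates collapsed\n",
              length(x$reactions), length(x$compounds), nrow(x$skip),
              nrow(x$duplicates)))
  invisible(x)
}

#' @export
length.hp_reaction_db <- function(x) length(x$reactions)

# ---- Km annotation --------------------------------------------------------

ec_matches <- function(rxn_ec, row_ec) {
  if (rxn_ec == row_ec) return(TRUE)
  if (endsWith(rxn_ec, "-")) {
    prefix <- sub("-$", "", rxn_ec)
    return(startsWith(row_ec, prefix))
  }
  FALSE
}

#' Annotate reactions with the minimum-Km source organism
#'
#' For each reaction with at least one EC number matching a row of the Km
#' table, the row with the minimum Michaelis constant is attached (ties are
#' broken alphabetically by organism name).  The minimum-Km ortholog marks
#' the organism whose enzyme is expected to have the highest substrate
#' affinity, a practical guide for choosing the gene source.  Wildcard EC
#' numbers such as `"1.3.99.-"` match by prefix on the defined digits.
#'
#' @param db an `hp_reaction_db`.
#' @param km_table `data.frame` (or TSV path) with columns `ec`, `organism`,
#'   `km_mM` (Michaelis constant in mM, positive).
#' @return the database with `km` fields (`km_value`, `organism`) filled
#'   where a match exists; unmatched reactions stay unannotated.
#' @export
attach_km <- function(db, km_table) {
  if (is.character(km_table)) {
    km_table <- utils::read.delim(km_table, stringsAsFactors = FALSE,
                                  quote = "", comment.char = "")
  }
  stopifnot(all(c("ec", "organism", "km_mM") %in% names(km_table)))
  stopifnot(all(km_table$km_mM > 0))
  for (rid in names(db$reactions)) {
    ecs <- db$reactions[[rid]]$ec
    if (length(ecs) == 0L) next
    hit <- vapply(seq_len(nrow(km_table)), function(j)
      any(vapply(ecs, ec_matches, logical(1), row_ec = km_table$ec[[j]])),
      logical(1))
    if (!any(hit)) next
    rows <- km_table[hit, , drop = FALSE]
    rows <- rows[order(rows$km_mM, rows$organism), , drop = FALSE]
    db$reactions[[rid]]$km <- list(km_value = rows$km_mM[[1]],
                                   organism = rows$organism[[1]])
  }
  db
}

#' Write the skip report of a reaction database
#'
#' @param db an `hp_reaction_db`.
#' @param path output TSV path.
#' @export
write_skip_report <- function(db, path) {
  utils::write.table(db$skip, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
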