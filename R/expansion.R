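# ---- iterative network expansion ------------------------------------------
#
# The host network (M0, R0) is grown by admitting candidate reactions from
# the database in rounds.  At round i a reaction joins Ri when (a) its
# stoichiometric signature is not already in the network, (b) one of its two
# firing directions is enabled by the metabolites accumulated so far, and
# (c) that direction produces at least one compound not yet reachable.  The
# newly produced compounds form Mi.  Every reaction is tried in both
# directions because reversibility information in reaction databases is too
# sparse to trust; implausible directions are left to downstream curation.

side_of <- function(r, direction) {
  if (direction == "forward") list(sub = r$substrates, prod = r$products)
  else list(sub = r$products, prod = r$substrates)
}

#' Expand a host metabolic network with heterologous reactions
#'
#' Runs the iterative expansion to termination (no further reaction
#' connectable).  Under the default `all_substrates` firing rule a direction
#' fires only when every substrate of that direction is already reachable —
#' the stoichiometrically meaningful choice; `any_substrate` (one reachable
#' substrate suffices) is provided as a permissive variant and always
#' connects a superset of compounds, never later.
#'
#' @param M0 character vector of native compound ids.
#' @param R0 character vector of native reaction signatures
#'   (see [native_sets()]).
#' @param db an `hp_reaction_db` of candidate heterologous reactions.
#' @param firing_rule `"all_substrates"` (default) or `"any_substrate"`.
#' @return object of class `hp_expansion` with `layers` (list of
#'   `list(index, Ri, Mi)` where `Ri` is a `data.frame` of
#'   `reaction_id`, `direction` and `Mi` a character vector), `producer_map`
#'   (`data.frame` `compound`, `reaction_id`, `direction`, `iteration`),
#'   `M0`, `terminated = TRUE`, and the database for backtracing.
#' @export
expand_network <- function(M0, R0, db,
                           firing_rule = c("all_substrates", "any_substrate")) {
  firing_rule <- match.arg(firing_rule)
  stopifnot(inherits(db, "hp_reaction_db"))
  R0 <- unique(R0)
  reachable <- unique(M0)
  rxn_ids <- sort(names(db$reactions))
  sigs <- vapply(db$reactions[rxn_ids], reaction_signature, character(1))
  # candidates must not already exist in the native network
  pool <- rxn_ids[!(sigs %in% R0)]

  layers <- list()
  producer <- data.frame(compound = character(), reaction_id = character(),
                         direction = character(), iteration = integer(),
                         stringsAsFactors = FALSE)
  admitted <- character()
  i <- 0L
  repeat {
    # closure semantics: reactions already admitted in earlier rounds stay in
    # the expanded network, so a direction enabled only later can still fire
    # and connect further compounds; the reaction itself joins Ri only once
    cand <- list()
    for (rid in pool) {
      r <- db$reactions[[rid]]
      for (dir in c("forward", "reverse")) {
        s <- side_of(r, dir)
        fires <- if (firing_rule == "all_substrates")
          all(s$sub$compound %in% reachable)
        else any(s$sub$compound %in% reachable)
        if (!fires) next
        new_comp <- setdiff(s$prod$compound, reachable)
        if (length(new_comp) == 0L) next
        cand[[length(cand) + 1L]] <- list(rid = rid, dir = dir, new = new_comp)
      }
    }
    if (length(cand) == 0L) break
    i <- i + 1L
    Ri <- data.frame(
      reaction_id = vapply(cand, `[[`, character(1), "rid"),
      direction = vapply(cand, `[[`, character(1), "dir"),
      stringsAsFactors = FALSE)
    Ri <- Ri[!(Ri$reaction_id %in% admitted), , drop = FALSE]
    rownames(Ri) <- NULL
    Mi <- sort(unique(unlist(lapply(cand, `[[`, "new"))))
    # deterministic producer choice: smallest reaction id, forward first
    for (m in Mi) {
      producing <- Filter(function(x) m %in% x$new, cand)
      ord <- order(vapply(producing, `[[`, character(1), "rid"),
                   vapply(producing, `[[`, character(1), "dir"))
      pick <- producing[[ord[[1]]]]
      producer <- rbind(producer, data.frame(
        compound = m, reaction_id = pick$rid, direction = pick$dir,
        iteration = i, stringsAsFactors = FALSE))
    }
    layers[[i]] <- list(index = i, Ri = Ri, Mi = Mi)
    reachable <- c(reachable, Mi)
    admitted <- c(admitted, unique(Ri$reaction_id))
  }
  structure(list(layers = layers, producer_map = producer,
                 M0 = unique(M0), terminated = TRUE,
                 firing_rule = firing_rule, db = db),
            class = "hp_expansion")
}

#' @export
print.hp_expansion <- function(x, ...) {
  cat(sprintf("<hp_expansion> %d iteration(s), %d nonnative compound(s) connected (firing rule: %s)\n",
              length(x$layers), nrow(x$producer_map), x$firing_rule))
  invisible(x)
}

#' Iteration at which a target compound connects to the network
#'
#' @param result an `hp_expansion`.
#' @param target compound id.
#' @return list with `status` (`"connected"`, `"native"` or
#'   `"not_connected"`) and `iteration` (layer index for connected targets,
#'   `0` for native, `NA` otherwise).
#' @export
connection_iteration <- function(result, target) {
  stopifnot(inherits(result, "hp_expansion"), isTRUE(result$terminated))
  if (target %in% result$M0)
    return(list(status = "native", iteration = 0L))
  k <- match(target, result$producer_map$compound)
  if (is.na(k)) return(list(status = "not_connected", iteration = NA_integer_))
  list(status = "connected", iteration = result$producer_map$iteration[[k]])
}

#' Backtrace the heterologous reaction set for a connected target
#'
#' Starting from the target's producer reaction, recursively includes the
#' producer of every nonnative substrate of each included reaction (taken in
#' its recorded firing direction).  The result is one deterministic pathway,
#' minimal in connection iteration (producers were chosen in the shallowest
#' layer); it is not guaranteed to be minimum-cardinality over all possible
#' reaction subsets.
#'
#' @param result an `hp_expansion`.
#' @param target compound id; a native target yields an empty pathway.
#' @return object of class `hp_pathway`: `target`, `reactions`
#'   (`data.frame` `reaction_id`, `direction`, `iteration` ordered by
#'   iteration then id), `n_reactions`, `connection_iteration`.
#' @export
backtrace <- function(result, target) {
  ci <- connection_iteration(result, target)
  if (ci$status == "not_connected")
    stop(sprintf("target %s is not connected to the host network", target))
  empty <- data.frame(reaction_id = character(), direction = character(),
                      iteration = integer(), stringsAsFactors = FALSE)
  if (ci$status == "native") {
    return(structure(list(target = target, reactions = empty,
                          n_reactions = 0L, connection_iteration = 0L),
                     class = "hp_pathway"))
  }
  pm <- result$producer_map
  included <- empty
  queue <- target
  seen_compounds <- character()
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    if (m %in% seen_compounds) next
    seen_compounds <- c(seen_compounds, m)
    k <- match(m, pm$compound)
    rid <- pm$reaction_id[[k]]; dir <- pm$direction[[k]]
    if (!any(included$reaction_id == rid & included$direction == dir)) {
      included <- rbind(included, data.frame(
        reaction_id = rid, direction = dir, iteration = pm$iteration[[k]],
        stringsAsFactors = FALSE))
      s <- side_of(result$db$reactions[[rid]], dir)
      nonnative <- setdiff(s$sub$compound, result$M0)
      queue <- c(queue, nonnative)
    }
  }
  included <- included[order(included$iteration, included$reaction_id), ,
                       drop = FALSE]
  rownames(included) <- NULL
  structure(list(target = target, reactions = included,
                 n_reactions = length(unique(included$reaction_id)),
                 connection_iteration = ci$iteration),
            class = "hp_pathway")
}

#' @export
print.hp_pathway <- function(x, ...) {
  cat(sprintf("<hp_pathway> target %s: %d heterologous reaction(s), connected at iteration %d\n",
              x$target, x$n_reactions, x$connection_iteration))
  if (nrow(x$reactions)) print(x$reactions)
  invisible(x)
}

#' Replay a pathway from the native metabolite set
#'
#' Fires the pathway's reactions in order (each in its recorded direction)
#' starting from `M0` and reports whether every reaction could fire under
#' the `all_substrates` rule and the target was produced — the sufficiency
#' check for a backtraced pathway.
#'
#' @param pathway an `hp_pathway`.
#' @param M0 native compound ids.
#' @param db the reaction database the pathway refers to.
#' @return logical.
#' @export
replay_pathway <- function(pathway, M0, db) {
  if (pathway$n_reactions == 0L) return(pathway$target %in% M0)
  avail <- unique(M0)
  for (j in seq_len(nrow(pathway$reactions))) {
    s <- side_of(db$reactions[[pathway$reactions$reaction_id[[j]]]],
                 pathway$reactions$direction[[j]])
    if (!all(s$sub$compound %in% avail)) return(FALSE)
    avail <- union(avail, s$prod$compound)
  }
  pathway$target %in% avail
}

#' Per-iteration and cumulative counts of connected metabolites
#'
#' @param result an `hp_expansion`.
#' @return `data.frame` with columns `iteration`, `n_new` (size of Mi) and
#'   `cumulative` (prefix sum); zero rows for a zero-layer result.
#' @export
iteration_curve <- function(result) {
  stopifnot(inherits(result, "hp_expansion"))
  n <- vapply(result$layers, function(l) length(l$Mi), integer(1))
  data.frame(iteration = seq_along(result$layers), n_new = n,
             cumulative = cumsum(n))
}

#' Export an expansion result as JSON
#'
#' @param result an `hp_expansion`.
#' @param path output path.
#' @export
write_expansion_json <- function(result, path) {
  out <- list(
    firing_rule = result$firing_rule,
    n_iterations = length(result$layers),
    layers = lapply(result$layers, function(l) list(
      index = l$index, reactions = l$Ri, compounds = l$Mi)),
    producer_map = result$producer_map)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Export a pathway as TSV
#'
#' Mirrors the screening-report column structure (reaction ids, firing
#' directions, EC numbers, genes, minimum-Km organism).
#'
#' @param pathway an `hp_pathway`.
#' @param db the reaction database (for annotations).
#' @param path output path.
#' @export
write_pathway_tsv <- function(pathway, db, path) {
  rx <- pathway$reactions
  ann <- function(rid, field) paste(db$reactions[[rid]][[field]], collapse = ";")
  out <- data.frame(
    target = rep(pathway$target, nrow(rx)),
    reaction_id = rx$reaction_id,
    direction = rx$direction,
    iteration = rx$iteration,
    equation = vapply(rx$reaction_id, function(r)
      serialize_equation(db$reactions[[r]]), character(1)),
    ec = vapply(rx$reaction_id, ann, character(1), field = "ec"),
    genes = vapply(rx$reaction_id, ann, character(1), field = "genes"),
    min_km_organism = vapply(rx$reaction_id, function(r) {
      km <- db$reactions[[r]]$km
      if (is.null(km)) "" else km$organism
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
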