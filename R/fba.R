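# ---- flux balance analysis ------------------------------------------------

HP_BIG_BOUND <- 1000  # conventional flux box for unconstrained reactions

#' Define a growth medium for flux balance analysis
#'
#' Exchange fluxes follow the usual sign convention: negative flux is
#' uptake.  The carbon source gets a finite uptake bound, a small set of
#' external metabolites is allowed to transport freely (CO2, water, sulfate,
#' ammonia, protons by default), oxygen uptake is capped to implement the
#' micro-aerobic condition, and every other exchange is closed for uptake
#' (secretion stays open).
#'
#' @param carbon_source compound id of the sole carbon source
#'   (default glucose, `"C00031"`).
#' @param carbon_uptake_max maximum uptake rate, mmol/gDW/h (default 10, the
#'   conventional glucose uptake used in genome-scale simulations).
#' @param oxygen_uptake_max oxygen uptake bound, mmol/gDW/h; the default 2
#'   is a small nonzero value implementing a micro-aerobic condition, and 0
#'   gives anaerobic growth.
#' @param free_exchanges compound ids with unbounded transport.
#' @param oxygen_id compound id of oxygen (default `"C00007"`).
#' @param yield_threshold_percent minimum yield (in percent) for a target to
#'   count as "produced" (default 1).
#' @return object of class `hp_medium`.
#' @export
medium_spec <- function(carbon_source = "C00031",
                        carbon_uptake_max = 10,
                        oxygen_uptake_max = 2,
                        free_exchanges = c("C00011", "C00001", "C00059",
                                           "C00014", "C00080"),
                        oxygen_id = "C00007",
                        yield_threshold_percent = 1) {
  stopifnot(carbon_uptake_max > 0, oxygen_uptake_max >= 0,
            yield_threshold_percent >= 0)
  structure(list(carbon_source = carbon_source,
                 carbon_uptake_max = carbon_uptake_max,
                 oxygen_uptake_max = oxygen_uptake_max,
                 free_exchanges = free_exchanges,
                 oxygen_id = oxygen_id,
                 yield_threshold_percent = yield_threshold_percent),
            class = "hp_medium")
}

#' Read / write a medium specification as JSON
#'
#' @param path JSON file path.
#' @export
read_medium <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(medium_spec))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop(sprintf("unknown medium key(s): %s",
                                paste(bad, collapse = ", ")))
  do.call(medium_spec, x)
}

#' @rdname read_medium
#' @param medium an `hp_medium`.
#' @export
write_medium <- function(medium, path) {
  jsonlite::write_json(unclass(medium), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# compound id represented by a single-metabolite exchange reaction;
# falls back to the model id when no mapping entry exists
exchange_compound <- function(r, mets) {
  ids <- names(r$stoich)
  kegg <- mets$kegg_id[match(ids, mets$model_id)]
  out <- unique(kegg[!is.na(kegg)])
  if (length(out) == 1L) return(out)
  if (length(ids) == 1L) return(ids)
  NA_character_
}

# model metabolite row for a compound id; cytosol preferred, then
# alphabetical compartment; a verbatim model id is accepted as fallback
model_row_for_compound <- function(cid, mets) {
  hits <- which(mets$kegg_id == cid & !is.na(mets$kegg_id))
  if (length(hits) == 0L) {
    if (cid %in% mets$model_id) return(cid)
    return(NA_character_)
  }
  comp <- mets$compartment[hits]
  ord <- order(comp != "c", comp)
  mets$model_id[hits[ord[[1]]]]
}

#' Build a flux model from a host, a heterologous pathway and a medium
#'
#' Assembles the stoichiometric matrix of the host model augmented with the
#' pathway's heterologous reactions (placed in the cytosol, reversible with
#' the conventional +/-1000 bound) and a demand column that exports the
#' target.  Nonnative compounds get fresh rows identified by their compound
#' id.  Medium bounds are applied to the host's exchange reactions.
#'
#' @param host an `hp_host_model`.
#' @param pathway an `hp_pathway` (may be empty for native targets).
#' @param db the reaction database resolving the pathway's reactions.
#' @param medium an `hp_medium`.
#' @param target compound id to couple to the demand column; must occur in
#'   the host (via the mapping) or in the pathway's reactions.
#' @return object of class `hp_flux_model`: `S` (dense matrix, rows =
#'   metabolites, columns = reactions), `lb`, `ub`, `columns` (ids),
#'   `biomass_col`, `demand_col`, `het_cols`, `carbon_exchange_col`,
#'   `kegg_rows` (compound id per row where known).
#' @export
build_flux_model <- function(host, pathway, db, medium, target) {
  stopifnot(inherits(host, "hp_host_model"), inherits(medium, "hp_medium"))
  mets <- host$metabolites
  rows <- mets$model_id
  kegg_rows <- mets$kegg_id
  cols <- character(); lb <- numeric(); ub <- numeric()
  entries <- list()  # per column: named stoich over row ids

  carbon_col <- NA_character_
  for (rid in names(host$reactions)) {
    r <- host$reactions[[rid]]
    l <- r$lb; u <- r$ub
    if (r$is_exchange) {
      cid <- exchange_compound(r, mets)
      # exchange stoich is negative on the metabolite: flux > 0 exports
      l <- 0
      if (!is.na(cid)) {
        if (cid == medium$carbon_source) {
          l <- -medium$carbon_uptake_max
          carbon_col <- rid
        } else if (cid == medium$oxygen_id) {
          l <- -medium$oxygen_uptake_max
        } else if (cid %in% medium$free_exchanges) {
          l <- -HP_BIG_BOUND
        }
      }
      u <- HP_BIG_BOUND
    }
    cols <- c(cols, rid); lb <- c(lb, l); ub <- c(ub, u)
    entries[[rid]] <- r$stoich
  }

  # heterologous columns: compounds mapped onto cytosolic host rows where
  # possible, new rows otherwise
  het_cols <- character()
  resolve_row <- function(cid) {
    mid <- model_row_for_compound(cid, mets)
    if (!is.na(mid)) return(mid)
    if (!(cid %in% rows)) {
      rows <<- c(rows, cid)
      kegg_rows <<- c(kegg_rows, cid)
    }
    cid
  }
  if (!is.null(pathway) && pathway$n_reactions > 0L) {
    for (rid in unique(pathway$reactions$reaction_id)) {
      r <- db$reactions[[rid]]
      if (is.null(r)) stop(sprintf("pathway reaction %s not in database", rid))
      st <- numeric()
      for (k in seq_len(nrow(r$substrates))) {
        rowid <- resolve_row(r$substrates$compound[[k]])
        st[rowid] <- (if (rowid %in% names(st)) st[[rowid]] else 0) -
          r$substrates$coef[[k]]
      }
      for (k in seq_len(nrow(r$products))) {
        rowid <- resolve_row(r$products$compound[[k]])
        st[rowid] <- (if (rowid %in% names(st)) st[[rowid]] else 0) +
          r$products$coef[[k]]
      }
      col <- paste0("HET_", rid)
      cols <- c(cols, col); lb <- c(lb, -HP_BIG_BOUND); ub <- c(ub, HP_BIG_BOUND)
      entries[[col]] <- st
      het_cols <- c(het_cols, col)
    }
  }

  # demand column for the target
  target_row <- model_row_for_compound(target, mets)
  if (is.na(target_row)) {
    if (target %in% rows) target_row <- target
    else stop(sprintf("target %s occurs neither in the host nor in the pathway",
                      target))
  }
  dem <- "DM_target"
  cols <- c(cols, dem); lb <- c(lb, 0); ub <- c(ub, HP_BIG_BOUND)
  entries[[dem]] <- stats::setNames(-1, target_row)

  S <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  for (cn in names(entries)) S[names(entries[[cn]]), cn] <- entries[[cn]]

  structure(list(S = S, lb = stats::setNames(lb, cols),
                 ub = stats::setNames(ub, cols), columns = cols,
                 biomass_col = host$biomass_id, demand_col = dem,
                 het_cols = het_cols, carbon_exchange_col = carbon_col,
                 kegg_rows = stats::setNames(kegg_rows, rows),
                 target = target, medium = medium),
            class = "hp_flux_model")
}

#' @export
print.hp_flux_model <- function(x, ...) {
  cat(sprintf("<hp_flux_model> %d metabolites x %d reactions (%d heterologous), target %s\n",
              nrow(x$S), ncol(x$S), length(x$het_cols), x$target))
  invisible(x)
}

#' Maximize a flux objective under steady state
#'
#' Solves `max v[objective_column]` subject to `S v = 0` and the model's
#' bounds.
#'
#' @param fm an `hp_flux_model`.
#' @param objective_column column id (e.g. `fm$biomass_col` or
#'   `fm$demand_col`).
#' @param extra_lb,extra_ub optional named vectors overriding bounds.
#' @return object of class `hp_fba_result`: `status`, `objective_value`,
#'   `fluxes` (named).
#' @export
fba_maximize <- function(fm, objective_column, extra_lb = NULL, extra_ub = NULL) {
  stopifnot(objective_column %in% fm$columns)
  lb <- fm$lb; ub <- fm$ub
  if (!is.null(extra_lb)) lb[names(extra_lb)] <- pmax(lb[names(extra_lb)], extra_lb)
  if (!is.null(extra_ub)) ub[names(extra_ub)] <- pmin(ub[names(extra_ub)], extra_ub)
  obj <- as.numeric(fm$columns == objective_column)
  res <- solve_lp(obj, fm$S, b = rep(0, nrow(fm$S)), lb = lb, ub = ub,
                  maximize = TRUE)
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = stats::setNames(res$solution, fm$columns),
                 objective_column = objective_column),
            class = "hp_fba_result")
}

#' @export
print.hp_fba_result <- function(x, ...) {
  cat(sprintf("<hp_fba_result> %s; objective (%s) = %s\n", x$status,
              x$objective_column,
              format(x$objective_value, digits = 8)))
  invisible(x)
}

#' Producibility of the target under maximum production flux
#'
#' A nonnative metabolite whose maximum production flux is zero is
#' non-producible under the given medium.
#'
#' @param fm an `hp_flux_model`.
#' @param zero_tol flux tolerance below which production counts as zero
#'   (default 1e-6).
#' @return list with `producible` (logical), `max_flux`, and the full
#'   `result`.
#' @export
producibility <- function(fm, zero_tol = 1e-6) {
  res <- fba_maximize(fm, fm$demand_col)
  ok <- identical(res$status, "optimal") && res$objective_value > zero_tol
  list(producible = ok,
       max_flux = if (identical(res$status, "optimal")) res$objective_value
                  else NA_real_,
       result = res)
}

#' Target production at fixed maximal biomass
#'
#' Lexicographic two-stage optimization resolving degenerate growth optima:
#' biomass production is maximized first, then the target demand flux is
#' maximized with the biomass flux fixed at its optimum (within a relative
#' tolerance), yielding a unique production flux at maximal growth.
#'
#' @param fm an `hp_flux_model`.
#' @param fix_tol absolute tolerance for fixing the biomass optimum
#'   (default 1e-9, so any flux leaked from the fixed optimum into the
#'   target stays below the zero-flux tolerance).
#' @return list with `status`, `biomass_opt`, `target_flux`, and the
#'   stage-2 `result` (an `hp_fba_result`).
#' @export
biomass_coupled_production <- function(fm, fix_tol = 1e-9) {
  s1 <- fba_maximize(fm, fm$biomass_col)
  if (!identical(s1$status, "optimal")) {
    return(list(status = s1$status, biomass_opt = NA_real_,
                target_flux = NA_real_, result = s1))
  }
  bstar <- s1$objective_value
  slack <- fix_tol
  s2 <- fba_maximize(fm, fm$demand_col,
                     extra_lb = stats::setNames(bstar - slack, fm$biomass_col))
  list(status = s2$status, biomass_opt = bstar,
       target_flux = if (identical(s2$status, "optimal"))
         s2$fluxes[[fm$demand_col]] else NA_real_,
       result = s2)
}

#' Molar production yield in percent
#'
#' Yield is defined as mol target produced per mol carbon source taken up,
#' times 100.  The uptake flux is read off the carbon-source exchange column
#' of the solved model (uptake is negative flux).
#'
#' @param result an `hp_fba_result` with optimal status.
#' @param fm the `hp_flux_model` the result belongs to.
#' @return list with `yield_percent`, `demand_flux`, `uptake_flux`, and
#'   `produced` (yield at or above the medium's threshold).
#' @export
yield_percent <- function(result, fm) {
  stopifnot(inherits(result, "hp_fba_result"))
  if (!identical(result$status, "optimal")) {
    return(list(yield_percent = NA_real_, demand_flux = NA_real_,
                uptake_flux = NA_real_, produced = FALSE))
  }
  demand <- result$fluxes[[fm$demand_col]]
  if (is.na(fm$carbon_exchange_col)) {
    stop("flux model has no carbon-source exchange column")
  }
  uptake <- -result$fluxes[[fm$carbon_exchange_col]]
  if (uptake <= 1e-9) {
    if (demand > 1e-6) {
      stop("inconsistent solution: positive target demand with zero carbon uptake")
    }
    return(list(yield_percent = 0, demand_flux = demand, uptake_flux = uptake,
                produced = FALSE))
  }
  y <- 100 * demand / uptake
  list(yield_percent = y, demand_flux = demand, uptake_flux = uptake,
       produced = y >= fm$medium$yield_threshold_percent)
}

#' Steady-state residual of a solved flux model
#'
#' @param fm an `hp_flux_model`.
#' @param result an `hp_fba_result`.
#' @return max-norm of `S v`.
#' @export
steady_state_residual <- function(fm, result) {
  max(abs(fm$S %*% result$fluxes))
}

# net production of a compound by the heterologous subnetwork at a solved
# optimum (positive = net produced); used for by-product bookkeeping
het_net_production <- function(fm, result, compound_id) {
  if (length(fm$het_cols) == 0L) return(0)
  rows_m <- names(fm$kegg_rows)[!is.na(fm$kegg_rows) & fm$kegg_rows == compound_id]
  if (length(rows_m) == 0L) return(0)
  sum(fm$S[rows_m, fm$het_cols, drop = FALSE] %*% result$fluxes[fm$het_cols])
}
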