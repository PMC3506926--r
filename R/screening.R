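# ---- genome-wide screening ------------------------------------------------

#' Screen all connectable nonnative metabolites of a host
#'
#' Runs the network expansion to termination, backtraces the heterologous
#' pathway for every connected nonnative compound, and evaluates each target
#' by flux balance analysis under two objectives: maximum target production
#' flux (producibility), and target flux at fixed maximal biomass
#' (growth-coupled production).  Per-target by-product bookkeeping reports
#' the net oxygen, NAD+ and NADP+ production of the heterologous subnetwork
#' at the growth-coupled optimum — the two mechanism classes by which
#' growth-coupled targets typically pay their way under micro-aerobic
#' conditions (oxygen evolution, and NADH/NADPH reoxidation).
#'
#' @param host an `hp_host_model`.
#' @param db an `hp_reaction_db`.
#' @param medium an `hp_medium`.
#' @param max_reactions optional cap: keep only targets whose pathway has at
#'   most this many heterologous reactions.
#' @param firing_rule passed to [expand_network()].
#' @return `data.frame` of target records ordered by compound id; one row
#'   per connected nonnative compound.  Solver failures are recorded in
#'   `solver_status`, never fatal.
#' @export
screen_targets <- function(host, db, medium, max_reactions = NULL,
                           firing_rule = "all_substrates") {
  ns <- native_sets(host)
  ex <- expand_network(ns$M0, ns$R0, db, firing_rule)
  targets <- sort(unique(ex$producer_map$compound))
  rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    pw <- backtrace(ex, tg)
    ann <- function(field) paste(unlist(lapply(
      pw$reactions$reaction_id, function(r) db$reactions[[r]][[field]])),
      collapse = ";")
    km_orgs <- paste(unlist(lapply(pw$reactions$reaction_id, function(r) {
      km <- db$reactions[[r]]$km
      if (is.null(km)) NULL else km$organism
    })), collapse = ";")
    rec <- data.frame(
      target = tg,
      connection_iteration = pw$connection_iteration,
      n_heterologous_reactions = pw$n_reactions,
      reaction_ids = paste(pw$reactions$reaction_id, collapse = ";"),
      directions = paste(pw$reactions$direction, collapse = ";"),
      ec = ann("ec"), genes = ann("genes"), min_km_organism = km_orgs,
      producible_max_target = FALSE, yield_max_target = NA_real_,
      producible_max_biomass = FALSE, yield_max_biomass = NA_real_,
      biomass_opt = NA_real_,
      byproduct_o2 = NA_real_, byproduct_nad = NA_real_,
      byproduct_nadp = NA_real_,
      solver_status = "not_run", stringsAsFactors = FALSE)
    res <- tryCatch({
      fm <- build_flux_model(host, pw, db, medium, tg)
      pr <- producibility(fm)
      rec$producible_max_target <- pr$producible
      if (identical(pr$result$status, "optimal")) {
        rec$yield_max_target <- yield_percent(pr$result, fm)$yield_percent
      }
      bc <- biomass_coupled_production(fm)
      rec$biomass_opt <- bc$biomass_opt
      if (identical(bc$status, "optimal")) {
        y <- yield_percent(bc$result, fm)
        rec$yield_max_biomass <- y$yield_percent
        rec$producible_max_biomass <- y$produced
        rec$byproduct_o2 <- het_net_production(fm, bc$result, "C00007")
        rec$byproduct_nad <- het_net_production(fm, bc$result, "C00003")
        rec$byproduct_nadp <- het_net_production(fm, bc$result, "C00006")
      }
      rec$solver_status <- paste(pr$result$status, bc$status, sep = "/")
      rec
    }, error = function(e) {
      rec$solver_status <- paste0("error: ", conditionMessage(e))
      rec
    })
    rows[[i]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    target = character(), connection_iteration = integer(),
    n_heterologous_reactions = integer(), reaction_ids = character(),
    directions = character(), ec = character(), genes = character(),
    min_km_organism = character(), producible_max_target = logical(),
    yield_max_target = numeric(), producible_max_biomass = logical(),
    yield_max_biomass = numeric(), biomass_opt = numeric(),
    byproduct_o2 = numeric(), byproduct_nad = numeric(),
    byproduct_nadp = numeric(), solver_status = character(),
    stringsAsFactors = FALSE)
  if (!is.null(max_reactions)) {
    out <- out[out$n_heterologous_reactions <= max_reactions, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# ---- chi-square category enrichment ---------------------------------------

chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-square enrichment of producible metabolites by functional category
#'
#' For each functional category, builds a contingency table of
#' growth-coupled-producible versus non-producible targets across hosts and
#' tests for departure from homogeneity with a raw (uncorrected) chi-square
#' statistic.  The default contingency structure compares all hosts at once
#' (hosts x produced/not); a per-host one-vs-rest 2x2 variant is available.
#' No multiple-testing correction is applied by default, matching the raw
#' significance threshold convention; Bonferroni is available as a flag.
#'
#' @param records_by_host named list of record frames from
#'   [screen_targets()], one per host.
#' @param category_map `data.frame` (or TSV path) with columns
#'   `compound_id`, `category`; many-to-many allowed.
#' @param alpha significance level (default 0.001).
#' @param mode `"hosts_by_produced"` (default) or `"one_vs_rest"`.
#' @param bonferroni apply Bonferroni correction over tested categories.
#' @return `data.frame` sorted by p-value with the per-host counts, the
#'   statistic, degrees of freedom, p-value, the contingency `mode`, and a
#'   `significant` flag; categories with an all-zero row or column margin
#'   are excluded and listed in the `"excluded"` attribute.
#' @export
category_enrichment <- function(records_by_host, category_map, alpha = 0.001,
                                mode = c("hosts_by_produced", "one_vs_rest"),
                                bonferroni = FALSE) {
  mode <- match.arg(mode)
  if (is.character(category_map)) {
    category_map <- utils::read.delim(category_map, stringsAsFactors = FALSE,
                                      quote = "")
  }
  stopifnot(all(c("compound_id", "category") %in% names(category_map)),
            length(names(records_by_host)) == length(records_by_host))
  hosts <- names(records_by_host)
  cats <- sort(unique(category_map$category))
  rows <- list(); excluded <- character()
  for (cat in cats) {
    comp <- category_map$compound_id[category_map$category == cat]
    counts <- t(vapply(hosts, function(h) {
      rec <- records_by_host[[h]]
      sel <- rec$target %in% comp
      c(produced = sum(rec$producible_max_biomass[sel]),
        not_produced = sum(!rec$producible_max_biomass[sel]))
    }, numeric(2)))
    tabs <- if (mode == "hosts_by_produced") {
      stats::setNames(list(counts), cat)
    } else {
      stats::setNames(lapply(hosts, function(h) {
        rbind(host = counts[h, ],
              rest = colSums(counts[setdiff(hosts, h), , drop = FALSE]))
      }), paste(cat, hosts, sep = "|"))
    }
    for (lab in names(tabs)) {
      tab <- tabs[[lab]]
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        excluded <- c(excluded, lab)
        next
      }
      cs <- chisq_stat(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        category = lab, mode = mode,
        n_produced = sum(tab[, "produced"]),
        n_not_produced = sum(tab[, "not_produced"]),
        statistic = cs$statistic, df = cs$df, p_value = cs$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    category = character(), mode = character(), n_produced = integer(),
    n_not_produced = integer(), statistic = numeric(), df = integer(),
    p_value = numeric(), stringsAsFactors = FALSE)
  thr <- if (bonferroni && nrow(out)) alpha / nrow(out) else alpha
  out$significant <- out$p_value < thr
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# ---- reports --------------------------------------------------------------

REPORT_NUMERIC_COLS <- c("yield_max_target", "yield_max_biomass",
                         "biomass_opt", "byproduct_o2", "byproduct_nad",
                         "byproduct_nadp")

#' Write a screening report (byte-stable TSV)
#'
#' Numeric columns are rendered with a fixed 10-significant-digit format so
#' that reruns on identical inputs produce identical bytes.
#'
#' @param records frame from [screen_targets()].
#' @param path output path.
#' @export
write_report <- function(records, path) {
  out <- records
  for (cn in intersect(REPORT_NUMERIC_COLS, names(out))) {
    out[[cn]] <- ifelse(is.na(records[[cn]]), "NA",
                        sprintf("%.10g", records[[cn]]))
  }
  con <- file(path, open = "wb")  # fixed newline convention across platforms
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read back a screening report
#'
#' @param path report TSV path.
#' @return `data.frame` with numeric and logical columns restored.
#' @export
read_report <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  for (cn in intersect(REPORT_NUMERIC_COLS, names(rec))) {
    rec[[cn]] <- as.numeric(rec[[cn]])
  }
  for (cn in intersect(c("producible_max_target", "producible_max_biomass"),
                       names(rec))) {
    rec[[cn]] <- rec[[cn]] == "TRUE"
  }
  for (cn in intersect(c("connection_iteration", "n_heterologous_reactions"),
                       names(rec))) {
    rec[[cn]] <- as.integer(rec[[cn]])
  }
  rec
}

#' Per-host summary of a screening run
#'
#' @param records_by_host named list of record frames.
#' @param path output JSON path.
#' @return the summary list, invisibly.
#' @export
write_screen_summary <- function(records_by_host, path) {
  summ <- lapply(records_by_host, function(rec) list(
    n_connected = nrow(rec),
    n_producible_max_target = sum(rec$producible_max_target),
    frac_producible_max_target = if (nrow(rec)) mean(rec$producible_max_target)
                                 else NA,
    n_producible_max_biomass = sum(rec$producible_max_biomass),
    frac_producible_max_biomass = if (nrow(rec)) mean(rec$producible_max_biomass)
                                  else NA))
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
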