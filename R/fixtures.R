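# ---- self-contained fixtures ----------------------------------------------
#
# Every fixture materializes as files in the standard dialects (reaction
# table TSV, two-section host model TSV, mapping TSV, medium JSON) and is
# loaded back through the standard readers, so format coverage is exercised
# by construction.  The worked-example cases rebuild published micro-host /
# reaction-set pairs whose heterologous reaction counts are known; random
# instances ship an independently coded breadth-first oracle.

#' Built-in compound name-to-identifier table
#'
#' Maps the compound names used by the worked-example fixtures to KEGG
#' compound identifiers where these are well established (cofactors, central
#' metabolites, printed target ids).  Names without an entry are resolved to
#' deterministic synthetic identifiers in the reserved `X_` namespace by
#' [resolve_compound()].
#'
#' @return `data.frame` with columns `name`, `compound_id`.
#' @export
hp_compound_table <- function() {
  tab <- c(
    "NAD+" = "C00003", "NADH" = "C00004", "NADPH" = "C00005",
    "NADP+" = "C00006", "H2O" = "C00001", "H+" = "C00080",
    "oxygen" = "C00007", "O2" = "C00007", "CO2" = "C00011",
    "CoA" = "C00010", "ATP" = "C00002", "ADP" = "C00008", "AMP" = "C00020",
    "diphosphate" = "C00013", "orthophosphate" = "C00009",
    "FAD" = "C00016", "FADH2" = "C01352",
    "acetate" = "C00033", "pyruvate" = "C00022",
    "methylglyoxal" = "C00546", "glucose" = "C00031",
    "glycerol" = "C00116", "formate" = "C00058",
    "formaldehyde" = "C00067", "acetaldehyde" = "C00084",
    "glycerone phosphate" = "C00111",
    "succinyl-CoA" = "C00091", "acetyl-CoA" = "C00024",
    "3-dehydroshikimate" = "C02637",
    "3,4-dihydroxybenzoate" = "C00230",
    "vanillin" = "C00755", "4-hydroxy-3-methoxy-benzaldehyde" = "C00755",
    "propane-1,3-diol" = "C02457", "1,3-propanediol" = "C02457",
    "(R)-propane-1,2-diol" = "C02912",
    "(R)-lactate" = "C00256", "(R)-lactaldehyde" = "C00937",
    "3-oxopropanoate" = "C00222", "adipate" = "C06104")
  data.frame(name = names(tab), compound_id = unname(tab),
             stringsAsFactors = FALSE)
}

# ---- micro-host construction ----------------------------------------------

# shared glucose -> pyruvate -> biomass backbone with NAD(H) cycling and
# oxygen-limited respiration; case natives ride on top with 1:1 pyruvate
# supply lumps (mass-true chemistry is not the point of these micro-hosts)
micro_host_text <- function(case_mets, supplies, extra_reactions = character()) {
  mets <- rbind(
    data.frame(model_id = c("glc_e", "glc_c", "pyr_c", "nad_c", "nadh_c",
                            "o2_e", "o2_c", "co2_e", "co2_c", "h2o_e",
                            "h2o_c", "h_e", "h_c"),
               compartment = c("e", "c", "c", "c", "c", "e", "c", "e", "c",
                               "e", "c", "e", "c"),
               kegg_id = c("C00031", "C00031", "C00022", "C00003", "C00004",
                           "C00007", "C00007", "C00011", "C00011", "C00001",
                           "C00001", "C00080", "C00080"),
               stringsAsFactors = FALSE),
    case_mets)
  rxns <- c(
    "EX_glc\tglc_e <=>\t-10\t1000\t0\t1",
    "T_glc\tglc_e <=> glc_c\t-1000\t1000\t0\t0",
    "GLYC\tglc_c + 2 nad_c <=> 2 pyr_c + 2 nadh_c + 2 h_c\t0\t1000\t0\t0",
    "RESP\tnadh_c + h_c + 0.5 o2_c <=> nad_c + h2o_c\t0\t1000\t0\t0",
    "EX_o2\to2_e <=>\t-2\t1000\t0\t1",
    "T_o2\to2_e <=> o2_c\t-1000\t1000\t0\t0",
    "EX_co2\tco2_e <=>\t-1000\t1000\t0\t1",
    "T_co2\tco2_e <=> co2_c\t-1000\t1000\t0\t0",
    "EX_h2o\th2o_e <=>\t-1000\t1000\t0\t1",
    "T_h2o\th2o_e <=> h2o_c\t-1000\t1000\t0\t0",
    "EX_h\th_e <=>\t-1000\t1000\t0\t1",
    "T_h\th_e <=> h_c\t-1000\t1000\t0\t0",
    "BIOMASS\tpyr_c <=>\t0\t1000\t1\t0",
    vapply(supplies, function(mid)
      sprintf("SUP_%s\tpyr_c <=> %s\t-1000\t1000\t0\t0", mid, mid),
      character(1)),
    extra_reactions)
  c("## metabolites",
    "model_id\tcompartment\tname",
    sprintf("%s\t%s\t%s", mets$model_id, mets$compartment, mets$model_id),
    "## reactions",
    "id\tequation\tlb\tub\tis_biomass\tis_exchange",
    rxns) -> lines
  list(lines = lines, mapping = mets[, c("model_id", "kegg_id")])
}

case_met <- function(kegg_id, compartment = "c") {
  data.frame(model_id = paste0(tolower(kegg_id), "_", compartment),
             compartment = compartment, kegg_id = kegg_id,
             stringsAsFactors = FALSE)
}

# ---- worked-example cases -------------------------------------------------

table2_case_specs <- function() {
  ct <- hp_compound_table()
  cid <- function(name) resolve_compound(name, ct)
  list(
    pentanedione_ecoli = list(
      description = "pentane-2,4-dione in a host with native acetate and methylglyoxal",
      natives = c("acetate", "methylglyoxal"),
      target = "pentane-2,4-dione",
      reactions = data.frame(
        reaction_id = "RT2_PTD1",
        equation = "Pentane-2,4-dione + oxygen <=> acetate + methylglyoxal",
        ec = "1.13.11.50", stringsAsFactors = FALSE),
      n_reactions = 1L, iteration = 1L),
    pentanedione_cglut = list(
      description = "pentane-2,4-dione in a host with glycerone phosphate but no methylglyoxal",
      natives = c("glycerone phosphate", "acetate", "orthophosphate"),
      extra_free = "C00009",
      # phosphate is not a carbon source: it gets an exchange, not a
      # pyruvate supply lump
      no_supply = "C00009",
      extra_mets = case_met("C00009", "e"),
      host_extra = c(
        "EX_pi\tc00009_e <=>\t-1000\t1000\t0\t1",
        "T_pi\tc00009_e <=> c00009_c\t-1000\t1000\t0\t0"),
      target = "pentane-2,4-dione",
      reactions = data.frame(
        reaction_id = c("RT2_MGS", "RT2_PTD1"),
        equation = c("Glycerone phosphate <=> methylglyoxal + orthophosphate",
                     "Pentane-2,4-dione + oxygen <=> acetate + methylglyoxal"),
        ec = c("4.2.3.3", "1.13.11.50"), stringsAsFactors = FALSE),
      n_reactions = 2L, iteration = 2L),
    vanillin = list(
      description = "vanillin from 3-dehydroshikimate and formate",
      natives = c("3-dehydroshikimate", "formate"),
      target = "4-hydroxy-3-methoxy-benzaldehyde",
      reactions = data.frame(
        reaction_id = c("RT2_FDH", "RT2_DHSD", "RT2_VDM", "RT2_VOX"),
        equation = c(
          "Formaldehyde + NAD+ + H2O <=> formate + NADH + H+",
          "3-Dehydroshikimate <=> 3,4-dihydroxybenzoate + H2O",
          "Vanillate + oxygen + NADH + H+ <=> 3,4-dihydroxybenzoate + NAD+ + H2O + formaldehyde",
          "Vanillate + NAD+ + H2O <=> 4-hydroxy-3-methoxy-benzaldehyde + oxygen + NADH + H+"),
        ec = c("1.2.1.46", "4.2.1.118", "1.14.13.82", "1.2.3.9"),
        stringsAsFactors = FALSE),
      n_reactions = 4L, iteration = 3L),
    propanediol_R12 = list(
      description = "(R)-propane-1,2-diol from (R)-lactate",
      natives = c("(R)-lactate"),
      target = "(R)-propane-1,2-diol",
      reactions = data.frame(
        reaction_id = c("RT2_LDH", "RT2_PDH"),
        equation = c(
          "(R)-Lactaldehyde + NAD+ + H2O <=> (R)-lactate + NADH + H+",
          "(R)-Propane-1,2-diol + NAD+ <=> (R)-lactaldehyde + NADH + H+"),
        ec = c("1.2.1.23", "1.1.1.77"), stringsAsFactors = FALSE),
      n_reactions = 2L, iteration = 2L),
    propynal = list(
      description = "2-propyn-1-al from acetaldehyde and CO2",
      natives = c("acetaldehyde"),
      target = "2-propyn-1-al",
      reactions = data.frame(
        reaction_id = c("RT2_MSD", "RT2_MSH", "RT2_PAD"),
        equation = c(
          "3-Oxopropanoate <=> acetaldehyde + CO2",
          "3-Oxopropanoate <=> propynoate + H2O",
          "2-Propyn-1-al + NAD+ + H2O <=> propynoate + NADH + H+"),
        ec = c("4.1.1.-", "4.2.1.27", "1.2.1.3"), stringsAsFactors = FALSE),
      n_reactions = 3L, iteration = 3L),
    adipate_semialdehyde = list(
      description = "adipate semialdehyde from succinyl-CoA and acetyl-CoA",
      natives = c("succinyl-CoA", "acetyl-CoA", "CoA", "FAD", "FADH2",
                  "ATP", "AMP", "diphosphate", "NADP+", "NADPH"),
      host_extra = c(
        "THD\tc00005_c + nad_c <=> c00006_c + nadh_c\t-1000\t1000\t0\t0",
        "ATPC\tc00002_c + h2o_c <=> c00020_c + c00013_c\t-1000\t1000\t0\t0",
        "FADC\tc00016_c + nadh_c + h_c <=> c01352_c + nad_c\t-1000\t1000\t0\t0",
        "ACCOA\tpyr_c + c00010_c <=> c00024_c + co2_c\t-1000\t1000\t0\t0",
        "SUCCOA\tpyr_c + co2_c + c00010_c <=> c00091_c + h2o_c\t-1000\t1000\t0\t0"),
      no_supply = c("C00091", "C00024", "C00010", "C00016", "C01352",
                    "C00002", "C00020", "C00013", "C00006", "C00005"),
      target = "adipate semialdehyde",
      reactions = data.frame(
        reaction_id = sprintf("RT2_ADP%d", 1:6),
        equation = c(
          "Succinyl-CoA + acetyl-CoA <=> CoA + 3-oxoadipyl-CoA",
          "(3S)-3-Hydroxyadipyl-CoA + NAD+ <=> 3-oxoadipyl-CoA + NADH + H+",
          "5-Carboxy-2-pentenoyl-CoA + H2O <=> (3S)-3-hydroxyadipyl-CoA",
          "Adipyl-CoA + FAD <=> 5-carboxy-2-pentenoyl-CoA + FADH2",
          "Adipate + CoA + ATP <=> adipyl-CoA + AMP + diphosphate",
          "Adipate semialdehyde + NADP+ + H2O <=> adipate + NADPH + H+"),
        ec = c("2.3.1.174", "1.1.1.35", "4.2.1.17", "1.3.99.-", "6.2.1.-",
               "1.2.1.4"), stringsAsFactors = FALSE),
      n_reactions = 6L, iteration = 6L),
    pdo_13 = list(
      description = "1,3-propanediol from glycerol (dehydratase then oxidoreductase)",
      natives = c("glycerol"),
      target = "propane-1,3-diol",
      reactions = data.frame(
        reaction_id = c("RT2_DHAB", "RT2_DHAT"),
        equation = c(
          "Glycerol <=> 3-hydroxypropanal + H2O",
          "3-Hydroxypropanal + NADH + H+ <=> propane-1,3-diol + NAD+"),
        ec = c("4.2.1.30", "1.1.1.202"), stringsAsFactors = FALSE),
      n_reactions = 2L, iteration = 2L)
  )
}

#' Names of the built-in worked-example fixture cases
#'
#' @return character vector of case names accepted by [table2_fixture()].
#' @export
fixture_cases <- function() names(table2_case_specs())

decoy_reactions <- function() {
  data.frame(
    reaction_id = c("DEC_FAR1", "DEC_FAR2", "DEC_SHORTCUT"),
    equation = c("unreachable compound a <=> unreachable compound b",
                 "oxygen + unreachable compound c <=> unreachable compound d",
                 "pyruvate <=> pyruvate dimer decoy"),
    ec = c("", "", ""), stringsAsFactors = FALSE)
}

#' Build a worked-example fixture (micro-host plus printed reaction set)
#'
#' Each case pairs a minimal host — the native metabolites the published
#' pathway requires plus a shared glucose/NAD(H)/oxygen backbone with a
#' biomass sink — with a reaction database restricted to the printed
#' equations for that pathway.  The expected number of heterologous
#' reactions and the expected connection iteration are attached with
#' provenance tags.  All files are written to `dir` in the standard dialects
#' and loaded back through the standard readers.
#'
#' @param case_name one of [fixture_cases()].
#' @param dir directory to materialize files into (created; default a fresh
#'   temporary directory).
#' @param decoys also include decoy reactions that must not change the
#'   backtraced pathway (default `FALSE`).
#' @return list of class `hp_fixture`: `name`, `host`, `db`, `target`
#'   (compound id), `medium`, `expected` (with `provenance`), `paths`.
#' @export
table2_fixture <- function(case_name, dir = tempfile("hpfix"), decoys = FALSE) {
  specs <- table2_case_specs()
  if (!case_name %in% names(specs)) {
    stop(sprintf("unknown fixture case '%s'; see fixture_cases()", case_name))
  }
  spec <- specs[[case_name]]
  ct <- hp_compound_table()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  native_ids <- resolve_compound(spec$natives, ct)
  case_mets <- do.call(rbind, lapply(native_ids, case_met))
  if (!is.null(spec$extra_mets)) case_mets <- rbind(case_mets, spec$extra_mets)
  no_supply <- if (is.null(spec$no_supply)) character() else spec$no_supply
  supplies <- case_mets$model_id[!(case_mets$kegg_id %in% no_supply)]
  host_extra <- if (is.null(spec$host_extra)) character() else spec$host_extra
  hm <- micro_host_text(case_mets, supplies, host_extra)

  paths <- list(
    host = file.path(dir, "host.tsv"),
    mapping = file.path(dir, "mapping.tsv"),
    reactions = file.path(dir, "reactions.tsv"),
    compounds = file.path(dir, "compounds.tsv"),
    medium = file.path(dir, "medium.json"))
  writeLines(hm$lines, paths$host)
  utils::write.table(cbind(hm$mapping, manual_flag = "0"), paths$mapping,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rxns <- spec$reactions
  if (decoys) rxns <- rbind(rxns, decoy_reactions())
  utils::write.table(rxns, paths$reactions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct, paths$compounds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  free <- medium_spec()$free_exchanges
  if (!is.null(spec$extra_free)) free <- union(free, spec$extra_free)
  medium <- medium_spec(free_exchanges = free)
  write_medium(medium, paths$medium)

  host <- load_host_model(paths$host, paths$mapping)
  db <- load_reaction_table(paths$reactions, paths$compounds)
  structure(list(
    name = case_name,
    description = spec$description,
    host = host, db = db,
    target = resolve_compound(spec$target, ct),
    medium = read_medium(paths$medium),
    expected = list(n_reactions = spec$n_reactions,
                    iteration = spec$iteration,
                    provenance = "published worked example"),
    paths = paths), class = "hp_fixture")
}

#' @export
print.hp_fixture <- function(x, ...) {
  cat(sprintf("<hp_fixture %s> target %s, %d candidate reaction(s): %s\n",
              x$name, x$target, length(x$db$reactions), x$description))
  invisible(x)
}

# ---- random instances with an independent oracle ---------------------------

#' Independent breadth-first reachability oracle
#'
#' A deliberately naive re-derivation of the expansion semantics used to
#' cross-check [expand_network()]: plain set scans over (reaction,
#' direction) pairs, assigning each reachable nonnative compound the round
#' in which it first appears.  Coded without reference to the production
#' implementation.
#'
#' @param M0 native compound ids.
#' @param reactions list of `list(id, sub, prod)` with plain character
#'   compound vectors per direction (forward reads `sub -> prod`).
#' @param firing_rule `"all_substrates"` or `"any_substrate"`.
#' @return named integer vector: first round per reachable nonnative
#'   compound.
#' @export
bfs_oracle_layers <- function(M0, reactions,
                              firing_rule = c("all_substrates", "any_substrate")) {
  firing_rule <- match.arg(firing_rule)
  have <- unique(M0)
  layer <- integer()
  round <- 0L
  repeat {
    round <- round + 1L
    new_this_round <- character()
    for (k in seq_along(reactions)) {
      r <- reactions[[k]]
      for (d in 1:2) {
        from <- if (d == 1L) r$sub else r$prod
        to <- if (d == 1L) r$prod else r$sub
        ok <- if (firing_rule == "all_substrates") all(from %in% have)
              else any(from %in% have)
        fresh <- setdiff(to, have)
        if (ok && length(fresh) > 0L) {
          new_this_round <- union(new_this_round, fresh)
        }
      }
    }
    if (length(new_this_round) == 0L) break
    for (m in new_this_round) layer[[m]] <- round
    have <- union(have, new_this_round)
  }
  layer
}

#' Generate a seeded random expansion instance
#'
#' Draws a random hypergraph of reactions over a small compound universe,
#' writes it out in the standard reaction-table dialect, loads it back, and
#' attaches the independent oracle's layer assignment as expected values.
#'
#' @param n_compounds universe size (>= 2).
#' @param n_reactions number of reactions (>= 1).
#' @param seed RNG seed; instances are reproducible given
#'   `(n_compounds, n_reactions, seed)`.
#' @param dir directory for the materialized files.
#' @return list of class `hp_fixture`: `M0`, `db`, `reactions_raw` (the
#'   plain list fed to the oracle), `expected$oracle_layers` per firing
#'   rule, tagged as derived from the oracle.
#' @export
random_instance <- function(n_compounds, n_reactions, seed,
                            dir = tempfile("hprand")) {
  stopifnot(n_compounds >= 2, n_reactions >= 1)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- sprintf("Z%04d", seq_len(n_compounds))
  n0 <- max(2L, round(0.3 * n_compounds))
  M0 <- sort(sample(compounds, n0))
  rows <- vector("list", n_reactions)
  raw <- vector("list", n_reactions)
  for (k in seq_len(n_reactions)) {
    ns <- sample(seq_len(min(3L, n_compounds - 1L)), 1)
    np <- sample(seq_len(min(3L, n_compounds - ns)), 1)
    picks <- sample(compounds, ns + np)
    sub <- sort(picks[seq_len(ns)]); prod <- sort(picks[ns + seq_len(np)])
    coef_s <- sample(1:2, ns, replace = TRUE)
    coef_p <- sample(1:2, np, replace = TRUE)
    eq <- paste(paste(ifelse(coef_s == 1, sub, paste(coef_s, sub)),
                      collapse = " + "),
                "<=>",
                paste(ifelse(coef_p == 1, prod, paste(coef_p, prod)),
                      collapse = " + "))
    rows[[k]] <- data.frame(reaction_id = sprintf("RR%04d", k), equation = eq,
                            stringsAsFactors = FALSE)
    raw[[k]] <- list(id = sprintf("RR%04d", k), sub = sub, prod = prod)
  }
  tab <- do.call(rbind, rows)
  path <- file.path(dir, "reactions.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  db <- load_reaction_table(path)
  structure(list(
    name = sprintf("random_%d_%d_seed%d", n_compounds, n_reactions, seed),
    M0 = M0, db = db, reactions_raw = raw,
    expected = list(
      oracle_layers = list(
        all_substrates = bfs_oracle_layers(M0, raw, "all_substrates"),
        any_substrate = bfs_oracle_layers(M0, raw, "any_substrate")),
      provenance = "independent breadth-first oracle"),
    paths = list(reactions = path)), class = "hp_fixture")
}

# ---- analytic flux-balance toys -------------------------------------------

toy_host <- function(lines, mapping, dir, name) {
  hp <- file.path(dir, paste0(name, "_host.tsv"))
  mp <- file.path(dir, paste0(name, "_mapping.tsv"))
  writeLines(lines, hp)
  utils::write.table(mapping, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_host_model(hp, mp)
}

#' An empty heterologous pathway (native target)
#'
#' @param target compound id.
#' @return an `hp_pathway` with zero reactions.
#' @export
empty_pathway <- function(target) {
  structure(list(target = target,
                 reactions = data.frame(reaction_id = character(),
                                        direction = character(),
                                        iteration = integer(),
                                        stringsAsFactors = FALSE),
                 n_reactions = 0L, connection_iteration = 0L),
            class = "hp_pathway")
}

#' Analytic flux-balance toy models with closed-form optima
#'
#' Four hand-solvable cases: a linear uptake-limited chain (maximum demand
#' equals the uptake bound, 100 percent molar yield), a 2:1 stoichiometric
#' branch (half the uptake, 50 percent), a strict biomass-competition toy
#' (target flux zero at the growth optimum), and an oxygen-limited
#' NADH-reoxidation toy in which target production regenerates NAD+ and so
#' survives biomass maximization (target flux strictly positive).
#'
#' @param dir directory for the materialized files.
#' @return named list of cases, each `list(name, host, medium, target,
#'   expected)` with closed-form expected values.
#' @export
analytic_fba_toys <- function(dir = tempfile("hptoy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  med <- medium_spec(carbon_source = "K0001", carbon_uptake_max = 10,
                     oxygen_uptake_max = 2, free_exchanges = character())

  map2 <- function(ids, kegg) data.frame(model_id = ids, kegg_id = kegg,
                                         manual_flag = "0",
                                         stringsAsFactors = FALSE)
  chain <- toy_host(c(
    "## metabolites", "model_id\tcompartment",
    "A_e\te", "A_c\tc", "B_c\tc",
    "## reactions", "id\tequation\tlb\tub\tis_biomass\tis_exchange",
    "EX_A\tA_e <=>\t-10\t1000\t0\t1",
    "T_A\tA_e <=> A_c\t-1000\t1000\t0\t0",
    "CONV\tA_c <=> B_c\t-1000\t1000\t0\t0",
    "BIOMASS\tB_c <=>\t0\t1000\t1\t0"),
    map2(c("A_e", "A_c", "B_c"), c("K0001", "K0001", "K0002")), dir, "chain")

  branch <- toy_host(c(
    "## metabolites", "model_id\tcompartment",
    "A_e\te", "A_c\tc", "B_c\tc",
    "## reactions", "id\tequation\tlb\tub\tis_biomass\tis_exchange",
    "EX_A\tA_e <=>\t-10\t1000\t0\t1",
    "T_A\tA_e <=> A_c\t-1000\t1000\t0\t0",
    "CONV2\t2 A_c <=> B_c\t-1000\t1000\t0\t0",
    "BIOMASS\tB_c <=>\t0\t1000\t1\t0"),
    map2(c("A_e", "A_c", "B_c"), c("K0001", "K0001", "K0002")), dir, "branch")

  competition <- toy_host(c(
    "## metabolites", "model_id\tcompartment",
    "A_e\te", "A_c\tc", "P_c\tc", "T_c\tc",
    "## reactions", "id\tequation\tlb\tub\tis_biomass\tis_exchange",
    "EX_A\tA_e <=>\t-10\t1000\t0\t1",
    "T_A\tA_e <=> A_c\t-1000\t1000\t0\t0",
    "V1\tA_c <=> P_c\t0\t1000\t0\t0",
    "VT\tP_c <=> T_c\t0\t1000\t0\t0",
    "BIOMASS\tP_c <=>\t0\t1000\t1\t0"),
    map2(c("A_e", "A_c", "P_c", "T_c"),
         c("K0001", "K0001", "K0003", "K0004")), dir, "competition")

  nadh <- toy_host(c(
    "## metabolites", "model_id\tcompartment",
    "A_e\te", "A_c\tc", "P_c\tc", "T_c\tc", "nad_c\tc", "nadh_c\tc",
    "o2_e\te", "o2_c\tc",
    "## reactions", "id\tequation\tlb\tub\tis_biomass\tis_exchange",
    "EX_A\tA_e <=>\t-10\t1000\t0\t1",
    "T_A\tA_e <=> A_c\t-1000\t1000\t0\t0",
    "EX_O2\to2_e <=>\t-2\t1000\t0\t1",
    "T_O2\to2_e <=> o2_c\t-1000\t1000\t0\t0",
    "V1\tA_c + nad_c <=> P_c + nadh_c\t0\t1000\t0\t0",
    "RESP\tnadh_c + 0.5 o2_c <=> nad_c\t0\t1000\t0\t0",
    "VT\tP_c + nadh_c <=> T_c + nad_c\t0\t1000\t0\t0",
    "BIOMASS\tP_c <=>\t0\t1000\t1\t0"),
    map2(c("A_e", "A_c", "P_c", "T_c", "nad_c", "nadh_c", "o2_e", "o2_c"),
         c("K0001", "K0001", "K0003", "K0004", "C00003", "C00004",
           "C00007", "C00007")), dir, "nadh")

  list(
    chain = list(name = "chain", host = chain, medium = med, target = "K0002",
                 expected = list(max_demand = 10, yield_percent = 100,
                                 provenance = "closed form")),
    branch = list(name = "branch", host = branch, medium = med,
                  target = "K0002",
                  expected = list(max_demand = 5, yield_percent = 50,
                                  provenance = "closed form")),
    competition = list(name = "competition", host = competition,
                       medium = med, target = "K0004",
                       expected = list(biomass_opt = 10, target_at_opt = 0,
                                       provenance = "closed form")),
    nadh = list(name = "nadh", host = nadh, medium = med, target = "K0004",
                expected = list(biomass_opt = 4, target_at_opt = 6,
                                provenance = "closed form"))
  )
}

#' Write a manifest of the built-in fixtures
#'
#' @param path output JSON path.
#' @export
write_fixture_manifest <- function(path) {
  specs <- table2_case_specs()
  out <- lapply(names(specs), function(nm) list(
    case = nm,
    description = specs[[nm]]$description,
    target = specs[[nm]]$target,
    n_candidate_reactions = nrow(specs[[nm]]$reactions),
    expected_n_reactions = specs[[nm]]$n_reactions,
    expected_iteration = specs[[nm]]$iteration,
    provenance = "published worked example"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
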