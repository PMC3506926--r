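screen_case <- function(cs, ...) {
  fx <- table2_fixture(cs)
  list(fx = fx,
       rec = screen_targets(fx$host, fx$db, fx$medium, ...))
}

test_that("screening returns one record per connected compound with printed counts", {
  counts <- c(pentanedione_ecoli = 1L, pentanedione_cglut = 2L,
              vanillin = 4L, propanediol_R12 = 2L, propynal = 3L,
              adipate_semialdehyde = 6L)
  for (cs in names(counts)) {
    s <- screen_case(cs)
    row <- s$rec[s$rec$target == s$fx$target, ]
    expect_equal(nrow(row), 1L, label = cs)
    expect_identical(row$n_heterologous_reactions, counts[[cs]], label = cs)
    expect_gte(row$connection_iteration, 1L)
  }
  # records are ordered deterministically by compound id
  s <- screen_case("adipate_semialdehyde")
  expect_identical(s$rec$target, sort(s$rec$target))
})

test_that("screening an empty database yields an empty record set", {
  fx <- table2_fixture("pentanedione_ecoli")
  p <- tempfile(fileext = ".tsv")
  writeLines("reaction_id\tequation", p)
  empty_db <- load_reaction_table(p)
  rec <- screen_targets(fx$host, empty_db, fx$medium)
  expect_equal(nrow(rec), 0L)
})

test_that("the pathway-size cap filters exactly by reaction count", {
  s <- screen_case("adipate_semialdehyde")
  for (k in c(1L, 3L, 10L)) {
    capped <- screen_targets(s$fx$host, s$fx$db, s$fx$medium,
                             max_reactions = k)
    manual <- s$rec[s$rec$n_heterologous_reactions <= k, ]
    rownames(manual) <- NULL
    expect_identical(capped, manual, label = sprintf("cap %d", k))
  }
})

test_that("growth-coupled producibility implies plain producibility", {
  for (cs in fixture_cases()) {
    s <- screen_case(cs)
    expect_true(all(!s$rec$producible_max_biomass |
                      s$rec$producible_max_target), label = cs)
    expect_true(all(s$rec$n_heterologous_reactions >= 1L), label = cs)
  }
})

test_that("worked-example targets are growth-coupled with the printed by-products", {
  # oxygen-evolving mechanism
  s <- screen_case("pentanedione_ecoli")
  row <- s$rec[s$rec$target == s$fx$target, ]
  expect_true(row$producible_max_biomass)
  expect_gt(row$byproduct_o2, 0)
  # NAD+-regenerating mechanism
  s2 <- screen_case("pdo_13")
  row2 <- s2$rec[s2$rec$target == s2$fx$target, ]
  expect_true(row2$producible_max_biomass)
  expect_gt(row2$byproduct_nad, 0)
})

fake_records <- function(produced, not_produced, prefix) {
  data.frame(
    target = sprintf("%s%03d", prefix, seq_len(produced + not_produced)),
    producible_max_biomass = rep(c(TRUE, FALSE), c(produced, not_produced)),
    stringsAsFactors = FALSE)
}

test_that("chi-square enrichment matches the textbook formula", {
  # perfectly separated 2x2 table: statistic 20, significant at P < 0.001
  recs <- list(hostA = fake_records(10, 0, "CA"),
               hostB = fake_records(0, 10, "CB"))
  cmap <- data.frame(
    compound_id = c(recs$hostA$target, recs$hostB$target),
    category = "cat1", stringsAsFactors = FALSE)
  enr <- category_enrichment(recs, cmap)
  expect_equal(nrow(enr), 1L)
  expect_equal(enr$statistic, 20, tolerance = 1e-12)
  expect_lt(enr$p_value, 0.001)
  expect_true(enr$significant)

  # identical producible fractions: statistic 0, not significant
  recs2 <- list(hostA = fake_records(5, 5, "DA"),
                hostB = fake_records(5, 5, "DB"))
  cmap2 <- data.frame(
    compound_id = c(recs2$hostA$target, recs2$hostB$target),
    category = "cat1", stringsAsFactors = FALSE)
  enr2 <- category_enrichment(recs2, cmap2)
  expect_equal(enr2$statistic, 0, tolerance = 1e-12)
  expect_false(enr2$significant)
})

test_that("the statistic equals the direct-loop oracle on random tables", {
  set.seed(37)
  for (i in 1:25) {
    nh <- sample(2:3, 1)
    tab <- matrix(sample(1:30, nh * 2, replace = TRUE), nh, 2)
    recs <- list(); cmap_rows <- list()
    for (h in seq_len(nh)) {
      nmh <- sprintf("host%d", h)
      recs[[nmh]] <- fake_records(tab[h, 1], tab[h, 2], sprintf("T%d_", h))
      cmap_rows[[h]] <- data.frame(compound_id = recs[[nmh]]$target,
                                   category = "c", stringsAsFactors = FALSE)
    }
    enr <- category_enrichment(recs, do.call(rbind, cmap_rows))
    expect_equal(enr$statistic, chisq_loop_oracle(tab), tolerance = 1e-10)
    expect_gte(enr$p_value, 0)
    expect_lte(enr$p_value, 1)
    # independent cross-check against the stock implementation
    suppressWarnings(
      expect_equal(enr$statistic,
                   unname(stats::chisq.test(tab, correct = FALSE)$statistic),
                   tolerance = 1e-10))
    # row permutation invariance
    perm <- sample(nh)
    enr_p <- category_enrichment(recs[perm], do.call(rbind, cmap_rows))
    expect_equal(enr_p$statistic, enr$statistic, tolerance = 1e-10)
  }
})

test_that("degenerate categories are excluded and logged", {
  recs <- list(hostA = fake_records(3, 0, "EA"),
               hostB = fake_records(2, 0, "EB"))
  cmap <- data.frame(
    compound_id = c(recs$hostA$target, recs$hostB$target),
    category = "allproduced", stringsAsFactors = FALSE)
  enr <- category_enrichment(recs, cmap)
  expect_equal(nrow(enr), 0L)
  expect_identical(attr(enr, "excluded"), "allproduced")
})

test_that("one-vs-rest mode emits a labelled 2x2 per host", {
  recs <- list(hostA = fake_records(8, 2, "FA"),
               hostB = fake_records(2, 8, "FB"),
               hostC = fake_records(5, 5, "FC"))
  cmap <- data.frame(
    compound_id = unlist(lapply(recs, `[[`, "target")),
    category = "cat1", stringsAsFactors = FALSE)
  enr <- category_enrichment(recs, cmap, mode = "one_vs_rest")
  expect_equal(nrow(enr), 3L)
  expect_setequal(enr$category, paste("cat1", names(recs), sep = "|"))
  expect_true(all(enr$df == 1L))
})

test_that("screening reports are byte-stable and round-trip", {
  s <- screen_case("adipate_semialdehyde")
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_report(s$rec, p1)
  # header + one data row per record
  expect_length(readLines(p1), nrow(s$rec) + 1L)
  # rerunning the whole screen reproduces identical bytes
  rec2 <- screen_targets(s$fx$host, s$fx$db, s$fx$medium)
  write_report(rec2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # numeric fields survive the round trip
  back <- read_report(p1)
  for (cn in c("yield_max_target", "yield_max_biomass", "biomass_opt")) {
    expect_equal(back[[cn]], s$rec[[cn]], tolerance = 1e-8, label = cn)
  }
  expect_identical(back$producible_max_biomass, s$rec$producible_max_biomass)
  expect_identical(back$n_heterologous_reactions,
                   s$rec$n_heterologous_reactions)
})

test_that("the screening summary counts producible targets per host", {
  s <- screen_case("pentanedione_ecoli")
  p <- tempfile(fileext = ".json")
  summ <- write_screen_summary(list(ecoli_like = s$rec), p)
  expect_equal(summ$ecoli_like$n_connected, nrow(s$rec))
  expect_equal(summ$ecoli_like$n_producible_max_biomass,
               sum(s$rec$producible_max_biomass))
  expect_true(file.exists(p))
})
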