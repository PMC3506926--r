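test_that("equation parsing handles the KEGG dialect and printed names", {
  eq <- parse_equation("C00022 + C00004 <=> C00186 + C00003")
  expect_equal(eq$substrates$compound, c("C00022", "C00004"))
  expect_equal(eq$products$compound, c("C00186", "C00003"))
  expect_equal(eq$substrates$coef, c(1, 1))
  expect_equal(eq$products$coef, c(1, 1))

  ct <- hp_compound_table()
  eq2 <- parse_equation("Succinyl-CoA + acetyl-CoA ↔ CoA + 3-oxoadipyl-CoA", ct)
  expect_equal(nrow(eq2$substrates), 2L)
  expect_equal(nrow(eq2$products), 2L)
  expect_true(all(c(eq2$substrates$coef, eq2$products$coef) == 1))
  expect_equal(eq2$substrates$compound, c("C00091", "C00024"))
  # unresolved names fall into the reserved synthetic namespace
  expect_match(eq2$products$compound[[2]], "^X_")

  # "=" separator and multi-token names with spaces
  eq3 <- parse_equation("adipate semialdehyde + 2 C00001 = C00033")
  expect_equal(eq3$substrates$coef, c(1, 2))
  expect_match(eq3$substrates$compound[[1]], "^X_adipate_semialdehyde$")
})

test_that("parse errors are classed and informative", {
  expect_error(parse_equation("C00001 + C00002"), class = "hetpath_parse_error")
  expect_error(parse_equation("n C00001 <=> C00002"),
               class = "hetpath_symbolic_coef")
  expect_error(parse_equation("(n+1) C00001 <=> C00002"),
               class = "hetpath_symbolic_coef")
  expect_error(parse_equation("C00001 <=> "), class = "hetpath_parse_error")
})

test_that("parse/serialize round trip is a fixed point on random equations", {
  set.seed(421)
  for (i in 1:100) {
    txt <- random_equation()
    p1 <- parse_equation(txt)
    expect_identical(serialize_equation(p1), txt)
    p2 <- parse_equation(serialize_equation(p1))
    expect_identical(p2, p1)
  }
})

test_that("reaction signatures are invariant to term order and side swap", {
  mk <- function(txt) {
    eq <- parse_equation(txt)
    hp_reaction("r", eq$substrates, eq$products)
  }
  expect_identical(reaction_signature(mk("A1 + B1 <=> D1")),
                   reaction_signature(mk("D1 <=> B1 + A1")))
  expect_false(identical(reaction_signature(mk("A1 + B1 <=> D1")),
                         reaction_signature(mk("A1 + 2 B1 <=> D1"))))
  expect_false(identical(reaction_signature(mk("A1 + B1 <=> D1")),
                         reaction_signature(mk("A1 + B1 <=> E1"))))
})

test_that("signature equality matches the brute-force multiset oracle", {
  set.seed(77)
  rxns <- lapply(1:50, function(i) {
    eq <- parse_equation(random_equation())
    hp_reaction(sprintf("r%02d", i), eq$substrates, eq$products)
  })
  sigs <- vapply(rxns, reaction_signature, character(1))
  msets <- vapply(rxns, signature_multiset, character(1))
  for (i in 1:49) {
    for (j in (i + 1):50) {
      expect_identical(sigs[[i]] == sigs[[j]], msets[[i]] == msets[[j]])
    }
  }
  # permuted / swapped variants collide with the original
  for (r in rxns[1:10]) {
    swapped <- hp_reaction("s", r$products[sample(nrow(r$products)), ],
                           r$substrates[sample(nrow(r$substrates)), ])
    expect_identical(reaction_signature(swapped), reaction_signature(r))
  }
})

test_that("reaction tables load with a complete skip report", {
  fx <- table2_fixture("adipate_semialdehyde")
  expect_s3_class(fx$db, "hp_reaction_db")
  expect_length(fx$db$reactions, 6L)

  # empty table
  p <- tempfile(fileext = ".tsv")
  writeLines("reaction_id\tequation", p)
  empty <- load_reaction_table(p)
  expect_length(empty$reactions, 0L)
  expect_equal(nrow(empty$skip), 0L)

  # symbolic coefficient -> skip report, not an error
  db <- mini_db("n C00001 <=> C00002")
  expect_length(db$reactions, 0L)
  expect_equal(nrow(db$skip), 1L)
  expect_match(db$skip$reason, "symbolic")

  # row count == usable + skipped
  db2 <- mini_db(c("C00001 <=> C00002", "n C00003 <=> C00004",
                   "C00005 + C00006 <=> C00007", "no separator here"))
  expect_equal(length(db2$reactions) + nrow(db2$skip), 4L)

  # duplicate ids and missing columns are hard errors
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "r1\tA1 <=> B1", "r1\tA1 <=> D1"), p2)
  expect_error(load_reaction_table(p2), "duplicate")
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tec", "r1\t1.1.1.1"), p3)
  expect_error(load_reaction_table(p3), "missing required column")
})

test_that("signature duplicates collapse to one annotated representative", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    reaction_id = c("r1", "r2", "r3"),
    equation = c("A1 + B1 <=> D1", "D1 <=> B1 + A1", "A1 <=> E1"),
    ec = c("1.1.1.1", "2.2.2.2", ""),
    stringsAsFactors = FALSE), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  db <- load_reaction_table(path)
  expect_length(db$reactions, 2L)
  expect_equal(db$duplicates$kept, "r1")
  expect_equal(db$duplicates$dropped, "r2")
  expect_setequal(db$reactions[["r1"]]$ec, c("1.1.1.1", "2.2.2.2"))
})

test_that("minimum-Km annotation picks the smallest Km with wildcard ECs", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    reaction_id = c("r1", "r2", "r3"),
    equation = c("A1 <=> B1", "D1 <=> E1", "F1 <=> G1"),
    ec = c("1.1.1.77", "1.3.99.-", ""),
    stringsAsFactors = FALSE), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  db0 <- load_reaction_table(path)  # pristine, never annotated
  db <- db0
  km <- data.frame(ec = c("1.1.1.77", "1.1.1.77", "1.3.99.7"),
                   organism = c("OrgA", "OrgB", "OrgC"),
                   km_mM = c(0.5, 0.2, 1.0), stringsAsFactors = FALSE)
  db <- attach_km(db, km)
  expect_equal(db$reactions[["r1"]]$km$km_value, 0.2)
  expect_equal(db$reactions[["r1"]]$km$organism, "OrgB")
  expect_equal(db$reactions[["r2"]]$km$organism, "OrgC")  # wildcard match
  expect_null(db$reactions[["r3"]]$km)

  # property: annotation always equals the linear-scan minimum
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    tabk <- data.frame(
      ec = sample(c("1.1.1.77", "1.1.1.78", "1.3.99.7"), n, replace = TRUE),
      organism = sample(LETTERS, n),
      km_mM = round(stats::runif(n, 0.01, 5), 3), stringsAsFactors = FALSE)
    db2 <- attach_km(db0, tabk)
    hits <- tabk[tabk$ec == "1.1.1.77", , drop = FALSE]
    if (nrow(hits)) {
      hits <- hits[order(hits$km_mM, hits$organism), ]
      expect_equal(db2$reactions[["r1"]]$km$km_value, hits$km_mM[[1]])
      expect_equal(db2$reactions[["r1"]]$km$organism, hits$organism[[1]])
    } else {
      expect_null(db2$reactions[["r1"]]$km)
    }
  }
})
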