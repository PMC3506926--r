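# independent oracles used across the suite; deliberately naive code paths
# that never call the implementation they check

# exact LP optimum by vertex enumeration: max obj'x s.t. A x = 0,
# lb <= x <= ub.  Only for small column counts (<= 6 or so).
vertex_enum_lp <- function(obj, A, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  subsets <- if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  best <- NA_real_
  for (F in subsets) {
    B <- setdiff(seq_len(n), F)
    grid <- if (length(F)) expand.grid(rep(list(1:2), length(F))) else
      data.frame(row.names = "v")
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      for (j in seq_along(F)) {
        x[F[[j]]] <- if (grid[g, j] == 1) lb[[F[[j]]]] else ub[[F[[j]]]]
      }
      if (length(B)) {
        AB <- A[, B, drop = FALSE]
        qrAB <- qr(AB)
        if (qrAB$rank < length(B)) next
        rhs <- -if (length(F)) A[, F, drop = FALSE] %*% x[F] else
          matrix(0, nrow(A), 1)
        xB <- tryCatch(qr.coef(qrAB, rhs), error = function(e) NULL)
        if (is.null(xB) || anyNA(xB)) next
        x[B] <- xB
      }
      if (max(abs(A %*% x)) > 1e-7) next
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      val <- sum(obj * x)
      if (is.na(best) || (maximize && val > best) || (!maximize && val < best))
        best <- val
    }
  }
  best
}

# random feasible box LP (x = 0 always feasible since b = 0 and lb <= 0 <= ub)
random_box_lp <- function(n_rows, n_cols) {
  A <- matrix(sample(-2:2, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
  lb <- -sample(0:3, n_cols, replace = TRUE)
  ub <- sample(0:3, n_cols, replace = TRUE)
  obj <- sample(-3:3, n_cols, replace = TRUE)
  list(obj = obj, A = A, lb = lb, ub = ub)
}

# random reaction equation over KEGG-style ids, in the canonical serialized
# dialect (so serialize(parse(t)) == t)
random_equation <- function(max_terms = 3) {
  ids <- sprintf("C%05d", sample(1:99999, 2 * max_terms))
  ns <- sample(1:max_terms, 1); np <- sample(1:max_terms, 1)
  term <- function(id) {
    coef <- sample(c(1, 1, 2, 3, 0.5), 1)
    if (coef == 1) id else paste(format(coef, trim = TRUE, digits = 12), id)
  }
  paste(paste(vapply(ids[seq_len(ns)], term, character(1)), collapse = " + "),
        "<=>",
        paste(vapply(ids[max_terms + seq_len(np)], term, character(1)),
              collapse = " + "))
}

# direct-loop chi-square oracle
chisq_loop_oracle <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# brute-force signature oracle: side-normalized sorted multiset of
# (compound, coefficient)
signature_multiset <- function(r) {
  net <- stats::setNames(c(-r$substrates$coef, r$products$coef),
                         c(r$substrates$compound, r$products$compound))
  net <- net[order(names(net))]
  if (net[[1]] < 0) net <- -net
  paste(names(net), signif(net, 10), sep = "=", collapse = ",")
}

# write a small reaction table and load it
mini_db <- function(equations, ids = sprintf("RX%02d", seq_along(equations)),
                    compound_table = NULL, ...) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(reaction_id = ids, equation = equations,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_reaction_table(path, compound_table = compound_table, ...)
}

# expansion run for a fixture case
run_case <- function(fx, rule = "all_substrates") {
  ns <- native_sets(fx$host)
  ex <- expand_network(ns$M0, ns$R0, fx$db, rule)
  list(ns = ns, ex = ex, pw = backtrace(ex, fx$target))
}

# layer map (compound -> iteration) from an expansion result
layer_map <- function(ex) {
  stats::setNames(as.integer(ex$producer_map$iteration),
                  ex$producer_map$compound)
}

same_layers <- function(got, expected) {
  length(got) == length(expected) &&
    setequal(names(got), names(expected)) &&
    (length(expected) == 0L || all(got[names(expected)] == expected))
}
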