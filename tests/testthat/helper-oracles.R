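# Independent oracles and small builders used across the suite. The
# oracles recompute quantities from first principles (direct sums over
# bond records) so they stay independent of the package's own code paths.

# valence weight per order, written out independently of bond_order_value
oracle_order_weight <- function(order) {
  switch(order,
         "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, "un" = 1,
         stop("oracle: unknown order ", order))
}

# brute-force per-atom valence sums straight off the bond table
oracle_valence_sums <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    w <- oracle_order_weight(mol$bonds$order[k])
    s[mol$bonds$a[k]] <- s[mol$bonds$a[k]] + w
    s[mol$bonds$b[k]] <- s[mol$bonds$b[k]] + w
  }
  s
}

# brute-force feasibility: bond absent and both endpoints stay within max
oracle_feasible <- function(mol, i, j, order, maxv) {
  if (i == j) return(FALSE)
  exists <- any((mol$bonds$a == i & mol$bonds$b == j) |
                  (mol$bonds$a == j & mol$bonds$b == i))
  if (exists) return(FALSE)
  s <- oracle_valence_sums(mol)
  w <- oracle_order_weight(order)
  all(s[c(i, j)] + w <= maxv[mol$atoms$element[c(i, j)]] + 1e-9)
}

# quick builder for a molecule out of element symbols and bond triples
mk_mol <- function(elements, bonds = NULL, name = "test") {
  syb <- ifelse(elements == "C", "C.3",
                ifelse(elements == "O", "O.3",
                       ifelse(elements == "N", "N.3", elements)))
  atoms <- data.frame(
    index = seq_along(elements),
    name = paste0(elements, seq_along(elements)),
    x = seq_along(elements) * 1.5, y = 0, z = 0,
    sybyl_type = syb, stringsAsFactors = FALSE)
  bdf <- NULL
  if (!is.null(bonds)) {
    bdf <- data.frame(bond_id = seq_len(nrow(bonds)),
                      a = bonds[, 1], b = bonds[, 2],
                      order = as.character(bonds[, 3]),
                      stringsAsFactors = FALSE)
  }
  molecule(name, atoms, bdf)
}

expect_same_graph <- function(m1, m2) {
  expect_equal(m1$atoms$name, m2$atoms$name)
  expect_equal(m1$atoms$element, m2$atoms$element)
  expect_equal(m1$atoms$sybyl_type, m2$atoms$sybyl_type)
  # writers print 9 decimals; 1e-6 Angstrom is far below any printed digit
  expect_equal(m1$atoms$x, m2$atoms$x, tolerance = 1e-6)
  expect_equal(m1$atoms$y, m2$atoms$y, tolerance = 1e-6)
  expect_equal(m1$atoms$z, m2$atoms$z, tolerance = 1e-6)
  expect_equal(m1$bonds$a, m2$bonds$a)
  expect_equal(m1$bonds$b, m2$bonds$b)
  expect_equal(m1$bonds$order, m2$bonds$order)
}

ethane_doc <- function() make_fixture("ethane_paper")
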