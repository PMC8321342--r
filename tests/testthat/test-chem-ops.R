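test_that("bond feasibility matches the valence budget on published ethane", {
  mol <- ethane_doc()$molecule
  # H3 (atom 5) and H4 (atom 6) are both saturated: red
  f <- bond_feasible(mol, 5, 6)
  expect_false(f$feasible)
  expect_match(f$reason, "valence")
  # upgrading C1-C2 to a double bond would put both carbons at 5: red
  f2 <- bond_feasible(mol, 1, 2, order = "2")
  expect_false(f2$feasible)
  expect_match(f2$reason, "already exists")
  expect_error(bond_feasible(mol, 1, 99), "no such atom")
  # two isolated carbons: green
  two <- mk_mol(c("C", "C"))
  expect_true(bond_feasible(two, 1, 2)$feasible)
})

test_that("bond feasibility is symmetric in its endpoints", {
  mols <- list(ethane_doc()$molecule,
               make_fixture("water")$molecule,
               make_fixture("random_alkane", n = 4, seed = 2)$molecule)
  for (mol in mols) {
    n <- n_atoms(mol)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        expect_equal(bond_feasible(mol, i, j)$feasible,
                     bond_feasible(mol, j, i)$feasible)
      }
    }
  }
})

test_that("feasibility and balancing agree with the brute-force valence oracle", {
  vm <- valence_model()
  maxv <- vm$max_valence
  # all fixture molecules with <= 6 heavy atoms
  mols <- c(list(ethane_doc()$molecule, make_fixture("methane")$molecule,
                 make_fixture("water")$molecule),
            lapply(1:6, function(s) make_fixture("random_alkane", n = s,
                                                 seed = s)$molecule))
  for (mol in mols) {
    n <- n_atoms(mol)
    for (i in seq_len(min(n, 8))) {
      for (j in seq_len(min(n, 8))) {
        if (i == j) next
        for (ord in c("1", "2")) {
          expect_equal(bond_feasible(mol, i, j, ord, vm)$feasible,
                       oracle_feasible(mol, i, j, ord, maxv),
                       info = sprintf("%s i=%d j=%d ord=%s",
                                      mol$name, i, j, ord))
        }
      }
    }
    # after balancing, every heavy atom sits exactly at its max valence
    bal <- balance_hydrogens(mol, vm)
    s <- oracle_valence_sums(bal)
    heavy <- bal$atoms$element != "H"
    expect_equal(s[heavy], unname(maxv[bal$atoms$element[heavy]]))
    expect_equal(nrow(validate_molecule(bal, vm)), 0)
  }
})

test_that("set_bond_order revalidates and refuses valence violations", {
  # ethene-like skeleton: C2H4 with a single C-C bond to upgrade
  eth <- mk_mol(c("C", "C", "H", "H", "H", "H"),
                rbind(c(1, 2, "1"), c(1, 3, "1"), c(1, 4, "1"),
                      c(2, 5, "1"), c(2, 6, "1")))
  up <- set_bond_order(eth, 1, 2, "2")
  expect_equal(up$bonds$order[1], "2")
  expect_equal(nrow(validate_molecule(up)), 0)
  # saturated ethane refuses the same upgrade, naming the valence problem
  mol <- ethane_doc()$molecule
  expect_error(set_bond_order(mol, 1, 2, "2"), "valence")
  expect_error(set_bond_order(mol, 3, 4, "1"), "no such bond")
  # identity rewrite leaves the molecule unchanged
  expect_identical(set_bond_order(eth, 1, 2, "1"), eth)
})

test_that("hydrogen balancing builds methane from bare carbon and is idempotent", {
  bare <- mk_mol("C", name = "bare")
  m <- balance_hydrogens(bare)
  expect_equal(molecular_formula(m), "CH4")
  expect_equal(n_bonds(m), 4)
  expect_true(all(m$bonds$a == 1))
  expect_equal(m$atoms$name[2:5], paste0("H", 1:4))
  # new H sit at the C-H table distance from the carbon
  for (i in 2:5) {
    expect_equal(sqrt(sum((as.numeric(m$atoms[i, c("x", "y", "z")]) -
                             as.numeric(m$atoms[1, c("x", "y", "z")]))^2)),
                 1.09, tolerance = 1e-9)
  }
  expect_equal(balance_hydrogens(m), m)
  # same seed, same placement; the operation is deterministic
  expect_equal(balance_hydrogens(bare, seed = 7),
               balance_hydrogens(bare, seed = 7))
  # saturated molecules come back unchanged
  eth <- ethane_doc()$molecule
  expect_equal(balance_hydrogens(eth), eth)
  h2 <- mk_mol(c("H", "H"), cbind(1, 2, "1"))
  expect_equal(balance_hydrogens(h2), h2)
})

test_that("balancing removes excess hydrogens, highest index first", {
  over <- mk_mol(c("C", rep("H", 5)), cbind(1, 2:6, "1"))
  bal <- balance_hydrogens(over)
  expect_equal(molecular_formula(bal), "CH4")
  # the surviving hydrogens are the four lowest-index originals
  # (helper names atoms by global position: H2..H6, so H6 goes)
  expect_equal(bal$atoms$name, c("C1", paste0("H", 2:5)))
  # an over-valent atom with no hydrogens to shed is an error naming it
  no_h <- mk_mol(c("O", "C", "C", "C"),
                 rbind(c(1, 2, "1"), c(1, 3, "1"), c(1, 4, "1")))
  expect_error(balance_hydrogens(no_h), "O1")
})

test_that("minimizer leaves an already-relaxed diatomic untouched", {
  two <- molecule("cc", data.frame(
    index = 1:2, name = c("C1", "C2"), x = c(0, 1.54), y = 0, z = 0,
    sybyl_type = "C.3"),
    data.frame(bond_id = 1L, a = 1L, b = 2L, order = "1"))
  res <- minimize_bonds(two)
  expect_equal(res$trace[1], 0)
  expect_true(res$converged)
  expect_equal(res$molecule$atoms$x, c(0, 1.54))
})

test_that("diatomic at 1.00 converges to the closed-form minimum 1.54", {
  two <- molecule("cc", data.frame(
    index = 1:2, name = c("C1", "C2"), x = c(0, 1.00), y = 0, z = 0,
    sybyl_type = "C.3"),
    data.frame(bond_id = 1L, a = 1L, b = 2L, order = "1"))
  res <- minimize_bonds(two, tol = 1e-6)
  expect_true(res$converged)
  d <- abs(res$molecule$atoms$x[2] - res$molecule$atoms$x[1])
  expect_equal(d, 1.54, tolerance = 1e-5)
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("published ethane relaxes its C-C bond from 1.115 to the table length", {
  mol <- ethane_doc()$molecule
  # oracle: Euclidean distance over the printed coordinates
  d0 <- sqrt(sum((c(-6.165, 0.925, -6.713) - c(-5.555, 0.741, -5.798))^2))
  expect_equal(d0, 1.115, tolerance = 1e-3)
  d_parsed <- sqrt(sum((as.numeric(mol$atoms[1, c("x", "y", "z")]) -
                          as.numeric(mol$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(d_parsed, d0)
  res <- minimize_bonds(mol)
  expect_true(res$converged)
  m <- res$molecule
  d1 <- sqrt(sum((as.numeric(m$atoms[1, c("x", "y", "z")]) -
                    as.numeric(m$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(d1, 1.54, tolerance = 1e-3)
  expect_equal(nrow(validate_molecule(m)), 0)
})

test_that("energy traces are monotone non-increasing on jittered alkanes", {
  for (s in 1:6) {
    doc <- make_fixture("random_alkane", n = s + 1, seed = s)
    res <- minimize_bonds(doc$molecule, max_steps = 500)
    expect_true(all(diff(res$trace) <= 1e-12),
                info = sprintf("alkane n=%d seed=%d", s + 1, s))
    expect_lt(res$trace[length(res$trace)], res$trace[1])
  }
})

test_that("a bond with no table entry is an error naming the pair", {
  two <- mk_mol(c("C", "Xx"), cbind(1, 2, "1"))
  tab <- bond_length_table()
  expect_error(minimize_bonds(two, tab), "C-Xx")
  expect_error(r0_lookup(tab, "Xx", "C"), "C-Xx")
  expect_equal(r0_lookup(tab, "H", "C"), 1.09)
  expect_equal(r0_lookup(tab, "C", "H"), 1.09)
})
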