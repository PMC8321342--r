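test_that("decimal normalization handles both dialects and rejects junk", {
  # values from the builder's printed ATOM records
  expect_equal(normalize_decimal("-6,165", "comma"), -6.165)
  expect_equal(normalize_decimal("1,910", "comma"), 1.910)
  expect_equal(normalize_decimal("0", "dot"), 0)
  expect_equal(normalize_decimal("-6.165", "dot"), -6.165)
  expect_error(normalize_decimal("1,234.5", "comma"), "both")
  expect_error(normalize_decimal("abc", "dot"), "malformed")
  expect_error(normalize_decimal("", "dot"), "empty")
})

test_that("the builder ethane block parses leniently with one logged repair", {
  doc <- parse_mol2(ethane_paper_text(), mode = "lenient")
  expect_equal(n_atoms(doc$molecule), 8)
  expect_equal(n_bonds(doc$molecule), 7)
  expect_equal(doc$molecule$name, "narupa builder molecule")
  expect_equal(doc$dialect, "comma")
  expect_equal(unname(doc$declared_counts[1:2]), c(8L, 7L))
  expect_equal(doc$mol_type, "SMALL")
  expect_equal(doc$charge_method, "GASTEIGER")
  expect_length(doc$repairs, 1)
  expect_match(doc$repairs, "re-split")
  # the repaired record is bond 7: atoms 3-1 order 1
  expect_equal(doc$molecule$bonds$a[7], 3)
  expect_equal(doc$molecule$bonds$b[7], 1)
  expect_equal(doc$molecule$bonds$order[7], "1")
  # coordinates after comma normalization, first and fifth printed atoms
  expect_equal(as.numeric(doc$molecule$atoms[1, c("x", "y", "z")]),
               c(-6.165, 0.925, -6.713))
  expect_equal(as.numeric(doc$molecule$atoms[5, c("x", "y", "z")]),
               c(-6.261, 1.910, -6.857))
  # charges are absent in the builder dialect
  expect_true(all(is.na(doc$molecule$atoms$charge)))
})

test_that("strict mode refuses the defective final bond record", {
  expect_error(parse_mol2(ethane_paper_text(), mode = "strict"),
               "BOND record")
})

test_that("edge cases: empty molecule, missing sections, bad references", {
  empty <- paste("@<TRIPOS>MOLECULE", "empty", "0 0 0 0 0", "SMALL",
                 "GASTEIGER", "@<TRIPOS>ATOM", "@<TRIPOS>BOND",
                 sep = "\n")
  doc <- parse_mol2(empty, mode = "strict")
  expect_equal(n_atoms(doc$molecule), 0)
  expect_equal(n_bonds(doc$molecule), 0)
  expect_length(doc$repairs, 0)

  expect_error(parse_mol2("just some text"), "MOLECULE")
  expect_error(parse_mol2("@<TRIPOS>MOLECULE\nm\n0 0 0 0 0\nSMALL\nUSER"),
               "no atoms")

  badref <- paste("@<TRIPOS>MOLECULE", "m", "2 1 0 0 0", "SMALL", "USER",
                  "@<TRIPOS>ATOM",
                  "1 C1 0.0 0.0 0.0 C.3 1 N1",
                  "2 C2 1.5 0.0 0.0 C.3 1 N1",
                  "@<TRIPOS>BOND", "1 1 9 1", sep = "\n")
  expect_error(parse_mol2(badref, mode = "strict"), "line 10")
  len <- parse_mol2(badref, mode = "lenient")
  expect_equal(n_bonds(len$molecule), 0)
  expect_match(len$repairs, "dropped", all = FALSE)
})

test_that("count mismatches raise in strict mode and log in lenient mode", {
  txt <- paste("@<TRIPOS>MOLECULE", "m", "5 0 0 0 0", "SMALL", "USER",
               "@<TRIPOS>ATOM", "1 C1 0.0 0.0 0.0 C.3 1 N1",
               sep = "\n")
  expect_error(parse_mol2(txt, mode = "strict"), "declared counts")
  doc <- parse_mol2(txt, mode = "lenient")
  expect_equal(n_atoms(doc$molecule), 1)
  expect_match(doc$repairs, "declared counts", all = FALSE)
})

test_that("standard dot-dialect mol2 with a charge column parses fully", {
  txt <- paste("@<TRIPOS>MOLECULE", "m", "2 1 0 0 0", "SMALL", "GASTEIGER",
               "@<TRIPOS>ATOM",
               "1 C1 0.000 0.000 0.000 C.3 1 LIG1 -0.0600",
               "2 H1 1.090 0.000 0.000 H 1 LIG1 0.0230",
               "@<TRIPOS>BOND", "1 1 2 1", sep = "\n")
  doc <- parse_mol2(txt, mode = "strict")
  expect_equal(doc$dialect, "dot")
  expect_equal(doc$molecule$atoms$charge, c(-0.06, 0.023))
  expect_equal(doc$molecule$atoms$subst_name, c("LIG1", "LIG1"))
  rt <- parse_mol2(write_mol2(doc), mode = "strict")
  expect_equal(rt$molecule$atoms$charge, doc$molecule$atoms$charge)
})

test_that("bond order vocabulary maps du/un/nc to unknown", {
  txt <- paste("@<TRIPOS>MOLECULE", "m", "4 3 0 0 0", "SMALL", "USER",
               "@<TRIPOS>ATOM",
               "1 C1 0.0 0.0 0.0 C.2 1 N1",
               "2 C2 1.3 0.0 0.0 C.2 1 N1",
               "3 O1 2.8 0.0 0.0 O.3 1 N1",
               "4 N1 4.0 0.0 0.0 N.am 1 N1",
               "@<TRIPOS>BOND", "1 1 2 2", "2 2 3 du", "3 3 4 un",
               sep = "\n")
  doc <- parse_mol2(txt, mode = "strict")
  expect_equal(doc$molecule$bonds$order, c("2", "un", "un"))
})

test_that("round trip is a fixed point on every fixture in both dialects", {
  fixtures <- c(list(ethane_doc(), make_fixture("methane"),
                     make_fixture("water")),
                lapply(1:5, function(s) make_fixture("random_alkane",
                                                     n = s + 1, seed = s)))
  for (doc in fixtures) {
    rt <- parse_mol2(write_mol2(doc), mode = "strict")
    expect_same_graph(rt$molecule, doc$molecule)
    expect_equal(rt$dialect, doc$dialect)
    # second pass equals the first byte for byte
    expect_identical(write_mol2(rt), write_mol2(doc))
    # cross-dialect write: numerically identical coordinates
    other <- if (doc$dialect == "dot") "comma" else "dot"
    cross <- parse_mol2(write_mol2(doc, dialect = other), mode = "strict")
    expect_equal(cross$dialect, other)
    expect_same_graph(cross$molecule, doc$molecule)
  }
})

test_that("file I/O preserves content and handles CRLF input", {
  doc <- make_fixture("water")
  path <- withr::local_tempfile(fileext = ".mol2")
  write_mol2_file(doc, path)
  rt <- read_mol2(path, mode = "strict")
  expect_same_graph(rt$molecule, doc$molecule)
  # CRLF line endings parse identically
  crlf <- gsub("\n", "\r\n", write_mol2(doc))
  expect_same_graph(parse_mol2(crlf)$molecule, doc$molecule)
  expect_error(read_mol2("/nonexistent/file.mol2"), "not found")
})

test_that("unsupported sections are skipped with a note", {
  txt <- paste("@<TRIPOS>MOLECULE", "m", "1 0 1 0 0", "SMALL", "USER",
               "@<TRIPOS>ATOM", "1 C1 0.0 0.0 0.0 C.3 1 N1",
               "@<TRIPOS>BOND",
               "@<TRIPOS>SUBSTRUCTURE", "1 N1 1 RESIDUE", sep = "\n")
  doc <- parse_mol2(txt, mode = "lenient")
  expect_equal(n_atoms(doc$molecule), 1)
  expect_match(doc$repairs, "SUBSTRUCTURE", all = FALSE)
})
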