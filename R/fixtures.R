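# Built-in fixture molecules: the verbatim Narupa Builder ethane export
# (the published worked example, comma dialect, including its defective
# final bond record), small reference molecules, and seeded random
# alkanes for property tests.

#' The verbatim Narupa Builder ethane export
#'
#' Returns the published ethane mol2 block exactly as the builder exported
#' it: comma decimal separators, header counts \code{"8 7 0 0 0"}, and a
#' final bond record printed as \code{"7 3 11"} — a fused \code{"1 1"}
#' that lenient parsing repairs (and strict parsing rejects).
#'
#' @return a single string (trailing newline included).
#' @export
ethane_paper_text <- function() {
  paste0(paste(c(
    "@<TRIPOS>MOLECULE",
    "narupa builder molecule",
    "8 7 0 0 0",
    "SMALL",
    "GASTEIGER",
    "@<TRIPOS>ATOM",
    "1 C1 -6,165 0,925 -6,713 C.3 1 N1",
    "2 C2 -5,555 0,741 -5,798 C.3 1 N1",
    "3 H1 -7,070 0,516 -6,599 H 1 N1",
    "4 H2 -5,711 0,516 -7,504 H 1 N1",
    "5 H3 -6,261 1,910 -6,857 H 1 N1",
    "6 H4 -4,737 0,221 -6,042 H 1 N1",
    "7 H5 -6,096 0,221 -5,137 H 1 N1",
    "8 H6 -5,287 1,615 -5,394 H 1 N1",
    "@<TRIPOS>BOND",
    "1 2 1 1",
    "2 8 2 1",
    "3 7 2 1",
    "4 6 2 1",
    "5 5 1 1",
    "6 4 1 1",
    "7 3 11"), collapse = "\n"), "\n")
}

.tetrahedral_dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                            ncol = 3, byrow = TRUE) / sqrt(3)

#' Built-in fixture molecules
#'
#' \describe{
#'   \item{\code{ethane_paper}}{the verbatim builder export (see
#'     \code{\link{ethane_paper_text}}), parsed leniently; its single
#'     logged repair is the re-split of the fused final bond token.}
#'   \item{\code{methane}}{CH4, tetrahedral, C-H 1.09 Angstrom, dot
#'     dialect.}
#'   \item{\code{water}}{H2O, O-H 0.96 Angstrom, 104.5 degree angle.}
#'   \item{\code{random_alkane}}{a straight-chain alkane CnH2n+2: carbons
#'     1.54 Angstrom apart along x, hydrogens added by
#'     \code{\link{balance_hydrogens}}, all coordinates jittered by a
#'     seeded perturbation (up to 0.05 Angstrom per component) so the
#'     minimizer has nontrivial work. Deterministic per \code{(n, seed)}.}
#' }
#'
#' @param name one of \code{"ethane_paper"}, \code{"methane"},
#'   \code{"water"}, \code{"random_alkane"}.
#' @param n chain length for \code{random_alkane} (1 to 20).
#' @param seed integer seed for \code{random_alkane} (default 0).
#' @return a \code{\link{mol2_document}}.
#' @export
make_fixture <- function(name, n = 3, seed = 0) {
  known <- c("ethane_paper", "methane", "water", "random_alkane")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  if (name == "ethane_paper") {
    return(parse_mol2(ethane_paper_text(), mode = "lenient"))
  }
  if (name == "methane") {
    h <- .tetrahedral_dirs * 1.09
    atoms <- data.frame(
      index = 1:5,
      name = c("C1", paste0("H", 1:4)),
      x = c(0, h[, 1]), y = c(0, h[, 2]), z = c(0, h[, 3]),
      sybyl_type = c("C.3", rep("H", 4)),
      stringsAsFactors = FALSE)
    bonds <- data.frame(bond_id = 1:4, a = 1L, b = 2:5, order = "1",
                        stringsAsFactors = FALSE)
    return(mol2_document(molecule("methane", atoms, bonds), dialect = "dot"))
  }
  if (name == "water") {
    half <- 104.5 / 2 * pi / 180
    atoms <- data.frame(
      index = 1:3,
      name = c("O1", "H1", "H2"),
      x = c(0, 0.96 * sin(half), -0.96 * sin(half)),
      y = c(0, 0.96 * cos(half), 0.96 * cos(half)),
      z = c(0, 0, 0),
      sybyl_type = c("O.3", "H", "H"),
      stringsAsFactors = FALSE)
    bonds <- data.frame(bond_id = 1:2, a = 1L, b = 2:3, order = "1",
                        stringsAsFactors = FALSE)
    return(mol2_document(molecule("water", atoms, bonds), dialect = "dot"))
  }
  # random_alkane
  if (!is.numeric(n) || n < 1 || n > 20) {
    stop("random_alkane chain length must be between 1 and 20")
  }
  n <- as.integer(n)
  atoms <- data.frame(
    index = seq_len(n),
    name = paste0("C", seq_len(n)),
    x = (seq_len(n) - 1) * 1.54, y = 0, z = 0,
    sybyl_type = "C.3",
    stringsAsFactors = FALSE)
  bonds <- if (n > 1) data.frame(
    bond_id = seq_len(n - 1), a = seq_len(n - 1), b = 2:n, order = "1",
    stringsAsFactors = FALSE) else NULL
  mol <- molecule(sprintf("alkane_C%d", n), atoms, bonds)
  mol <- balance_hydrogens(mol, seed = seed)
  gen <- lcg_new(seed + 1)
  for (i in seq_len(n_atoms(mol))) {
    jit <- (lcg_unif(gen, 3) - 0.5) * 0.1
    # 4-decimal coordinates, like a real builder export
    mol$atoms$x[i] <- round(mol$atoms$x[i] + jit[1], 4)
    mol$atoms$y[i] <- round(mol$atoms$y[i] + jit[2], 4)
    mol$atoms$z[i] <- round(mol$atoms$z[i] + jit[3], 4)
  }
  mol2_document(mol, dialect = "dot")
}

#' Write the demo fixture files to a directory
#'
#' Emits \code{ethane_paper.mol2} (the verbatim builder export),
#' \code{methane.mol2} and \code{water.mol2}.
#'
#' @param dir output directory (created if absent).
#' @return character vector of the written paths, invisibly.
#' @export
write_demo_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "ethane_paper.mol2")
  writeLines(sub("\n$", "", ethane_paper_text()), p, useBytes = TRUE)
  paths <- c(paths, p)
  for (nm in c("methane", "water")) {
    p <- file.path(dir, paste0(nm, ".mol2"))
    write_mol2_file(make_fixture(nm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
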