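# Core molecular-graph types: atoms, bonds, molecule, valence model.
# All containers are plain data.frames inside a classed list so that
# downstream modules (mol2 I/O, XML serialization, chemistry ops) share
# one in-memory representation.

# Recognised element symbols (SYBYL prefixes must resolve to one of these).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te",
  "I", "Xe", "Cs", "Ba", "W", "Re", "Os", "Ir", "Pt", "Au",
  "Hg", "Tl", "Pb", "Bi", "U"
)

# Bond-order vocabulary and the numeric weight each order contributes to a
# valence sum. Aromatic counts 1.5 (Kekule-free accounting), amide 1,
# unknown ("du"/"un"/"nc" in mol2) conservatively 1.
.BOND_ORDERS <- c("1", "2", "3", "ar", "am", "un")

#' Numeric valence weight of a bond order
#'
#' Maps the symbolic bond orders used throughout the package to the value
#' they contribute to an atom's valence sum: single/double/triple map to
#' 1/2/3, aromatic to 1.5, amide and unknown to 1.
#'
#' @param order character vector of bond orders
#'   (\code{"1"}, \code{"2"}, \code{"3"}, \code{"ar"}, \code{"am"}, \code{"un"}).
#' @return numeric vector of the same length.
#' @export
bond_order_value <- function(order) {
  v <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, "un" = 1)
  bad <- !order %in% names(v)
  if (any(bad)) {
    stop("unknown bond order: ", paste(unique(order[bad]), collapse = ", "))
  }
  unname(v[order])
}

#' Derive the chemical element from a SYBYL atom type
#'
#' The element is the text before the first \code{"."} of the SYBYL type
#' (e.g. \code{"C.3"} is carbon, \code{"Cl"} chlorine). The first letter is
#' uppercased and a second lowercase alphabetic letter is kept, so the atom
#' *name* (which may be \code{"C1"}) is never consulted.
#'
#' @param sybyl_type character vector of SYBYL types.
#' @return character vector of element symbols; unrecognized symbols are
#'   returned as-is (validation reports them as violations rather than
#'   raising here).
#' @export
sybyl_element <- function(sybyl_type) {
  prefix <- sub("\\..*$", "", sybyl_type)
  out <- vapply(prefix, function(p) {
    if (!nzchar(p)) return(p)
    first <- toupper(substr(p, 1, 1))
    rest <- substr(p, 2, 2)
    if (nzchar(rest) && grepl("^[a-z]$", rest)) paste0(first, rest) else first
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Construct a molecule
#'
#' Builds a validated-in-structure molecular graph from an atom table and a
#' bond table. Atom indices are normalized to \code{1..N} (bond endpoints
#' are remapped accordingly); bonds must connect two distinct existing
#' atoms and each unordered atom pair may appear at most once.
#'
#' @param name molecule name.
#' @param atoms data.frame with columns \code{index}, \code{name},
#'   \code{x}, \code{y}, \code{z}, \code{sybyl_type}, and optionally
#'   \code{subst_id}, \code{subst_name}, \code{charge}. The \code{element}
#'   column is always (re)derived from \code{sybyl_type}.
#' @param bonds data.frame with columns \code{bond_id}, \code{a}, \code{b},
#'   \code{order} (see \code{\link{bond_order_value}}); may have zero rows.
#' @return an object of class \code{"molecule"}.
#' @export
molecule <- function(name, atoms, bonds = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (is.null(bonds)) {
    bonds <- data.frame(bond_id = integer(), a = integer(), b = integer(),
                        order = character(), stringsAsFactors = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)

  need <- c("index", "name", "x", "y", "z", "sybyl_type")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"subst_id" %in% names(atoms)) atoms$subst_id <- rep(1L, nrow(atoms))
  if (!"subst_name" %in% names(atoms)) atoms$subst_name <- rep("N1", nrow(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- rep(NA_real_, nrow(atoms))

  n <- nrow(atoms)
  if (n > 0) {
    if (anyDuplicated(atoms$index)) stop("duplicate atom indices")
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite atom coordinates")
    }
    # normalize indices to 1..N in file order, remapping bond endpoints
    remap <- seq_len(n)
    names(remap) <- as.character(atoms$index)
    if (nrow(bonds) > 0) {
      ka <- as.character(bonds$a)
      kb <- as.character(bonds$b)
      if (!all(ka %in% names(remap)) || !all(kb %in% names(remap))) {
        bad <- unique(c(bonds$a[!ka %in% names(remap)],
                        bonds$b[!kb %in% names(remap)]))
        stop("bond references nonexistent atom index: ",
             paste(bad, collapse = ", "))
      }
      bonds$a <- unname(remap[ka])
      bonds$b <- unname(remap[kb])
    }
    atoms$index <- seq_len(n)
  } else if (nrow(bonds) > 0) {
    stop("bonds present but no atoms")
  }
  atoms$element <- sybyl_element(atoms$sybyl_type)

  if (nrow(bonds) > 0) {
    if (any(bonds$a == bonds$b)) stop("bond connects an atom to itself")
    if (!all(bonds$order %in% .BOND_ORDERS)) {
      stop("unknown bond order: ",
           paste(unique(bonds$order[!bonds$order %in% .BOND_ORDERS]),
                 collapse = ", "))
    }
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    bonds$bond_id <- seq_len(nrow(bonds))
  }
  atoms <- atoms[c("index", "name", "x", "y", "z", "sybyl_type", "element",
                   "subst_id", "subst_name", "charge")]
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(list(name = name, atoms = atoms, bonds = bonds),
            class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol a \code{molecule}.
#' @return integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of bonds in a molecule
#' @param mol a \code{molecule}.
#' @return integer count.
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds (%s)\n",
              x$name, n_atoms(x), n_bonds(x), molecular_formula(x)))
  invisible(x)
}

#' Degree of an atom
#'
#' Counts the bonds incident to an atom (bond multiplicity is ignored; a
#' double bond contributes 1 to the degree).
#'
#' @param mol a \code{molecule}.
#' @param atom_index 1-based atom index.
#' @return non-negative integer.
#' @export
atom_degree <- function(mol, atom_index) {
  if (length(atom_index) != 1 || !atom_index %in% mol$atoms$index) {
    stop("no such atom: ", atom_index)
  }
  sum(mol$bonds$a == atom_index | mol$bonds$b == atom_index)
}

#' Adjacency list of a molecule
#' @param mol a \code{molecule}.
#' @return list of integer vectors, element i holding the neighbours of atom i.
#' @export
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (n_bonds(mol) > 0) {
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' Per-atom valence sums
#'
#' Sum of numeric bond-order weights over the bonds incident to each atom
#' (see \code{\link{bond_order_value}}).
#'
#' @param mol a \code{molecule}.
#' @return numeric vector of length \code{n_atoms(mol)}.
#' @export
valence_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  if (n_bonds(mol) > 0) {
    w <- bond_order_value(mol$bonds$order)
    for (k in seq_len(n_bonds(mol))) {
      s[mol$bonds$a[k]] <- s[mol$bonds$a[k]] + w[k]
      s[mol$bonds$b[k]] <- s[mol$bonds$b[k]] + w[k]
    }
  }
  s
}

#' Molecular formula in Hill order
#' @param mol a \code{molecule}.
#' @return string such as \code{"C2H6"}; \code{""} for an empty molecule.
#' @export
molecular_formula <- function(mol) {
  if (n_atoms(mol) == 0) return("")
  tab <- table(mol$atoms$element)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1) e else paste0(e, tab[[e]])
  }, character(1)), collapse = "")
}

#' Valence model: maximum bond-order budget per element
#'
#' The model realizes a simple feasibility rule: an atom may not carry a
#' valence sum above its element's maximum. Defaults ship with the package
#' (H 1, C 4, N 3, O 2, S 6, P 5, halogens 1) and can be overridden from a
#' key-value config file or a named vector.
#'
#' @param path optional path to a config file (lines of
#'   \code{"<element> <max>"}; \code{#} starts a comment).
#' @param values optional named numeric/integer vector overriding or
#'   extending the defaults, e.g. \code{c(C = 4, Xx = 2)}.
#' @return object of class \code{"valence_model"} (a named integer vector
#'   wrapped in a list).
#' @export
valence_model <- function(path = NULL, values = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "valence.conf", package = "mol2narupa")
  }
  max_valence <- .read_kv_config(path, n_fields = 2)
  mv <- stats::setNames(as.integer(max_valence[[2]]), max_valence[[1]])
  if (!is.null(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values)))) {
      stop("'values' must be a fully named vector")
    }
    mv[names(values)] <- as.integer(values)
  }
  if (any(mv < 1)) stop("valence maxima must be >= 1")
  structure(list(max_valence = mv), class = "valence_model")
}

#' @export
print.valence_model <- function(x, ...) {
  cat("<valence_model>", paste(names(x$max_valence), x$max_valence,
                               sep = ":", collapse = " "), "\n")
  invisible(x)
}

max_valence_of <- function(model, element) {
  if (!element %in% names(model$max_valence)) {
    stop("no valence entry for element: ", element)
  }
  unname(model$max_valence[[element]])
}

# key-value config reader shared by valence_model and bond_length_table
.read_kv_config <- function(path, n_fields) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[ \t]+")
  bad <- vapply(toks, length, integer(1)) != n_fields
  if (any(bad)) {
    stop("malformed config line in ", path, ": '", lines[which(bad)[1]], "'")
  }
  as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
}

#' Validate a molecule against a valence model
#'
#' Checks every bond (distinct endpoints, valid references, unique pairs —
#' these are enforced at construction, so violations can only enter through
#' manual edits) and every atom (recognized element with a valence entry;
#' valence sum within the element's maximum). This is the library analogue
#' of the builder's green/red bond display: an empty report means every
#' bond shown would be green.
#'
#' @param mol a \code{molecule}.
#' @param model a \code{\link{valence_model}}; defaults to the shipped one.
#' @return data.frame with columns \code{kind} (\code{"atom"} or
#'   \code{"bond"}), \code{subject} (atom index or bond id), \code{rule},
#'   \code{message}; zero rows when the molecule is valid.
#' @export
validate_molecule <- function(mol, model = valence_model()) {
  stopifnot(inherits(mol, "molecule"))
  viol <- list()
  add <- function(kind, subject, rule, message) {
    viol[[length(viol) + 1]] <<- data.frame(
      kind = kind, subject = as.integer(subject), rule = rule,
      message = message, stringsAsFactors = FALSE)
  }
  sums <- valence_sums(mol)
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[i]
    if (!el %in% .ELEMENTS) {
      add("atom", i, "unknown element",
          sprintf("atom %d (%s): unrecognized element symbol '%s'",
                  i, mol$atoms$name[i], el))
      next
    }
    if (!el %in% names(model$max_valence)) {
      add("atom", i, "no valence entry",
          sprintf("atom %d (%s): element '%s' has no entry in the valence model",
                  i, mol$atoms$name[i], el))
      next
    }
    mx <- max_valence_of(model, el)
    if (sums[i] > mx + 1e-9) {
      add("atom", i, "valence exceeded",
          sprintf("atom %d (%s): valence sum %.1f exceeds maximum %d for %s",
                  i, mol$atoms$name[i], sums[i], mx, el))
    }
  }
  if (n_bonds(mol) > 0) {
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      if (a == b) {
        add("bond", mol$bonds$bond_id[k], "self bond",
            sprintf("bond %d connects atom %d to itself", k, a))
      }
      if (!a %in% mol$atoms$index || !b %in% mol$atoms$index) {
        add("bond", mol$bonds$bond_id[k], "dangling bond",
            sprintf("bond %d references a nonexistent atom", k))
      }
    }
  }
  if (length(viol) == 0) {
    return(data.frame(kind = character(), subject = integer(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
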