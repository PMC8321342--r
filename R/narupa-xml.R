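# NarupaXR-style simulation XML.
#
# The document layout is a root <Simulation> element holding <Temperature>,
# <Atoms>, <Bonds> and <Mappings> blocks. The two per-atom mapping elements
# follow the NarupaXR spelling exactly:
#
#   <MM3AtomMapping AtomPath="0" Type=" "/>
#   <LennardJonesAtomMapping AtomPath="0" MM3Type=" "/>
#
# AtomPath is the zero-based decimal index of the atom; an untyped atom
# carries a single-space placeholder (the state a user fills in by hand
# from their mm3.xml glossary). Serialization is deterministic, and
# write -> parse -> write is byte-stable.

#' Construct a simulation spec
#'
#' A molecule plus the simulation metadata needed for the XML file:
#' temperature and one MM3 and one Lennard-Jones type code per atom, keyed
#' by zero-based AtomPath strings.
#'
#' @param molecule a \code{\link{molecule}}.
#' @param temperature simulation temperature in kelvin (default 300).
#' @param mm3_types,lj_types named character vectors with exactly one entry
#'   per atom; names must be \code{"0" .. "N-1"}. Blank entries are the
#'   single space \code{" "}. Default: all blank.
#' @return object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(molecule, temperature = 300,
                            mm3_types = NULL, lj_types = NULL) {
  stopifnot(inherits(molecule, "molecule"))
  n <- n_atoms(molecule)
  paths <- as.character(seq_len(n) - 1L)
  blank <- stats::setNames(rep(" ", n), paths)
  if (is.null(mm3_types)) mm3_types <- blank
  if (is.null(lj_types)) lj_types <- blank
  for (nm in c("mm3_types", "lj_types")) {
    v <- get(nm)
    if (length(v) != n || !identical(sort(names(v)), sort(paths))) {
      stop(nm, " must have exactly one entry per atom, named '0'..'",
           n - 1, "'")
    }
  }
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature)) {
    stop("temperature must be a finite number (kelvin)")
  }
  structure(list(molecule = molecule, temperature = as.numeric(temperature),
                 mm3_types = mm3_types[paths], lj_types = lj_types[paths]),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  typed <- sum(x$mm3_types != " ")
  cat(sprintf(
    "<simulation_spec> %s: %d atoms, %d bonds, T=%g K, %d/%d atoms typed\n",
    x$molecule$name, n_atoms(x$molecule), n_bonds(x$molecule),
    x$temperature, typed, n_atoms(x$molecule)))
  invisible(x)
}

#' Build a simulation spec from a mol2 document
#'
#' Creates one MM3 and one Lennard-Jones mapping entry per atom, in file
#' order with zero-based AtomPaths. Without a glossary (or where no
#' glossary rule matches) entries are the blank placeholder \code{" "} —
#' exactly the manual-fill state of a freshly converted file. With a
#' glossary, \code{\link{assign_types}} fills both mappings with the same
#' code.
#'
#' @param doc a \code{\link{mol2_document}} (or a bare
#'   \code{\link{molecule}}).
#' @param temperature kelvin; default 300.
#' @param glossary optional \code{\link{load_glossary}} result.
#' @return a \code{\link{simulation_spec}}.
#' @export
build_spec <- function(doc, temperature = 300, glossary = NULL) {
  mol <- if (inherits(doc, "mol2_document")) doc$molecule else doc
  stopifnot(inherits(mol, "molecule"))
  if (is.null(glossary)) {
    return(simulation_spec(mol, temperature))
  }
  asg <- assign_types(mol, glossary)
  simulation_spec(mol, temperature, mm3_types = asg$types,
                  lj_types = asg$types)
}

.xml_attr_line <- function(tag, attrs) {
  vals <- vapply(attrs, function(v) {
    v <- gsub("&", "&amp;", v, fixed = TRUE)
    v <- gsub("<", "&lt;", v, fixed = TRUE)
    gsub("\"", "&quot;", v, fixed = TRUE)
  }, character(1))
  paste0("<", tag, " ",
         paste0(names(attrs), "=\"", vals, "\"", collapse = " "), "/>")
}

#' Serialize a simulation spec to XML
#'
#' Output is UTF-8 with an XML declaration, stable element/attribute
#' ordering and fixed numeric formatting, so repeated calls are
#' byte-identical.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param path optional output file; when given the text is also written
#'   there.
#' @return the XML text as a single string.
#' @export
write_simulation_xml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  mol <- spec$molecule
  ind <- function(k) strrep("  ", k)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<Simulation Name=\"%s\">", gsub("\"", "&quot;", mol$name)),
    paste0(ind(1), .xml_attr_line("Temperature",
                                  c(Value = fmt_num(spec$temperature, 0)))),
    paste0(ind(1), "<Atoms>"))
  for (i in seq_len(n_atoms(mol))) {
    a <- mol$atoms[i, ]
    attrs <- c(AtomPath = as.character(i - 1L), Name = a$name,
               Element = a$element, SybylType = a$sybyl_type,
               X = fmt_num(a$x), Y = fmt_num(a$y), Z = fmt_num(a$z),
               SubstId = as.character(a$subst_id), SubstName = a$subst_name)
    if (!is.na(a$charge)) attrs <- c(attrs, Charge = fmt_num(a$charge, 4))
    lines <- c(lines, paste0(ind(2), .xml_attr_line("Atom", attrs)))
  }
  lines <- c(lines, paste0(ind(1), "</Atoms>"), paste0(ind(1), "<Bonds>"))
  for (k in seq_len(n_bonds(mol))) {
    b <- mol$bonds[k, ]
    lines <- c(lines, paste0(ind(2), .xml_attr_line(
      "Bond", c(A = as.character(b$a - 1L), B = as.character(b$b - 1L),
                Order = b$order))))
  }
  lines <- c(lines, paste0(ind(1), "</Bonds>"), paste0(ind(1), "<Mappings>"))
  paths <- as.character(seq_len(n_atoms(mol)) - 1L)
  for (p in paths) {
    lines <- c(lines, paste0(ind(2), .xml_attr_line(
      "MM3AtomMapping", c(AtomPath = p, Type = spec$mm3_types[[p]]))))
  }
  for (p in paths) {
    lines <- c(lines, paste0(ind(2), .xml_attr_line(
      "LennardJonesAtomMapping",
      c(AtomPath = p, MM3Type = spec$lj_types[[p]]))))
  }
  lines <- c(lines, paste0(ind(1), "</Mappings>"), "</Simulation>")
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", out), path, useBytes = TRUE)
  out
}

#' Parse simulation XML back into a spec
#'
#' Inverse of \code{\link{write_simulation_xml}} on its own output. Unknown
#' child elements are skipped with a warning; a missing or out-of-range
#' mapping entry is an error naming the AtomPath.
#'
#' @param text XML as a string, or a path to an XML file.
#' @return a \code{\link{simulation_spec}}.
#' @export
parse_simulation_xml <- function(text) {
  src <- if (length(text) == 1 && !grepl("<", text, fixed = TRUE) &&
             file.exists(text)) text else paste(text, collapse = "\n")
  doc <- xml2::read_xml(src)
  if (xml2::xml_name(doc) != "Simulation") {
    stop("root element is <", xml2::xml_name(doc), ">, expected <Simulation>")
  }
  known <- c("Temperature", "Atoms", "Bonds", "Mappings")
  kids <- xml2::xml_children(doc)
  unknown <- setdiff(unique(xml2::xml_name(kids)), known)
  if (length(unknown)) {
    warning("skipping unknown element(s): ", paste(unknown, collapse = ", "))
  }
  temp_node <- xml2::xml_find_first(doc, "./Temperature")
  temperature <- if (inherits(temp_node, "xml_missing")) 300 else
    as.numeric(xml2::xml_attr(temp_node, "Value"))

  atom_nodes <- xml2::xml_find_all(doc, "./Atoms/Atom")
  n <- length(atom_nodes)
  atoms <- data.frame(
    index = as.integer(vapply(atom_nodes, xml2::xml_attr, character(1),
                              attr = "AtomPath")) + 1L,
    name = vapply(atom_nodes, xml2::xml_attr, character(1), attr = "Name"),
    x = as.numeric(vapply(atom_nodes, xml2::xml_attr, character(1),
                          attr = "X")),
    y = as.numeric(vapply(atom_nodes, xml2::xml_attr, character(1),
                          attr = "Y")),
    z = as.numeric(vapply(atom_nodes, xml2::xml_attr, character(1),
                          attr = "Z")),
    sybyl_type = vapply(atom_nodes, xml2::xml_attr, character(1),
                        attr = "SybylType"),
    subst_id = as.integer(vapply(atom_nodes, xml2::xml_attr, character(1),
                                 attr = "SubstId")),
    subst_name = vapply(atom_nodes, xml2::xml_attr, character(1),
                        attr = "SubstName"),
    charge = as.numeric(vapply(atom_nodes, function(nd) {
      v <- xml2::xml_attr(nd, "Charge")
      if (is.na(v)) NA_character_ else v
    }, character(1))),
    stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$index), , drop = FALSE]

  bond_nodes <- xml2::xml_find_all(doc, "./Bonds/Bond")
  bonds <- if (length(bond_nodes)) data.frame(
    bond_id = seq_along(bond_nodes),
    a = as.integer(vapply(bond_nodes, xml2::xml_attr, character(1),
                          attr = "A")) + 1L,
    b = as.integer(vapply(bond_nodes, xml2::xml_attr, character(1),
                          attr = "B")) + 1L,
    order = vapply(bond_nodes, xml2::xml_attr, character(1), attr = "Order"),
    stringsAsFactors = FALSE) else NULL

  mol <- molecule(xml2::xml_attr(doc, "Name"), atoms, bonds)

  read_mapping <- function(tag, attr) {
    nodes <- xml2::xml_find_all(doc, paste0("./Mappings/", tag))
    paths <- vapply(nodes, xml2::xml_attr, character(1), attr = "AtomPath")
    vals <- vapply(nodes, xml2::xml_attr, character(1), attr = attr)
    valid <- as.character(seq_len(n) - 1L)
    out_of_range <- setdiff(paths, valid)
    if (length(out_of_range)) {
      stop(tag, " entry for nonexistent AtomPath ",
           paste(out_of_range, collapse = ", "),
           " (molecule has ", n, " atoms)")
    }
    missing <- setdiff(valid, paths)
    if (length(missing)) {
      stop("missing ", tag, " entry for AtomPath ",
           paste(missing, collapse = ", "))
    }
    stats::setNames(vals, paths)[valid]
  }
  simulation_spec(mol, temperature,
                  mm3_types = read_mapping("MM3AtomMapping", "Type"),
                  lj_types = read_mapping("LennardJonesAtomMapping",
                                          "MM3Type"))
}
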