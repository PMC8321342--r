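# MM3-style force-field glossary: load ordered typing rules from a small
# XML file and assign per-atom type codes. This fills the Type/MM3Type
# attributes that a NarupaXR user otherwise copies by hand from the
# mm3.xml glossary shipped with the engine; that file's schema is not
# public, so the package defines its own documented rule format and ships
# a demo glossary for common organic atoms (users transcribe their
# mm3.xml entries into it).
#
# Glossary file format:
#
#   <ForceFieldGlossary Name="demo-mm3">
#     <Rule element="C" sybyl="C.3" type="1"/>
#     <Rule element="C" degree="3"  type="2"/>
#     <Rule element="H"             type="5"/>
#   </ForceFieldGlossary>
#
# Each <Rule> needs a type code and at least one of element / degree /
# sybyl. Matching precedence per atom: an explicit sybyl pattern beats
# element+degree, which beats element-only; within a tier, document order
# wins (first match).

#' Load a force-field glossary
#'
#' @param x path to a glossary XML file, or the XML text itself.
#' @return object of class \code{"ff_glossary"} with an ordered \code{rules}
#'   data.frame (\code{element}, \code{degree}, \code{sybyl}, \code{type})
#'   and \code{source_name}.
#' @export
load_glossary <- function(x) {
  src <- if (length(x) == 1 && !grepl("<", x, fixed = TRUE)) {
    if (!file.exists(x)) stop("glossary file not found: ", x)
    x
  } else {
    paste(x, collapse = "\n")
  }
  doc <- xml2::read_xml(src)
  if (xml2::xml_name(doc) != "ForceFieldGlossary") {
    stop("glossary root element must be <ForceFieldGlossary>, got <",
         xml2::xml_name(doc), ">")
  }
  nodes <- xml2::xml_find_all(doc, "./Rule")
  if (length(nodes) == 0) stop("empty glossary: no <Rule> entries")
  rules <- lapply(seq_along(nodes), function(i) {
    nd <- nodes[[i]]
    type <- xml2::xml_attr(nd, "type")
    if (is.na(type)) {
      stop("glossary rule ", i, " lacks the required 'type' attribute")
    }
    el <- xml2::xml_attr(nd, "element")
    deg <- xml2::xml_attr(nd, "degree")
    syb <- xml2::xml_attr(nd, "sybyl")
    if (is.na(el) && is.na(deg) && is.na(syb)) {
      stop("glossary rule ", i,
           " needs at least one of element/degree/sybyl")
    }
    if (!is.na(deg) && is.na(suppressWarnings(as.integer(deg)))) {
      stop("glossary rule ", i, ": degree '", deg, "' is not an integer")
    }
    data.frame(element = el, degree = if (is.na(deg)) NA_integer_ else
      as.integer(deg), sybyl = syb, type = type, stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rules)
  name <- xml2::xml_attr(doc, "Name")
  structure(list(rules = rules,
                 source_name = if (is.na(name)) "" else name),
            class = "ff_glossary")
}

#' @export
print.ff_glossary <- function(x, ...) {
  cat(sprintf("<ff_glossary> %s: %d rules\n", x$source_name, nrow(x$rules)))
  invisible(x)
}

#' Serialize a glossary back to XML
#' @param glossary an \code{"ff_glossary"}.
#' @param path optional output file.
#' @return the XML text.
#' @export
write_glossary <- function(glossary, path = NULL) {
  stopifnot(inherits(glossary, "ff_glossary"))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<ForceFieldGlossary Name=\"%s\">",
                     glossary$source_name))
  for (i in seq_len(nrow(glossary$rules))) {
    r <- glossary$rules[i, ]
    attrs <- character()
    if (!is.na(r$element)) attrs <- c(attrs, sprintf("element=\"%s\"",
                                                     r$element))
    if (!is.na(r$degree)) attrs <- c(attrs, sprintf("degree=\"%d\"",
                                                    r$degree))
    if (!is.na(r$sybyl)) attrs <- c(attrs, sprintf("sybyl=\"%s\"", r$sybyl))
    attrs <- c(attrs, sprintf("type=\"%s\"", r$type))
    lines <- c(lines, paste0("  <Rule ", paste(attrs, collapse = " "), "/>"))
  }
  lines <- c(lines, "</ForceFieldGlossary>")
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", out), path, useBytes = TRUE)
  out
}

#' The shipped demo glossary
#' @return an \code{"ff_glossary"} covering common organic atoms.
#' @export
demo_glossary <- function() {
  load_glossary(system.file("extdata", "demo_glossary.xml",
                            package = "mol2narupa"))
}

#' Assign force-field type codes to every atom
#'
#' Pure function of the molecule and glossary: each atom gets the type
#' code of the first matching rule under the precedence sybyl >
#' element+degree > element-only (document order within a tier), or the
#' blank placeholder \code{" "} with a warning entry when nothing matches
#' — reproducing the manual-fill state of an untyped simulation file.
#'
#' @param mol a \code{molecule}.
#' @param glossary an \code{"ff_glossary"}, or \code{NULL} for no typing.
#' @return list with \code{types} (named character vector, one entry per
#'   atom keyed by zero-based AtomPath) and \code{warnings} (character
#'   vector naming unmatched atoms).
#' @export
assign_types <- function(mol, glossary = NULL) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  paths <- as.character(seq_len(n) - 1L)
  types <- stats::setNames(rep(" ", n), paths)
  warnings <- character()
  degs <- vapply(seq_len(n), function(i) atom_degree(mol, i), integer(1))
  rules <- if (is.null(glossary)) NULL else glossary$rules
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    syb <- mol$atoms$sybyl_type[i]
    match_type <- NA_character_
    if (!is.null(rules) && nrow(rules) > 0) {
      tier <- rep(NA_integer_, nrow(rules))
      for (r in seq_len(nrow(rules))) {
        rl <- rules[r, ]
        if (!is.na(rl$element) && rl$element != el) next
        if (!is.na(rl$sybyl)) {
          if (rl$sybyl == syb) tier[r] <- 1L
        } else if (!is.na(rl$degree)) {
          if (!is.na(rl$element) && rl$degree == degs[i]) tier[r] <- 2L
        } else if (!is.na(rl$element)) {
          tier[r] <- 3L
        }
      }
      if (any(!is.na(tier))) {
        best <- which(tier == min(tier, na.rm = TRUE))[1]
        match_type <- rules$type[best]
      }
    }
    if (is.na(match_type)) {
      warnings <- c(warnings, sprintf(
        "atom %d (%s, %s, degree %d): no glossary rule matched",
        i, mol$atoms$name[i], syb, degs[i]))
    } else {
      types[[paths[i]]] <- match_type
    }
  }
  list(types = types, warnings = warnings)
}
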